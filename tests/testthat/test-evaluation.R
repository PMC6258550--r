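test_that("tp_fraction has the right fixed points and matches the random expectation", {
  gold <- data.frame(species = rep("s", 3), id_A = c("a1", "a2", "a3"),
                     id_B = c("b1", "b2", "b3"))
  expect_equal(tp_fraction(gold, gold), 1)
  wrong <- transform(gold, id_B = c("b2", "b3", "b1"))
  expect_equal(tp_fraction(wrong, gold), 0)
  expect_error(tp_fraction(gold[0, ], gold), "no predicted pairs")
  # exclusion removes training pairs from the denominator
  mixed <- rbind(gold[1:2, ], wrong[3, ])
  expect_equal(tp_fraction(mixed, gold, exclude = gold[1, ]), 0.5)

  # Monte-Carlo random within-species pairing matches (#species)/M
  aln <- small_coupled_alignment(seed = 31, n_species = 20, m = 4,
                                 L_A = 4, L_B = 4, n_coupled = 0, epsilon = 0)
  mc <- random_pairing_tp(aln, n_draws = 600, rng_seed = 1)
  expected <- random_pairing_expectation(aln)
  expect_equal(expected, 20 / 80)
  expect_lt(abs(mc$mean - expected), 3 * mc$se + 1e-12)
})

test_that("excess shared predictions: identical gives 1, the worked example gives 0, null is centered", {
  # identical predictions: numerator equals denominator
  st_same <- data.frame(m = c(4, 6), p = c(2, 3), q = c(2, 3), k_obs = c(2, 3))
  expect_equal(excess_shared(st_same), 1)
  # single species m=4, p=q=2, k_obs=1: <k> = 1, numerator 0
  st0 <- data.frame(m = 4, p = 2, q = 2, k_obs = 1)
  expect_equal(excess_shared(st0), 0)
  # degenerate denominator
  expect_warning(e <- excess_shared(data.frame(m = 2, p = 2, q = 2, k_obs = 2)),
                 "degenerate")
  expect_true(is.na(e))
  # independent predictors: mean E within 3 standard errors of 0
  set.seed(33)
  st <- data.frame(m = sample(3:10, 20, replace = TRUE))
  st$p <- vapply(st$m, function(m) sample.int(m, 1) - 1L, 1L)
  st$q <- vapply(st$m, function(m) sample.int(m, 1) - 1L, 1L)
  null <- excess_shared_null(st, n_sims = 4000, rng_seed = 34)
  expect_lt(abs(null$mean), 3 * null$se)
})

test_that("shared_prediction_stats counts per-species joint correctness", {
  gold <- data.frame(species = rep(c("s1", "s2"), each = 2),
                     id_A = c("a1", "a2", "a3", "a4"),
                     id_B = c("b1", "b2", "b3", "b4"))
  p1 <- gold                                   # all correct
  p2 <- gold
  p2$id_B <- c("b2", "b1", "b3", "b4")         # s1 wrong, s2 correct
  st <- shared_prediction_stats(p1, p2, gold)
  expect_equal(st$m, c(2L, 2L))
  expect_equal(st$p, c(2L, 2L))
  expect_equal(st$q, c(0L, 2L))
  expect_equal(st$k_obs, c(0L, 2L))
})

test_that("column scrambling preserves marginals and sizes but kills inter-column MI", {
  aln <- small_coupled_alignment(seed = 35, n_species = 25, m = 4,
                                 L_A = 6, L_B = 6, n_coupled = 3,
                                 epsilon = 0.95)
  scr <- scramble_columns(aln, rng_seed = 5)
  expect_equal(dim(scr$A), dim(aln$A))
  expect_identical(rownames(scr$A), rownames(aln$A))
  expect_identical(scr$gold, aln$gold)
  for (j in seq_len(ncol(aln$A)))
    expect_equal(tabulate(scr$A[, j], 21), tabulate(aln$A[, j], 21))
  # single-row alignment is unchanged
  one <- paired_alignment(aln$A[1, , drop = FALSE], aln$B[1, , drop = FALSE],
                          aln$species_A[1], aln$species_B[1])
  expect_identical(scramble_columns(one)$A, one$A)

  # scrambled-column pairwise MI sits at the iid-null level at matched M;
  # each scramble comes from a fresh coupled alignment so replicates are
  # independent on both sides of the two-sample comparison
  spec_c <- synthetic_spec(n_species = 25, pairs_per_species = 4,
                           L_A = 6, L_B = 6, n_coupled = 3, epsilon = 0.95)
  mi_scr <- replicate(20, {
    s <- scramble_columns(generate_alignment(spec_c))
    pairwise_mi(concatenate_pairs(s), 6)
  })
  spec0 <- synthetic_spec(n_species = 1, pairs_per_species = nrow(aln$A),
                          L_A = 6, L_B = 6, n_coupled = 0, epsilon = 0)
  mi_iid <- replicate(20, {
    a0 <- generate_alignment(spec0)
    pairwise_mi(concatenate_pairs(a0), 6)
  })
  # two-sample check: scrambles are statistically indistinguishable from iid
  expect_gt(stats::t.test(mi_scr, mi_iid)$p.value, 0.01)
  # and far below the MI of the intact coupled alignment
  gold_ca <- cbind(aln$A[match(aln$gold$id_A, rownames(aln$A)), ],
                   aln$B[match(aln$gold$id_B, rownames(aln$B)), ])
  expect_lt(mean(mi_scr), pairwise_mi(gold_ca, aln$L_A))
})

test_that("replication fractions aggregate restarts; consensus ranking helps", {
  fake_result <- function(pairs, conf = 1) {
    structure(list(final_pairs = transform(pairs, confidence = conf,
                                           is_training = FALSE)),
              class = "ipa_result")
  }
  g <- data.frame(species = "s", id_A = c("a1", "a2"), id_B = c("b1", "b2"))
  alt <- transform(g, id_B = c("b2", "b1"))
  rt <- replication_fractions(list(fake_result(g), fake_result(g)))
  expect_true(all(rt$fraction %in% c(0, 1)))
  rt2 <- replication_fractions(list(fake_result(g), fake_result(alt)))
  expect_true(all(rt2$fraction == 0.5))  # two replicates disagree on one species

  # real replicates on coupled data: bimodal fractions, consensus TP >= mean TP
  aln <- small_coupled_alignment(seed = 36, n_species = 40, m = 4,
                                 L_A = 10, L_B = 12, n_coupled = 8,
                                 epsilon = 0.9)
  results <- run_ipa_replicates(aln, ipa_options(n_increment = 6,
                                                 rng_seed = 50),
                                n_replicates = 6)
  rt3 <- replication_fractions(results)
  M <- alignment_summary(aln)$n_pairs
  per_rep <- vapply(results, function(r)
    tail(r$trajectory$tp_fraction, 1), numeric(1))
  consensus <- top_m_tp(rt3, M, aln$gold)
  expect_gte(consensus, mean(per_rep) - 0.02)
  # extreme fractions dominate for genuinely coupled families
  expect_gt(mean(rt3$fraction <= 0.1 | rt3$fraction >= 0.9), 0.3)
})

test_that("MI spectra rank planted site pairs first; candidate ranking finds the true partner", {
  spec <- synthetic_spec(n_species = 60, pairs_per_species = 4,
                         L_A = 8, L_B = 8, n_coupled = 3, epsilon = 0.9)
  aln <- filter_and_balance(generate_alignment(spec, rng_seed = 37))
  planted <- attr(generate_alignment(spec, rng_seed = 37), "coupled_sites")
  a_rows <- match(aln$gold$id_A, rownames(aln$A))
  b_rows <- match(aln$gold$id_B, rownames(aln$B))
  fm <- frequency_model(cbind(aln$A[a_rows, ], aln$B[b_rows, ]), aln$L_A)
  sm <- build_score_model(fm, "pmi")
  spectrum <- mi_spectrum(sm, top_k = 3)
  expect_setequal(paste(spectrum$i, spectrum$j),
                  paste(planted[, "i"], planted[, "j"]))
  expect_equal(spectrum$j_concat, spectrum$j + aln$L_A)
  # averaging identical replicates changes nothing
  expect_equal(mi_spectrum(list(sm, sm)), mi_spectrum(sm))

  # orphan-style partner ranking: true partner of a focal A ranks first
  sp <- aln$species_A[a_rows[1]]
  cand <- aln$B[aln$species_B == sp, , drop = FALSE]
  ranking <- rank_candidate_partners(aln$A[a_rows[1], ], cand, sm)
  expect_equal(ranking$id_B[1], aln$gold$id_B[1])
  # zero table: all tied, stable id order
  sm0 <- sm
  sm0$table <- sm$table * 0
  r0 <- rank_candidate_partners(aln$A[a_rows[1], ], cand, sm0)
  expect_equal(r0$id_B, sort(rownames(cand)))
})
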