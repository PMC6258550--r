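test_that("PMI closed forms: independent sites give 0, coupled binary columns give log 2", {
  # independence: frequencies with lambda = 1 factorize exactly
  ca <- matrix(sample.int(21L, 10 * 4, replace = TRUE), 10, 4)
  fm <- frequency_model(ca, 2L, theta = 0, lambda = 1)
  sm <- build_score_model(fm, mode = "pmi")
  expect_true(all(abs(sm$table) < 1e-12))
  expect_true(all(abs(sm$mi) < 1e-12))

  # perfectly coupled two-state columns, lambda = 0:
  # f(1,1) = f(2,2) = 1/2 -> PMI(1,1) = log 2, MI = log 2
  ca2 <- cbind(rep(c(1L, 2L), 8), rep(c(1L, 2L), 8))
  fm2 <- frequency_model(ca2, 1L, theta = 0, lambda = 0,
                         weights = rep(1, 16))
  expect_warning(sm2 <- build_score_model(fm2, mode = "pmi"), "-Inf")
  expect_equal(table_cell(sm2$table, 1, 1, 1, 1), log(2))
  expect_equal(table_cell(sm2$table, 1, 1, 2, 2), log(2))
  expect_equal(sm2$mi[1, 1], log(2))
})

test_that("score tables match brute-force formula evaluation on a 6-row toy CA", {
  set.seed(6)
  ca <- matrix(sample.int(21L, 6 * 5, replace = TRUE), 6, 5)
  L_A <- 2L
  fm <- frequency_model(ca, L_A, theta = 0.3, lambda = 0.15)
  oracle <- oracle_frequencies(ca, L_A, fm$weights, lambda = 0.15)
  for (mode in c("pmi", "npmi", "cov")) {
    sm <- build_score_model(fm, mode = mode)
    for (i in seq_len(L_A))
      for (j in seq_len(5L - L_A))
        for (a in c(ca[1, i], ca[3, i]))
          for (b in c(ca[1, L_A + j], ca[4, L_A + j])) {
            f2 <- oracle$f2[i, j, a, b]
            fi <- oracle$f1[i, a]
            fj <- oracle$f1[L_A + j, b]
            expected <- switch(mode,
              pmi = log(f2 / (fi * fj)),
              npmi = -log(f2 / (fi * fj)) / log(f2),
              cov = f2 - fi * fj)
            expect_equal(table_cell(sm$table, i, j, a, b), expected,
                         tolerance = 1e-12)
          }
    # MI equals sum of f2 * PMI with the same frequencies (internal consistency)
    mi_direct <- sum(oracle$f2[1, 1, , ] *
                       log(oracle$f2[1, 1, , ] /
                             outer(oracle$f1[1, ], oracle$f1[L_A + 1, ])))
    expect_equal(sm$mi[1, 1], mi_direct, tolerance = 1e-12)
  }
})

test_that("pair_score sums exactly the inter-protein table entries selected by the sequences", {
  q <- 21L
  L_A <- 2L
  L_B <- 3L
  set.seed(7)
  tab <- matrix(rnorm(L_A * q * L_B * q), L_A * q, L_B * q)
  sm <- structure(list(table = tab, q = q, L_A = L_A, L_B = L_B),
                  class = "score_model")
  seqA <- c(5L, 20L)
  seqB <- c(1L, 21L, 13L)
  hand <- 0
  for (i in seq_len(L_A))
    for (j in seq_len(L_B))
      hand <- hand + table_cell(tab, i, j, seqA[i], seqB[j])
  expect_equal(pair_score(seqA, seqB, sm), hand)

  # all-zero table and the 1x1 single-cell cases
  sm0 <- sm
  sm0$table <- tab * 0
  expect_equal(pair_score(seqA, seqB, sm0), 0)
  sm1 <- structure(list(table = matrix(3.5, 21, 21), q = q, L_A = 1L, L_B = 1L),
                   class = "score_model")
  expect_equal(pair_score(2L, 9L, sm1), 3.5)

  # the vectorized cross-pair path agrees with pair_score
  matA <- rbind(a1 = c(5L, 20L), a2 = c(1L, 2L))
  matB <- rbind(b1 = seqB, b2 = c(21L, 21L, 21L))
  S <- miipa:::cross_pair_scores(matA, matB, sm)
  for (a in 1:2)
    for (b in 1:2)
      expect_equal(S[a, b], pair_score(matA[a, ], matB[b, ], sm))
})

test_that("assignment_score is the mean pair score and rejects empty assignments", {
  expect_equal(assignment_score(4.2), 4.2)
  expect_equal(assignment_score(c(1, 2, 3, 1, 2, 3)),
               assignment_score(c(1, 2, 3)))  # mean invariance
  expect_error(assignment_score(numeric(0)), "empty")
})

test_that("with unit weights and no pseudocount, S_X over the model's own CA equals the summed MI", {
  aln <- small_coupled_alignment(seed = 10, n_species = 8)
  ca <- cbind(aln$A, aln$B)
  fm <- frequency_model(ca, aln$L_A, theta = 0, lambda = 0)
  suppressWarnings(sm <- build_score_model(fm, mode = "pmi"))
  scores <- vapply(seq_len(nrow(ca)), function(r)
    pair_score(ca[r, seq_len(aln$L_A)], ca[r, -seq_len(aln$L_A)], sm),
    numeric(1))
  expect_equal(assignment_score(scores), sum(mi_matrix(fm)), tolerance = 1e-10)
})

test_that("masking suppresses masked site pairs and the empty mask changes nothing", {
  aln <- small_coupled_alignment(seed = 12, n_species = 6)
  fm <- frequency_model(cbind(aln$A, aln$B), aln$L_A)
  sm <- build_score_model(fm, mode = "pmi")
  sm_empty <- build_score_model(fm, mode = "pmi",
                                mask = matrix(integer(0), 0, 2))
  expect_identical(sm$table, sm_empty$table)
  mask <- rbind(c(1L, 1L), c(3L, 5L))
  sm_masked <- build_score_model(fm, mode = "pmi", mask = mask)
  expect_true(all(sm_masked$table[1:21, 1:21] == 0))
  expect_true(all(sm_masked$table[2 * 21 + 1:21, 4 * 21 + 1:21] == 0))
  # unmasked cells untouched
  expect_identical(sm_masked$table[22:42, 22:42], sm$table[22:42, 22:42])
})

test_that("naive pairwise MI has the right limits and the fit correction extrapolates it away", {
  # two fully coupled uniform columns, the rest independent: MI ~ log 21
  spec <- synthetic_spec(n_species = 1, pairs_per_species = 3000,
                         L_A = 2, L_B = 2, n_coupled = 1, epsilon = 1)
  aln <- generate_alignment(spec, rng_seed = 5)
  ca <- concatenate_pairs(aln)
  mi_naive <- pairwise_mi(ca, 2, correction = "none")
  # one coupled pair at log(21) plus small positive bias from 3 null pairs
  expect_gt(mi_naive, log(21) * 0.97)
  expect_lt(mi_naive, log(21) + 0.5)

  # iid data: naive estimate is pure positive bias; the 1/M fit removes most of it
  spec0 <- synthetic_spec(n_species = 1, pairs_per_species = 2000,
                          L_A = 3, L_B = 3, n_coupled = 0, epsilon = 0)
  ca0 <- with(generate_alignment(spec0, rng_seed = 6), cbind(A, B))
  naive <- pairwise_mi(ca0, 3, correction = "none")
  fitted <- pairwise_mi(ca0, 3, correction = "fit", rng_seed = 6)
  expect_gt(naive, 0)
  expect_lt(abs(fitted), naive / 2)
  expect_error(pairwise_mi(ca0[1:500, ], 3, correction = "fit"), "M < 1000")
  expect_error(pairwise_mi(ca0, 3, correction = "nsb"), "not implemented")
})
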