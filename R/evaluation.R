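# Benchmark statistics: TP fraction and its random baseline, excess shared
# predictions between two algorithms (hypergeometric null), replication
# fractions across stochastic restarts, column scrambling null, MI spectra,
# and candidate-partner ranking for orphan proteins.

#' True-positive fraction of a predicted pairing
#'
#' Fraction of predicted (id_A, id_B) pairs that appear in the gold pairing,
#' over non-excluded pairs.
#'
#' @param predicted data.frame with columns \code{id_A}, \code{id_B} (an
#'   \code{ipa_result} is accepted: its non-training final pairs are used).
#' @param gold data.frame with columns \code{id_A}, \code{id_B}.
#' @param exclude optional data.frame of pairs to exclude (e.g. training
#'   pairs), matched on id_A.
#' @return scalar in [0, 1].
#' @export
tp_fraction <- function(predicted, gold, exclude = NULL) {
  if (inherits(predicted, "ipa_result"))
    predicted <- predicted$final_pairs[!predicted$final_pairs$is_training, ]
  if (!is.null(exclude))
    predicted <- predicted[!predicted$id_A %in% exclude$id_A, , drop = FALSE]
  if (nrow(predicted) == 0L) stop("no predicted pairs to evaluate")
  mean(paste(predicted$id_A, predicted$id_B) %in%
         paste(gold$id_A, gold$id_B))
}

#' Expected TP fraction of random within-species pairings
#'
#' A uniformly random permutation has one fixed point on average regardless
#' of its size, so the expected TP fraction of random within-species
#' pairings is (number of species) / (number of pairs).
#'
#' @param aln a balanced \code{\link{paired_alignment}}.
#' @return scalar expectation.
#' @export
random_pairing_expectation <- function(aln) {
  s <- alignment_summary(aln)
  s$n_species / s$n_pairs
}

#' Monte-Carlo TP fraction of random within-species pairings
#'
#' @param aln a balanced \code{\link{paired_alignment}} with gold pairing.
#' @param n_draws number of random pairings.
#' @param rng_seed optional seed.
#' @return list with \code{mean}, \code{se}, \code{draws}.
#' @export
random_pairing_tp <- function(aln, n_draws = 1000L, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (is.null(aln$gold)) stop("gold pairing required")
  idx <- species_index(aln)
  gold_keys <- paste(aln$gold$id_A, aln$gold$id_B)
  M <- sum(vapply(idx, function(x) min(length(x$A), length(x$B)), 1L))
  draws <- vapply(seq_len(n_draws), function(d) {
    hits <- 0L
    for (s in names(idx)) {
      a <- idx[[s]]$A
      b <- idx[[s]]$B
      m <- min(length(a), length(b))
      bb <- b[sample.int(length(b))][seq_len(m)]
      hits <- hits + sum(paste(rownames(aln$A)[a[seq_len(m)]],
                               rownames(aln$B)[bb]) %in% gold_keys)
    }
    hits / M
  }, numeric(1))
  list(mean = mean(draws), se = stats::sd(draws) / sqrt(n_draws), draws = draws)
}

#' Per-species shared-prediction statistics of two algorithms
#'
#' For each species: m (pairs), p and q (pairs correctly predicted by each
#' algorithm), and k_obs (correct in both).
#'
#' @param pred1,pred2 data.frames with columns \code{species}, \code{id_A},
#'   \code{id_B} (or \code{ipa_result}s); both must cover the same species
#'   partition.
#' @param gold gold pairing data.frame.
#' @return data.frame with columns species, m, p, q, k_obs.
#' @export
shared_prediction_stats <- function(pred1, pred2, gold) {
  get_pairs <- function(x) {
    if (inherits(x, "ipa_result")) x <- x$final_pairs[!x$final_pairs$is_training, ]
    x
  }
  pred1 <- get_pairs(pred1)
  pred2 <- get_pairs(pred2)
  stopifnot(setequal(pred1$species, pred2$species))
  gold_keys <- paste(gold$id_A, gold$id_B)
  sp <- sort(unique(pred1$species))
  do.call(rbind, lapply(sp, function(s) {
    p1 <- pred1[pred1$species == s, ]
    p2 <- pred2[pred2$species == s, ]
    c1 <- p1$id_A[paste(p1$id_A, p1$id_B) %in% gold_keys]
    c2 <- p2$id_A[paste(p2$id_A, p2$id_B) %in% gold_keys]
    data.frame(species = s, m = nrow(p1), p = length(c1), q = length(c2),
               k_obs = length(intersect(c1, c2)), stringsAsFactors = FALSE)
  }))
}

#' Relative excess of shared correct predictions
#'
#' Under the null that two algorithms pick their correct pairs independently
#' within each species, the number of jointly correct pairs follows a
#' hypergeometric law with mean p q / m. The relative excess
#' E = sum(k_obs - pq/m) / sum(min(p, q) - pq/m) is 0 on average for
#' independent predictors and 1 when the shared correct predictions are
#' maximal (in particular for identical predictions).
#'
#' @param stats data.frame as returned by
#'   \code{\link{shared_prediction_stats}} (columns m, p, q, k_obs).
#' @return scalar E, or NA with a warning when the denominator is 0
#'   (degenerate: no species can share fewer than the maximum).
#' @export
excess_shared <- function(stats) {
  expect_k <- stats$p * stats$q / stats$m
  num <- sum(stats$k_obs - expect_k)
  den <- sum(pmin(stats$p, stats$q) - expect_k)
  if (den == 0) {
    warning("degenerate shared-prediction statistics: denominator is 0, E undefined")
    return(NA_real_)
  }
  num / den
}

#' Replication fractions of candidate pairs across IPA replicates
#'
#' For every candidate pair predicted in at least one replicate, the fraction
#' of replicates in which it is predicted, together with its mean confidence
#' (over the replicates predicting it). Each replicate contributes exactly
#' one predicted partner per family-A protein.
#'
#' @param results list of \code{ipa_result} differing only by seed.
#' @return data.frame (species, id_A, id_B, fraction, mean_confidence),
#'   sorted by decreasing fraction (ties: decreasing mean confidence, then
#'   species/id order).
#' @export
replication_fractions <- function(results) {
  stopifnot(length(results) >= 2L)
  all_pairs <- do.call(rbind, lapply(results, function(r) {
    fp <- r$final_pairs[!r$final_pairs$is_training, ]
    fp[, c("species", "id_A", "id_B", "confidence")]
  }))
  key <- paste(all_pairs$species, all_pairs$id_A, all_pairs$id_B, sep = "\t")
  agg <- do.call(rbind, lapply(split(seq_along(key), key), function(rows) {
    data.frame(species = all_pairs$species[rows[1L]],
               id_A = all_pairs$id_A[rows[1L]],
               id_B = all_pairs$id_B[rows[1L]],
               fraction = length(rows) / length(results),
               mean_confidence = mean(all_pairs$confidence[rows]),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(-agg$fraction, -agg$mean_confidence, agg$species,
                   agg$id_A), ]
  rownames(agg) <- NULL
  agg
}

#' TP fraction among the top-ranked pairs of a replication table
#'
#' Takes the \code{m} candidate pairs with the highest replication fraction
#' (ties broken by mean confidence, then species/id order -- already the sort
#' order of \code{\link{replication_fractions}}) and returns their TP
#' fraction: the consensus-over-restarts prediction.
#'
#' @param rt data.frame from \code{\link{replication_fractions}}.
#' @param m number of top pairs to keep (typically the dataset size M).
#' @param gold gold pairing data.frame.
#' @return scalar TP fraction.
#' @export
top_m_tp <- function(rt, m, gold) {
  top <- head(rt, m)
  tp_fraction(top, gold)
}

#' Scramble each alignment column independently
#'
#' Every column of both family blocks is independently permuted across all
#' rows, destroying inter-sequence correlations while preserving one-site
#' frequencies exactly. Species labels and the gold pairing are untouched;
#' this is the null model for interaction signatures.
#'
#' @param aln a \code{\link{paired_alignment}}.
#' @param rng_seed optional seed.
#' @return scrambled \code{paired_alignment}.
#' @export
scramble_columns <- function(aln, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  scr <- function(mat) {
    out <- apply(mat, 2L, function(col) col[sample.int(length(col))])
    if (!is.matrix(out)) out <- matrix(out, nrow = nrow(mat))  # 1-row case
    rownames(out) <- rownames(mat)
    out
  }
  paired_alignment(scr(aln$A), scr(aln$B), aln$species_A, aln$species_B,
                   gold = aln$gold)
}

#' Averaged inter-protein MI spectrum over replicates
#'
#' Averages the per-site-pair MI matrices of one or more score models (e.g.
#' from the final iterations of IPA replicates) and returns the ranked list
#' of site pairs by decreasing MI. Interacting family pairs show
#' substantially larger top values than non-interacting ones.
#'
#' @param models a \code{score_model}, an MI matrix, or a list of either.
#' @param top_k number of top pairs to return (default: all).
#' @return data.frame as in \code{\link{ranked_mi_pairs}}.
#' @export
mi_spectrum <- function(models, top_k = NULL) {
  if (inherits(models, "score_model") || is.matrix(models))
    models <- list(models)
  mats <- lapply(models, function(m) if (inherits(m, "score_model")) m$mi else m)
  avg <- Reduce(`+`, mats) / length(mats)
  ranked_mi_pairs(avg, top_k = top_k)
}

#' Rank candidate partners of a focal protein
#'
#' Scores the focal family-A sequence against every candidate family-B
#' sequence (e.g. all members of one species, for orphan or crosstalk
#' analysis) with a trained score model, and ranks them by decreasing score.
#' Ties are broken by id order, stably.
#'
#' @param seqA integer state vector (length L_A) of the focal protein.
#' @param candidates_B integer matrix of candidate B sequences (rownames:
#'   ids).
#' @param sm a \code{\link{build_score_model}} result.
#' @return data.frame (id_B, score, rank) sorted by decreasing score.
#' @export
rank_candidate_partners <- function(seqA, candidates_B, sm) {
  scores <- vapply(seq_len(nrow(candidates_B)), function(b)
    pair_score(seqA, candidates_B[b, ], sm), numeric(1))
  ids <- rownames(candidates_B)
  ord <- order(-scores, ids)
  data.frame(id_B = ids[ord], score = scores[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Monte-Carlo null for the excess shared predictions statistic
#'
#' Simulates two independent predictors: per species, given m and the
#' marginal correct counts p and q, draws k from the hypergeometric null and
#' recomputes E. Used to verify that E is centered on 0 for independent
#' predictors.
#'
#' @param stats data.frame with columns m, p, q (k_obs is ignored).
#' @param n_sims number of simulated datasets.
#' @param rng_seed optional seed.
#' @return list with \code{mean}, \code{se}, \code{values}.
#' @export
excess_shared_null <- function(stats, n_sims = 1000L, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  vals <- vapply(seq_len(n_sims), function(i) {
    sim <- stats
    sim$k_obs <- rhyper(nrow(stats), m = stats$q, n = stats$m - stats$q,
                        k = stats$p)
    excess_shared(sim)
  }, numeric(1))
  list(mean = mean(vals), se = stats::sd(vals) / sqrt(n_sims), values = vals)
}
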