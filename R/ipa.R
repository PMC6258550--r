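# The iterative pairing algorithm (IPA): initialize a concatenated alignment
# (CA), score all within-species candidate pairs, assign one-to-one partners
# per species, rank assigned pairs by confidence, grow the CA with the top
# pairs, and repeat until every protein is paired.

#' Options of an IPA run
#'
#' @param mode scoring mode: \code{"mi"} (PMI scores, the main algorithm),
#'   \code{"npmi"}, \code{"cov"}, or \code{"dca"} (mean-field effective
#'   interaction energies).
#' @param n_start number of gold training pairs placed permanently in the CA
#'   (0 = no training set: the first CA is one uniformly random
#'   within-species pairing of the whole dataset).
#' @param n_increment number of additional pairs entering the CA per
#'   iteration; at iteration n > 1 the CA holds the training pairs plus the
#'   (n - 1) * n_increment assigned pairs with the highest confidences.
#' @param theta sequence-weighting neighbor threshold; defaults to 0.15
#'   (0.3 in dca mode).
#' @param lambda pseudocount weight; defaults to 0.15 (0.5 in dca mode).
#' @param assignment \code{"hungarian"} (exact; default except in dca mode)
#'   or \code{"greedy"} (default in dca mode, mirroring the historical
#'   energy-based variant).
#' @param rng_seed optional integer seed for all stochastic choices of the
#'   run (initial pairing, training-pair draw).
#' @param mask optional two-column matrix of family-local site pairs whose
#'   score contributions are suppressed (e.g. structural contacts).
#' @return list of class \code{ipa_options}.
#' @export
ipa_options <- function(mode = c("mi", "npmi", "cov", "dca"),
                        n_start = 0L, n_increment = 6L,
                        theta = NULL, lambda = NULL,
                        assignment = NULL, rng_seed = NULL, mask = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_start >= 0L, n_increment >= 1L)
  if (is.null(theta)) theta <- if (mode == "dca") 0.3 else 0.15
  if (is.null(lambda)) lambda <- if (mode == "dca") 0.5 else 0.15
  if (is.null(assignment)) assignment <- if (mode == "dca") "greedy" else "hungarian"
  assignment <- match.arg(assignment, c("hungarian", "greedy"))
  structure(list(mode = mode, n_start = as.integer(n_start),
                 n_increment = as.integer(n_increment),
                 theta = theta, lambda = lambda, assignment = assignment,
                 rng_seed = rng_seed, mask = mask),
            class = "ipa_options")
}

# score-model mode string for an options object
#' @keywords internal
score_mode <- function(options) {
  switch(options$mode, mi = "pmi", npmi = "npmi", cov = "cov", dca = "dca")
}

#' Initialize the concatenated alignment of the first IPA iteration
#'
#' With a training set (\code{n_start > 0}), the CA consists of
#' \code{n_start} gold pairs drawn reproducibly at random. Without one, every
#' protein A is paired with a uniformly random protein B of its species, so
#' the CA covers the whole dataset and contains on average one correct pair
#' per species.
#'
#' @param aln a filtered, balanced \code{\link{paired_alignment}}.
#' @param options an \code{\link{ipa_options}} (its \code{rng_seed}, when
#'   set, seeds the draw).
#' @return data.frame with columns \code{a_row}, \code{b_row} (row indices
#'   into \code{aln$A} / \code{aln$B}) and \code{species}.
#' @export
initialize_ca <- function(aln, options) {
  if (!is.null(options$rng_seed)) set.seed(options$rng_seed)
  if (options$n_start > 0L) {
    if (is.null(aln$gold)) stop("a training set requires a gold pairing")
    if (options$n_start > nrow(aln$gold))
      stop("n_start exceeds the number of gold pairs")
    sel <- aln$gold[sample.int(nrow(aln$gold), options$n_start), , drop = FALSE]
    data.frame(a_row = match(sel$id_A, rownames(aln$A)),
               b_row = match(sel$id_B, rownames(aln$B)),
               species = sel$species, stringsAsFactors = FALSE)
  } else {
    idx <- species_index(aln)
    do.call(rbind, lapply(names(idx), function(s) {
      a <- idx[[s]]$A
      b <- idx[[s]]$B
      m <- min(length(a), length(b))
      data.frame(a_row = a[seq_len(m)],
                 b_row = b[sample.int(length(b))][seq_len(m)],
                 species = s, stringsAsFactors = FALSE)
    }))
  }
}

#' Run the iterative pairing algorithm
#'
#' Each iteration (1) recomputes the frequency and score models from the
#' current CA, (2) scores every within-species candidate pair of the full
#' dataset, (3) solves the per-species assignment and computes leave-one-out
#' confidences, and (4) rebuilds the CA from the training pairs plus the
#' globally top-confidence assigned pairs. The run terminates at the
#' iteration whose CA would include every assigned pair; the assignment
#' produced from the last scored CA is the result.
#'
#' Training pairs stay in the CA throughout and their proteins are excluded
#' from the assignable pool; reported TP fractions cover non-training pairs
#' only.
#'
#' @param aln a filtered, balanced \code{\link{paired_alignment}} (see
#'   \code{\link{filter_and_balance}}).
#' @param options an \code{\link{ipa_options}}.
#' @param verbose print one line per iteration.
#' @return object of class \code{ipa_result}: \code{final_pairs} (data.frame
#'   species, id_A, id_B, score, confidence, is_training and, when gold is
#'   available, is_correct), \code{trajectory} (data.frame iteration,
#'   ca_size, s_x, tp_fraction), \code{n_iterations}, \code{options}.
#' @export
run_ipa <- function(aln, options = ipa_options(), verbose = FALSE) {
  stopifnot(inherits(aln, "paired_alignment"))
  idx <- species_index(aln)
  bad <- names(idx)[vapply(idx, function(x) length(x$A) != length(x$B), TRUE)]
  if (length(bad))
    stop("unbalanced species (run filter_and_balance first): ",
         paste(head(bad, 3L), collapse = ", "))

  ca <- initialize_ca(aln, options)  # consumes rng_seed if set
  training <- if (options$n_start > 0L) ca else ca[0L, ]
  gold_keys <- if (!is.null(aln$gold))
    paste(aln$gold$id_A, aln$gold$id_B) else NULL

  # assignable pool: everything outside the training pairs, per species
  pool <- lapply(idx, function(x) x)
  if (nrow(training) > 0L) {
    for (s in unique(training$species)) {
      pool[[s]]$A <- setdiff(pool[[s]]$A, training$a_row[training$species == s])
      pool[[s]]$B <- setdiff(pool[[s]]$B, training$b_row[training$species == s])
    }
  }
  pool <- pool[vapply(pool, function(x) length(x$A) > 0L, TRUE)]
  M_assign <- sum(vapply(pool, function(x) length(x$A), 1L))
  if (M_assign == 0L) stop("nothing left to assign outside the training set")

  trajectory <- data.frame()
  n <- 0L
  repeat {
    n <- n + 1L
    ca_mat <- cbind(aln$A[ca$a_row, , drop = FALSE],
                    aln$B[ca$b_row, , drop = FALSE])
    fm <- frequency_model(ca_mat, aln$L_A,
                          theta = options$theta, lambda = options$lambda)
    sm <- build_score_model(fm, mode = score_mode(options),
                            mask = options$mask)
    solver <- if (options$assignment == "hungarian") optimal_assignment
              else greedy_assignment
    assigned <- do.call(rbind, lapply(names(pool), function(s) {
      a <- pool[[s]]$A
      b <- pool[[s]]$B
      S <- cross_pair_scores(aln$A[a, , drop = FALSE],
                             aln$B[b, , drop = FALSE], sm)
      asg <- solver(S)
      conf <- confidence_scores(S, asg, solver = solver)
      data.frame(species = s, a_row = a, b_row = b[asg$cols],
                 score = S[cbind(seq_along(a), asg$cols)],
                 confidence = conf, stringsAsFactors = FALSE)
    }))
    s_x <- assignment_score(assigned$score)
    tp <- if (!is.null(gold_keys)) {
      keys <- paste(rownames(aln$A)[assigned$a_row],
                    rownames(aln$B)[assigned$b_row])
      mean(keys %in% gold_keys)
    } else NA_real_
    trajectory <- rbind(trajectory,
                        data.frame(iteration = n, ca_size = nrow(ca),
                                   s_x = s_x, tp_fraction = tp))
    if (verbose)
      message(sprintf("iteration %d: CA size %d, S_X = %.4f, TP = %s",
                      n, nrow(ca), s_x,
                      if (is.na(tp)) "NA" else sprintf("%.3f", tp)))
    if (n * options$n_increment >= M_assign) {
      # next CA would contain every assigned pair: final iteration
      n <- n + 1L
      break
    }
    ranked <- rank_predictions(assigned)
    top <- ranked[seq_len(min(n * options$n_increment, M_assign)), ]
    ca <- rbind(training,
                top[, c("a_row", "b_row", "species"), drop = FALSE])
  }

  final <- rank_predictions(assigned)
  final_pairs <- data.frame(species = final$species,
                            id_A = rownames(aln$A)[final$a_row],
                            id_B = rownames(aln$B)[final$b_row],
                            score = final$score,
                            confidence = final$confidence,
                            is_training = FALSE,
                            stringsAsFactors = FALSE)
  if (nrow(training) > 0L) {
    tr <- data.frame(species = training$species,
                     id_A = rownames(aln$A)[training$a_row],
                     id_B = rownames(aln$B)[training$b_row],
                     score = NA_real_, confidence = NA_real_,
                     is_training = TRUE, stringsAsFactors = FALSE)
    final_pairs <- rbind(final_pairs, tr)
  }
  if (!is.null(gold_keys))
    final_pairs$is_correct <- paste(final_pairs$id_A, final_pairs$id_B) %in%
      gold_keys
  structure(list(final_pairs = final_pairs, trajectory = trajectory,
                 n_iterations = n, options = options),
            class = "ipa_result")
}

#' Rank assigned pairs by decreasing confidence
#'
#' Global descending sort of the per-species assigned pairs by confidence;
#' +Inf sentinels (singleton species) sort first; ties are broken by species
#' then family-A row for determinism.
#'
#' @param assigned data.frame with at least columns \code{confidence},
#'   \code{species}, \code{a_row}.
#' @return the same data.frame, reordered.
#' @export
rank_predictions <- function(assigned) {
  out <- assigned[order(-assigned$confidence, assigned$species,
                        assigned$a_row), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.ipa_result <- function(x, ...) {
  last <- x$trajectory[nrow(x$trajectory), ]
  cat(sprintf("ipa_result (%s, %s): %d iterations, %d predicted pairs\n",
              x$options$mode, x$options$assignment, x$n_iterations,
              sum(!x$final_pairs$is_training)))
  cat(sprintf("  final S_X = %.4f%s\n", last$s_x,
              if (!is.na(last$tp_fraction))
                sprintf(", final TP fraction = %.3f", last$tp_fraction)
              else ""))
  invisible(x)
}

#' Run several IPA replicates differing only by seed
#'
#' @param aln a balanced \code{\link{paired_alignment}}.
#' @param options an \code{\link{ipa_options}}; its \code{rng_seed} is the
#'   base seed, replicate r uses base + r - 1.
#' @param n_replicates number of replicates.
#' @param verbose print per-iteration progress.
#' @return list of \code{ipa_result}.
#' @export
run_ipa_replicates <- function(aln, options = ipa_options(),
                               n_replicates = 2L, verbose = FALSE) {
  base <- if (is.null(options$rng_seed)) 1L else options$rng_seed
  lapply(seq_len(n_replicates), function(r) {
    opts <- options
    opts$rng_seed <- base + r - 1L
    run_ipa(aln, opts, verbose = verbose)
  })
}
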