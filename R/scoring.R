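# Score tables over inter-protein site pairs (PMI / normalized PMI /
# covariance / mean-field DCA couplings), per-site-pair mutual information,
# and scores of candidate protein pairs and whole assignments.

#' Build a score model from a frequency model
#'
#' For every inter-protein site pair (i, j) and state pair (alpha, beta) the
#' table holds, depending on \code{mode}:
#' \describe{
#'   \item{pmi}{log[ f_ij(a,b) / (f_i(a) f_j(b)) ], corrected frequencies.}
#'   \item{npmi}{-PMI_ij(a,b) / log f_ij(a,b).}
#'   \item{cov}{f_ij(a,b) - f_i(a) f_j(b).}
#'   \item{dca}{mean-field direct couplings e_ij(a,b) (see
#'     \code{\link{fit_mf_dca}}); summing them gives minus the effective
#'     interaction energy, so maximizing the pair score minimizes energy.}
#' }
#' The per-site-pair mutual information MI_ij is always computed from the same
#' corrected frequencies. With \code{lambda = 0} a zero joint frequency yields
#' a -Inf PMI cell (with a warning naming the first such cell); such cells are
#' never visited when scoring rows of the CA the model was built from.
#'
#' @param fm a \code{\link{frequency_model}}.
#' @param mode one of "pmi", "npmi", "cov", "dca".
#' @param mask optional two-column matrix/data.frame of family-local site
#'   pairs (i in 1..L_A, j in 1..L_B) whose contributions are suppressed
#'   (table entries set to 0), e.g. structural contacts.
#' @return object of class \code{score_model}: \code{table} ((L_A q) x
#'   (L_B q)), \code{mi} (L_A x L_B), plus bookkeeping fields.
#' @export
build_score_model <- function(fm, mode = c("pmi", "npmi", "cov", "dca"),
                              mask = NULL) {
  mode <- match.arg(mode)
  q <- fm$q
  # outer product of corrected one-site marginals, matching f2's layout
  pA <- as.vector(t(fm$f1[seq_len(fm$L_A), , drop = FALSE]))        # (i-1)q+a
  pB <- as.vector(t(fm$f1[fm$L_A + seq_len(fm$L_B), , drop = FALSE]))
  prod_marg <- outer(pA, pB)
  tab <- switch(mode,
    pmi = ,
    npmi = {
      if (fm$lambda == 0 && any(fm$f2 == 0)) {
        z <- which(fm$f2 == 0, arr.ind = TRUE)[1L, ]
        warning(sprintf(
          "lambda = 0 with zero joint frequency (site pair i=%d, j=%d, states %d/%d): PMI is -Inf there",
          (z[1L] - 1L) %/% q + 1L, (z[2L] - 1L) %/% q + 1L,
          (z[1L] - 1L) %% q + 1L, (z[2L] - 1L) %% q + 1L))
      }
      pmi <- log(fm$f2) - log(prod_marg)
      if (mode == "npmi") -pmi / log(fm$f2) else pmi
    },
    cov = fm$f2 - prod_marg,
    dca = {
      dca <- fit_mf_dca(fm)
      dca$table
    })
  mi <- mi_matrix(fm)
  if (!is.null(mask)) {
    mask <- as.matrix(mask)[, 1:2, drop = FALSE]
    stopifnot(all(mask[, 1L] >= 1L), all(mask[, 1L] <= fm$L_A),
              all(mask[, 2L] >= 1L), all(mask[, 2L] <= fm$L_B))
    for (k in seq_len(nrow(mask))) {
      rows <- (mask[k, 1L] - 1L) * q + seq_len(q)
      cols <- (mask[k, 2L] - 1L) * q + seq_len(q)
      tab[rows, cols] <- 0
    }
  }
  structure(list(table = tab, mi = mi, mode = mode, mask = mask,
                 q = q, L_A = fm$L_A, L_B = fm$L_B,
                 lambda = fm$lambda, theta = fm$theta),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("score_model (%s): %d x %d inter-protein site pairs, %s\n",
              x$mode, x$L_A, x$L_B,
              if (is.null(x$mask)) "no mask"
              else sprintf("%d masked pairs", nrow(x$mask))))
  invisible(x)
}

#' Per-site-pair mutual information of a frequency model
#'
#' MI_ij = sum over states of f_ij log[f_ij / (f_i f_j)], in nats, using the
#' model's (corrected) frequencies; zero joint cells contribute 0.
#'
#' @param fm a \code{\link{frequency_model}}.
#' @return L_A x L_B matrix of MI values.
#' @export
mi_matrix <- function(fm) {
  q <- fm$q
  pA <- as.vector(t(fm$f1[seq_len(fm$L_A), , drop = FALSE]))
  pB <- as.vector(t(fm$f1[fm$L_A + seq_len(fm$L_B), , drop = FALSE]))
  terms <- fm$f2 * (log(fm$f2) - log(outer(pA, pB)))
  terms[fm$f2 == 0] <- 0
  # collapse q x q state blocks to site pairs
  block_sum(terms, q)
}

# sum q x q blocks of a (m*q) x (n*q) matrix -> m x n
#' @keywords internal
block_sum <- function(x, q) {
  m <- nrow(x) / q
  n <- ncol(x) / q
  grp_r <- rep(seq_len(m), each = q)
  grp_c <- rep(seq_len(n), each = q)
  rs <- rowsum(x, grp_r)                       # m*q? no: (m) x (n*q)
  t(rowsum(t(rs), grp_c))
}

#' Pairing score of one candidate protein pair
#'
#' The score S_AB of a concatenated candidate sequence is the sum of the
#' score-table entries of all inter-protein site pairs (masked pairs
#' contribute 0 because their entries are zeroed).
#'
#' @param seqA,seqB integer state vectors of lengths L_A and L_B.
#' @param sm a \code{\link{build_score_model}} result.
#' @return scalar score (nats for PMI mode).
#' @export
pair_score <- function(seqA, seqB, sm) {
  stopifnot(length(seqA) == sm$L_A, length(seqB) == sm$L_B)
  rows <- (seq_len(sm$L_A) - 1L) * sm$q + seqA
  cols <- (seq_len(sm$L_B) - 1L) * sm$q + seqB
  sum(sm$table[rows, cols])
}

# score matrix for all cross pairs between rows of matA and rows of matB
# (used per species); exploits precomputed profiles P = rowsum over A sites
#' @keywords internal
cross_pair_scores <- function(matA, matB, sm) {
  mA <- nrow(matA)
  mB <- nrow(matB)
  S <- matrix(0, mA, mB, dimnames = list(rownames(matA), rownames(matB)))
  colsB <- t((t(matB) + (seq_len(sm$L_B) - 1L) * sm$q))  # mB x L_B col indices
  for (a in seq_len(mA)) {
    rows <- (seq_len(sm$L_A) - 1L) * sm$q + matA[a, ]
    Ta <- sm$table[rows, , drop = FALSE]
    prof <- colSums(Ta)                                  # length L_B * q
    S[a, ] <- rowSums(matrix(prof[colsB], nrow = mB))
  }
  S
}

#' Mean pairing score of an assignment
#'
#' S_X = (1/M') sum of S_AB over the assigned pairs; with uniform weights and
#' no pseudocount, scoring the very CA used to build a PMI model gives
#' S_X = sum over inter-protein site pairs of MI_ij.
#'
#' @param pair_scores numeric vector of S_AB values of the assigned pairs.
#' @return scalar mean score.
#' @export
assignment_score <- function(pair_scores) {
  if (length(pair_scores) == 0L) stop("empty assignment")
  mean(pair_scores)
}

#' Naive and finite-size-corrected pairwise mutual information
#'
#' The pairwise MI of a concatenated alignment is the sum of MI_ij over all
#' inter-protein site pairs, estimated from empirical frequencies without
#' weighting or pseudocounts. The naive estimator carries a positive
#' finite-size bias with leading order K/M; \code{correction = "fit"} removes
#' it by subsampling the alignment at several depths, fitting a degree-3
#' polynomial in 1/M through the naive estimates, and reporting the
#' intercept. The fit is refused for M < 1000, where subleading corrections
#' dominate and polynomial extrapolation is unreliable. An \code{"nsb"}
#' correction hook is reserved but not implemented.
#'
#' @param ca integer matrix (M x L).
#' @param L_A width of the family-A block.
#' @param correction "none" (default), "fit", or "nsb" (not implemented).
#' @param degree polynomial degree for the fit correction.
#' @param n_depths number of subsampling depths (spread evenly in 1/M between
#'   M and M/3).
#' @param n_reps independent subsample draws averaged per depth (reduces the
#'   variance of the extrapolated intercept).
#' @param rng_seed optional seed for the subsampling draws.
#' @return scalar pairwise MI in nats.
#' @export
pairwise_mi <- function(ca, L_A, correction = c("none", "fit", "nsb"),
                        degree = 3L, n_depths = 10L, n_reps = 3L,
                        rng_seed = NULL) {
  correction <- match.arg(correction)
  stopifnot(is.matrix(ca), nrow(ca) >= 2L)
  naive <- function(rows) {
    fm <- frequency_model(ca[rows, , drop = FALSE], L_A,
                          theta = 0, lambda = 0,
                          weights = rep(1, length(rows)))
    sum(mi_matrix(fm))
  }
  if (correction == "none") return(naive(seq_len(nrow(ca))))
  if (correction == "nsb")
    stop("NSB entropy correction is not implemented (reserved hook)")
  M <- nrow(ca)
  if (M < 1000L)
    stop("fit correction refused: M < 1000, polynomial extrapolation in 1/M is unreliable there")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  inv_m <- seq(1 / M, 3 / M, length.out = n_depths)
  sizes <- round(1 / inv_m)
  est <- vapply(sizes, function(m) {
    if (m == M) return(naive(seq_len(M)))
    mean(vapply(seq_len(n_reps), function(r) naive(sample.int(M, m)),
                numeric(1)))
  }, numeric(1))
  fit <- lm(est ~ poly(1 / sizes, degree = degree, raw = TRUE))
  unname(coef(fit)[1L])
}

#' Export ranked inter-protein MI site pairs
#'
#' @param mi L_A x L_B MI matrix (or a \code{score_model}).
#' @param top_k number of top pairs to keep (default: all).
#' @return data.frame with family-local 1-based site indices \code{i} and
#'   \code{j}, concatenated-coordinate indices, and \code{mi}, sorted by
#'   decreasing MI (ties: by i then j).
#' @export
ranked_mi_pairs <- function(mi, top_k = NULL) {
  if (inherits(mi, "score_model")) mi <- mi$mi
  df <- data.frame(i = as.vector(row(mi)), j = as.vector(col(mi)),
                   mi = as.vector(mi))
  df$i_concat <- df$i
  df$j_concat <- df$j + nrow(mi)
  df <- df[order(-df$mi, df$i, df$j), c("i", "j", "i_concat", "j_concat", "mi")]
  rownames(df) <- NULL
  if (!is.null(top_k)) df <- head(df, top_k)
  df
}
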