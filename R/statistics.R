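# Similarity-weighted, pseudocounted one- and two-site frequencies of a
# concatenated alignment. A concatenated alignment (CA) is an integer matrix
# of M rows and L = L_A + L_B sites, states 1..21.

# sparse one-hot encoding: M x (L*q), column (i-1)*q + alpha
#' @keywords internal
one_hot <- function(mat, q = N_STATES) {
  M <- nrow(mat)
  L <- ncol(mat)
  j <- as.integer(t((col(mat) - 1L) * q + mat))  # row-major per sequence
  i <- rep(seq_len(M), each = L)
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(M, L * q))
}

#' Similarity weights and effective sequence count of a CA
#'
#' Each row a receives weight 1/m_a, where m_a is the number of rows (a
#' itself included) whose mean per-site Hamming distance to a is strictly
#' below \code{theta}. Distances are computed on the full concatenated rows,
#' gaps counted as an ordinary 21st state. M_eff is the sum of the weights.
#'
#' @param ca integer matrix (M x L), states 1..21.
#' @param theta neighbor threshold in [0, 1]; \code{theta = 0} yields unit
#'   weights (no row is strictly closer than 0 to another unless identical --
#'   identical rows have distance 0 which is not < 0, so all weights are 1).
#' @return list with \code{weights} (length M) and \code{M_eff}.
#' @export
sequence_weights <- function(ca, theta) {
  stopifnot(is.matrix(ca), theta >= 0, theta <= 1)
  M <- nrow(ca)
  L <- ncol(ca)
  if (M == 1L) return(list(weights = 1, M_eff = 1))
  X <- one_hot(ca)
  matches <- as.matrix(Matrix::tcrossprod(X))   # shared-state counts
  d <- 1 - matches / L                          # mean per-site Hamming distance
  m_a <- pmax(rowSums(d < theta), 1)  # theta = 0: nothing is a neighbor, unit weights
  w <- 1 / m_a
  list(weights = w, M_eff = sum(w))
}

#' Weighted, pseudocounted frequency model of a concatenated alignment
#'
#' Raw frequencies are weighted counts divided by M_eff. The pseudocount
#' mixes them with the uniform distribution: corrected one-site frequencies
#' are lambda/q + (1-lambda) f_i(alpha); corrected two-site frequencies for
#' distinct sites are lambda/q^2 + (1-lambda) f_ij(alpha, beta). Only
#' inter-protein site pairs (i in A, j in B) are tabulated in \code{f2}; the
#' diagonal identity f_ii(alpha, beta) = f_i(alpha) delta_ab is implicit.
#'
#' @param ca integer matrix (M x L = L_A + L_B).
#' @param L_A width of the family-A block (first L_A columns).
#' @param theta neighbor-distance threshold for sequence weighting.
#' @param lambda pseudocount weight in [0, 1].
#' @param weights optional precomputed weights (skips \code{sequence_weights}).
#' @return object of class \code{frequency_model}: \code{f1} (L x q corrected
#'   one-site frequencies), \code{f2} ((L_A q) x (L_B q) corrected
#'   inter-protein two-site frequencies, row (i-1)q+alpha, column
#'   (j-1)q+beta), \code{f1_raw}, \code{weights}, \code{M_eff}, \code{q},
#'   \code{lambda}, \code{theta}, \code{L_A}, \code{L_B}, \code{M}, and the
#'   one-hot matrix \code{X} retained for downstream reuse (DCA).
#' @export
frequency_model <- function(ca, L_A, theta = 0.15, lambda = 0.15,
                            weights = NULL) {
  stopifnot(is.matrix(ca), nrow(ca) >= 1L, L_A >= 1L, L_A < ncol(ca),
            lambda >= 0, lambda <= 1)
  q <- N_STATES
  L <- ncol(ca)
  L_B <- L - L_A
  if (is.null(weights)) {
    sw <- sequence_weights(ca, theta)
    weights <- sw$weights
    M_eff <- sw$M_eff
  } else {
    M_eff <- sum(weights)
  }
  X <- one_hot(ca)
  f1_raw <- matrix(as.numeric(Matrix::colSums(X * weights)) / M_eff,
                   nrow = L, ncol = q, byrow = TRUE)
  cols_A <- seq_len(L_A * q)
  cols_B <- L_A * q + seq_len(L_B * q)
  f2_raw <- as.matrix(Matrix::crossprod(X[, cols_A, drop = FALSE] * weights,
                                        X[, cols_B, drop = FALSE])) / M_eff
  f1 <- lambda / q + (1 - lambda) * f1_raw
  f2 <- lambda / q^2 + (1 - lambda) * f2_raw
  structure(list(f1 = f1, f2 = f2, f1_raw = f1_raw,
                 weights = weights, M_eff = M_eff,
                 q = q, lambda = lambda, theta = theta,
                 L_A = L_A, L_B = L_B, L = L, M = nrow(ca), X = X),
            class = "frequency_model")
}

#' @export
print.frequency_model <- function(x, ...) {
  cat(sprintf("frequency_model: M = %d, M_eff = %.2f, L = %d (%d + %d), lambda = %g, theta = %g\n",
              x$M, x$M_eff, x$L, x$L_A, x$L_B, x$lambda, x$theta))
  invisible(x)
}

# corrected two-site frequencies over *all* site pairs, reduced to q-1 states
# per site (gap dropped); used by the mean-field DCA comparator. Returns the
# (L*(q-1)) x (L*(q-1)) matrix of corrected f_ij(alpha, beta) with the Eq-12
# diagonal convention f_ii(alpha, beta) = f_i(alpha) delta_ab.
#' @keywords internal
full_pair_frequencies_reduced <- function(fm) {
  q <- fm$q
  L <- fm$L
  keep <- as.vector(outer(seq_len(q - 1L), (seq_len(L) - 1L) * q, `+`))
  Xr <- fm$X[, keep, drop = FALSE]
  f2_raw <- as.matrix(Matrix::crossprod(Xr * fm$weights, Xr)) / fm$M_eff
  f2 <- fm$lambda / q^2 + (1 - fm$lambda) * f2_raw
  # overwrite diagonal site blocks with the one-site convention
  f1r <- fm$f1[, seq_len(q - 1L), drop = FALSE]  # corrected, states 1..q-1
  for (i in seq_len(L)) {
    rows <- (i - 1L) * (q - 1L) + seq_len(q - 1L)
    f2[rows, rows] <- diag(f1r[i, ], nrow = q - 1L)
  }
  f2
}
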