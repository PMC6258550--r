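# Mean-field direct coupling analysis comparator: infer pairwise couplings
# from the CA by inverting the regularized covariance matrix, and score
# candidate pairs by effective interaction energy.

#' Fit a mean-field DCA model
#'
#' Builds the covariance matrix C_ij(a, b) = f_ij(a, b) - f_i(a) f_j(b) over
#' all sites of the concatenated alignment in the reduced-state convention
#' (the gap state is dropped, leaving q - 1 = 20 states per site, the
#' standard mean-field gauge choice), inverts it, and keeps the couplings
#' e = -C^{-1} restricted to the inter-protein blocks. The pseudocount in the
#' frequency model regularizes C so the inversion succeeds; the conventional
#' comparator parameterization is theta = 0.3, lambda = 0.5.
#'
#' @param fm a \code{\link{frequency_model}} (lambda > 0 required).
#' @return object of class \code{dca_model}: \code{table} ((L_A q) x (L_B q)
#'   couplings, zero at gap states, same layout as a score model table),
#'   \code{frobenius} (L_A x L_B per-site-pair coupling norms over the
#'   reduced-state block), \code{theta}, \code{lambda}.
#' @export
fit_mf_dca <- function(fm) {
  if (fm$lambda <= 0)
    stop("mean-field DCA requires a positive pseudocount (lambda > 0) to regularize the covariance matrix")
  q <- fm$q
  qr_ <- q - 1L
  L <- fm$L
  f2 <- full_pair_frequencies_reduced(fm)
  f1r <- as.vector(t(fm$f1[, seq_len(qr_), drop = FALSE]))  # (i-1)(q-1)+a
  C <- f2 - outer(f1r, f1r)
  inv <- tryCatch(solve(C), error = function(e) {
    stop(sprintf("covariance matrix is singular despite the pseudocount (lambda = %g, reciprocal condition estimate %.3g): %s",
                 fm$lambda, rcond(C), conditionMessage(e)))
  })
  e_red <- -inv[seq_len(fm$L_A * qr_),
                fm$L_A * qr_ + seq_len(fm$L_B * qr_), drop = FALSE]
  # expand to q states per site with zeros at the gap state
  keepA <- as.vector(outer(seq_len(qr_), (seq_len(fm$L_A) - 1L) * q, `+`))
  keepB <- as.vector(outer(seq_len(qr_), (seq_len(fm$L_B) - 1L) * q, `+`))
  tab <- matrix(0, fm$L_A * q, fm$L_B * q)
  tab[keepA, keepB] <- e_red
  frob <- sqrt(block_sum(tab^2, q))
  structure(list(table = tab, frobenius = frob,
                 theta = fm$theta, lambda = fm$lambda,
                 L_A = fm$L_A, L_B = fm$L_B, q = q),
            class = "dca_model")
}

#' @export
print.dca_model <- function(x, ...) {
  cat(sprintf("dca_model: %d x %d inter-protein site pairs (theta = %g, lambda = %g)\n",
              x$L_A, x$L_B, x$theta, x$lambda))
  invisible(x)
}

#' Effective interaction energy of a candidate pair
#'
#' E_AB = - sum over inter-protein site pairs of e_ij(alpha_i, beta_j); lower
#' energy means a better pair (gauge offsets cancel within a species, so
#' only energy differences matter for assignment).
#'
#' @param seqA,seqB integer state vectors of lengths L_A and L_B.
#' @param model a \code{\link{fit_mf_dca}} result.
#' @return scalar energy.
#' @export
interaction_energy <- function(seqA, seqB, model) {
  stopifnot(length(seqA) == model$L_A, length(seqB) == model$L_B)
  rows <- (seq_len(model$L_A) - 1L) * model$q + seqA
  cols <- (seq_len(model$L_B) - 1L) * model$q + seqB
  -sum(model$table[rows, cols])
}
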