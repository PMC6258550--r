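# Within-species one-to-one assignment: exact Hungarian solver, greedy
# alternative, and leave-one-out confidence scores.

# O(n^3) Hungarian algorithm (potentials + augmenting paths) for *minimum*
# total cost on a square finite matrix. Returns col assigned to each row.
#' @keywords internal
hungarian_min <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  u <- numeric(n)          # row potentials
  v <- numeric(n)          # column potentials
  p <- integer(n)          # p[j]: row matched to column j (0 = free)
  for (i in seq_len(n)) {
    links <- integer(n)    # predecessor column on the alternating path
    minv <- rep(Inf, n)
    used <- rep(FALSE, n)
    j0 <- 0L               # virtual start column, matched to row i
    i0 <- i
    repeat {
      cur <- cost[i0, ] - u[i0] - v
      better <- !used & cur < minv
      minv[better] <- cur[better]
      links[better] <- j0
      free <- which(!used)
      jf <- free[which.min(minv[free])]
      delta <- minv[jf]
      u[i] <- u[i] + delta
      usedj <- which(used)
      if (length(usedj)) {
        u[p[usedj]] <- u[p[usedj]] + delta
        v[usedj] <- v[usedj] - delta
      }
      minv[free] <- minv[free] - delta
      j0 <- jf
      used[j0] <- TRUE
      if (p[j0] == 0L) break
      i0 <- p[j0]
    }
    repeat {               # augment along the stored path
      j1 <- links[j0]
      p[j0] <- if (j1 == 0L) i else p[j1]
      if (j1 == 0L) break
      j0 <- j1
    }
  }
  match_col <- integer(n)
  match_col[p] <- seq_len(n)
  match_col
}

# deterministic tie-break: an infinitesimal lexicographic (row, col)
# perturbation, consistently applied, so equal-score optima resolve the same
# way on every platform. The perturbation is far below score resolution and
# totals are always reported on the unperturbed matrix.
#' @keywords internal
tie_perturbation <- function(n, scale) {
  eps <- scale * 1e-9 / (n * n + n + 1)
  outer(seq_len(n), seq_len(n), function(i, j) eps * (i * n + j))
}

#' Exact maximum-score assignment within a species
#'
#' Solves the square assignment problem exactly with the Hungarian algorithm:
#' picks one entry per row and per column of the score matrix such that the
#' total is maximal. Ties are broken deterministically by lexicographic
#' (row, column) order.
#'
#' @param S square numeric score matrix (rows: family-A members, columns:
#'   family-B members; dimnames carry ids if available). All entries must be
#'   finite.
#' @return object of class \code{assignment}: \code{cols} (column assigned to
#'   each row), \code{total} (sum of assigned scores), \code{method}.
#' @export
optimal_assignment <- function(S) {
  S <- as.matrix(S)
  n <- nrow(S)
  stopifnot(n == ncol(S))
  if (!all(is.finite(S))) stop("non-finite entries in the score matrix")
  if (n == 1L) {
    asg <- list(cols = 1L, total = S[1L, 1L], method = "hungarian")
    class(asg) <- "assignment"
    return(asg)
  }
  scale <- max(abs(range(S)), 1)
  cols <- hungarian_min(-(S + tie_perturbation(n, scale)))
  asg <- list(cols = cols, total = sum(S[cbind(seq_len(n), cols)]),
              method = "hungarian")
  class(asg) <- "assignment"
  asg
}

#' Greedy assignment within a species
#'
#' Iteratively selects the highest remaining score cell (ties broken by
#' lexicographic row, column order), removing its row and column from
#' consideration. Not optimal in general; it is the assignment rule
#' historically paired with DCA energies.
#'
#' @inheritParams optimal_assignment
#' @return an \code{assignment} (see \code{\link{optimal_assignment}}).
#' @export
greedy_assignment <- function(S) {
  S <- as.matrix(S)
  n <- nrow(S)
  stopifnot(n == ncol(S))
  if (!all(is.finite(S))) stop("non-finite entries in the score matrix")
  W <- S
  cols <- integer(n)
  for (k in seq_len(n)) {
    best <- which(W == max(W), arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
    cols[best[1L]] <- best[2L]
    W[best[1L], ] <- -Inf
    W[, best[2L]] <- -Inf
  }
  asg <- list(cols = cols, total = sum(S[cbind(seq_len(n), cols)]),
              method = "greedy")
  class(asg) <- "assignment"
  asg
}

#' @export
print.assignment <- function(x, ...) {
  cat(sprintf("assignment (%s): %d pairs, total score %.6g\n",
              x$method, length(x$cols), x$total))
  invisible(x)
}

#' Leave-one-out confidence scores of an assignment
#'
#' For each assigned pair, the pair's cell is disallowed, the assignment is
#' re-solved, and the confidence is the drop in total score:
#' deltaS = total - constrained total. With the exact solver deltaS >= 0.
#' For a 1x1 species no alternative exists and the confidence is +Inf.
#'
#' @param S square numeric score matrix.
#' @param asg assignment produced from \code{S}.
#' @param solver function used for the re-solve (\code{optimal_assignment}
#'   by default; pass \code{greedy_assignment} to mirror the greedy variant).
#' @return numeric vector of confidences, one per row of \code{S}.
#' @export
confidence_scores <- function(S, asg, solver = optimal_assignment) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (n == 1L) return(Inf)
  # finite penalty large enough that a forbidden cell is never chosen
  penalty <- (n + 1) * (diff(range(S)) + 1)
  vapply(seq_len(n), function(r) {
    S2 <- S
    S2[r, asg$cols[r]] <- min(S) - penalty
    max(asg$total - solver(S2)$total, 0)
  }, numeric(1))
}
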