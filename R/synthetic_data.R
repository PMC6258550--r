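# Synthetic paired alignments with a planted one-to-one within-species
# pairing and tunable inter-protein column correlations, so every pipeline
# stage is testable without external data.

#' Specification of a synthetic paired-alignment benchmark
#'
#' The generator emulates the structure of real two-family benchmark
#' alignments: species blocks of a few to a few dozen pairs, family widths
#' defaulting to the histidine-kinase / response-regulator interaction-domain
#' geometry (64 and 112 columns), 21 states per site, and a planted gold
#' pairing. Statistical dependence between true partners is injected at
#' \code{n_coupled} site pairs (one A column, one B column each; columns are
#' used by at most one coupled pair): for each true pair and each coupled
#' site pair, with probability \code{epsilon} both sites copy a shared latent
#' state drawn from the background, otherwise both are drawn independently.
#'
#' @param n_species number of species.
#' @param pairs_per_species either a single integer (fixed block size) or a
#'   length-2 vector giving an inclusive uniform range.
#' @param L_A,L_B alignment widths of families A and B.
#' @param n_coupled number of coupled inter-protein site pairs (at most
#'   min(L_A, L_B)).
#' @param epsilon coupling strength in [0, 1].
#' @param background "uniform" (default) or "dirichlet" (per-site state
#'   distributions drawn from a symmetric Dirichlet with parameter
#'   \code{dirichlet_alpha}).
#' @param dirichlet_alpha concentration for the Dirichlet background.
#' @param dup_prob probability that a generated pair is a mutated copy of an
#'   earlier pair of the same species (a crude stand-in for shared
#'   evolutionary history; default off).
#' @param dup_mu per-site mutation probability applied to duplicated pairs.
#' @return object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_species = 100L, pairs_per_species = c(2L, 10L),
                           L_A = 64L, L_B = 112L, n_coupled = 20L,
                           epsilon = 0.9, background = c("uniform", "dirichlet"),
                           dirichlet_alpha = 0.5, dup_prob = 0, dup_mu = 0.1) {
  background <- match.arg(background)
  stopifnot(n_species >= 1L, epsilon >= 0, epsilon <= 1,
            n_coupled >= 0L, n_coupled <= min(L_A, L_B),
            dup_prob >= 0, dup_prob <= 1)
  structure(list(n_species = as.integer(n_species),
                 pairs_per_species = as.integer(pairs_per_species),
                 L_A = as.integer(L_A), L_B = as.integer(L_B), q = N_STATES,
                 n_coupled = as.integer(n_coupled), epsilon = epsilon,
                 background = background, dirichlet_alpha = dirichlet_alpha,
                 dup_prob = dup_prob, dup_mu = dup_mu),
            class = "synthetic_spec")
}

#' Generate a synthetic paired alignment with a planted pairing
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param rng_seed optional integer seed; when NULL the current RNG stream is
#'   used.
#' @return a \code{\link{paired_alignment}} with \code{gold} set to the
#'   planted pairing. The coupled site pairs are recorded in the
#'   \code{"coupled_sites"} attribute (columns \code{i}, \code{j},
#'   family-local). Family-B records are shuffled within each species so row
#'   order carries no pairing information.
#' @export
generate_alignment <- function(spec, rng_seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  q <- spec$q
  # per-site background distributions
  bg_draw <- function(L) {
    if (spec$background == "uniform") {
      matrix(1 / q, L, q)
    } else {
      g <- matrix(stats::rgamma(L * q, shape = spec$dirichlet_alpha), L, q)
      g / rowSums(g)
    }
  }
  bgA <- bg_draw(spec$L_A)
  bgB <- bg_draw(spec$L_B)
  coupled <- if (spec$n_coupled > 0L)
    cbind(i = sample.int(spec$L_A, spec$n_coupled),
          j = sample.int(spec$L_B, spec$n_coupled))
  else cbind(i = integer(0), j = integer(0))

  m_p <- if (length(spec$pairs_per_species) == 1L)
    rep(spec$pairs_per_species, spec$n_species)
  else
    sample(seq(spec$pairs_per_species[1L], spec$pairs_per_species[2L]),
           spec$n_species, replace = TRUE)
  M <- sum(m_p)
  sample_bg <- function(bg, n, site) sample.int(q, n, replace = TRUE,
                                                prob = bg[site, ])
  A <- matrix(0L, M, spec$L_A)
  B <- matrix(0L, M, spec$L_B)
  for (i in seq_len(spec$L_A)) A[, i] <- sample_bg(bgA, M, i)
  for (j in seq_len(spec$L_B)) B[, j] <- sample_bg(bgB, M, j)
  # plant the coupling between row k of A and row k of B (the true pairs)
  for (k in seq_len(nrow(coupled))) {
    i <- coupled[k, "i"]
    j <- coupled[k, "j"]
    copy <- runif(M) < spec$epsilon
    latent <- sample_bg(bgA, M, i)
    A[copy, i] <- latent[copy]
    B[copy, j] <- latent[copy]
  }
  species <- rep(sprintf("sp%04d", seq_len(spec$n_species)), m_p)
  # optional duplication: overwrite some pairs by mutated copies of an
  # earlier pair of the same species
  if (spec$dup_prob > 0) {
    for (s in unique(species)) {
      rows <- which(species == s)
      for (r in rows[-1L]) {
        if (runif(1) < spec$dup_prob) {
          src <- if (r == rows[2L]) rows[1L] else sample(rows[rows < r], 1L)
          mutA <- runif(spec$L_A) < spec$dup_mu
          mutB <- runif(spec$L_B) < spec$dup_mu
          A[r, ] <- A[src, ]
          B[r, ] <- B[src, ]
          A[r, mutA] <- sample.int(q, sum(mutA), replace = TRUE)
          B[r, mutB] <- sample.int(q, sum(mutB), replace = TRUE)
        }
      }
    }
  }
  ids_A <- sprintf("A%05d", seq_len(M))
  ids_B <- sprintf("B%05d", seq_len(M))
  rownames(A) <- ids_A
  rownames(B) <- ids_B
  gold <- data.frame(species = species, id_A = ids_A, id_B = ids_B,
                     stringsAsFactors = FALSE)
  # shuffle B within species so row order is uninformative
  perm <- unlist(lapply(split(seq_len(M), species),
                        function(x) x[sample.int(length(x))]),
                 use.names = FALSE)
  B <- B[perm, , drop = FALSE]
  aln <- paired_alignment(A, B, species, species[perm], gold = gold)
  attr(aln, "coupled_sites") <- coupled
  aln
}

#' Exact mutual information of one coupled column pair of the generator
#'
#' Under a uniform background the joint distribution of a coupled site pair
#' is the mixture p(a, b) = epsilon * delta_ab / q + (1 - epsilon) / q^2,
#' whose MI has a closed form evaluated here (in nats). Refused for
#' non-uniform backgrounds, where no closed form is kept.
#'
#' @param spec a \code{\link{synthetic_spec}} (or a scalar epsilon).
#' @param q number of states (ignored when \code{spec} is a spec object).
#' @return scalar MI in nats.
#' @export
theoretical_column_mi <- function(spec, q = N_STATES) {
  if (inherits(spec, "synthetic_spec")) {
    if (spec$background != "uniform")
      stop("closed-form column MI is only available for the uniform background")
    eps <- spec$epsilon
    q <- spec$q
  } else {
    eps <- spec
  }
  stopifnot(eps >= 0, eps <= 1)
  if (eps == 0) return(0)
  p_diag <- eps / q + (1 - eps) / q^2    # q cells
  p_off <- (1 - eps) / q^2               # q^2 - q cells
  term_off <- if (p_off > 0) (q^2 - q) * p_off * log(q^2 * p_off) else 0
  q * p_diag * log(q^2 * p_diag) + term_off
}
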