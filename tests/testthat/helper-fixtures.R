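# Shared in-code fixtures and independent oracles for the test suite.

# tiny paired alignment built by hand from state matrices
toy_alignment <- function(n_per_species = c(sp1 = 2L, sp2 = 3L),
                          L_A = 4L, L_B = 5L, seed = 1L) {
  set.seed(seed)
  M <- sum(n_per_species)
  A <- matrix(sample.int(21L, M * L_A, replace = TRUE), M, L_A)
  B <- matrix(sample.int(21L, M * L_B, replace = TRUE), M, L_B)
  rownames(A) <- sprintf("a%02d", seq_len(M))
  rownames(B) <- sprintf("b%02d", seq_len(M))
  species <- rep(names(n_per_species), n_per_species)
  gold <- data.frame(species = species,
                     id_A = rownames(A), id_B = rownames(B),
                     stringsAsFactors = FALSE)
  paired_alignment(A, B, species, species, gold = gold)
}

# all permutations of 1..n (exhaustive assignment oracle)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub)
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

# brute-force maximum assignment total over all permutations
brute_force_max <- function(S) {
  n <- nrow(S)
  best <- -Inf
  for (p in all_permutations(n))
    best <- max(best, sum(S[cbind(seq_len(n), p)]))
  best
}

# independent frequency oracle: plain double loops over Eqs for weighted,
# pseudocounted one- and two-site frequencies of a CA
oracle_frequencies <- function(ca, L_A, weights, lambda, q = 21L) {
  M_eff <- sum(weights)
  L <- ncol(ca)
  f1 <- matrix(0, L, q)
  for (a in seq_len(nrow(ca)))
    for (i in seq_len(L))
      f1[i, ca[a, i]] <- f1[i, ca[a, i]] + weights[a]
  f1 <- f1 / M_eff
  L_B <- L - L_A
  f2 <- array(0, c(L_A, L_B, q, q))
  for (a in seq_len(nrow(ca)))
    for (i in seq_len(L_A))
      for (j in seq_len(L_B))
        f2[i, j, ca[a, i], ca[a, L_A + j]] <-
          f2[i, j, ca[a, i], ca[a, L_A + j]] + weights[a]
  f2 <- f2 / M_eff
  list(f1 = lambda / q + (1 - lambda) * f1,
       f2 = lambda / q^2 + (1 - lambda) * f2)
}

# pull the (i, j, alpha, beta) cell out of a packed (L_A q) x (L_B q) table
table_cell <- function(tab, i, j, a, b, q = 21L) {
  tab[(i - 1L) * q + a, (j - 1L) * q + b]
}

# small balanced synthetic alignment for pipeline tests
small_coupled_alignment <- function(seed = 3L, n_species = 30L, m = 4L,
                                    L_A = 12L, L_B = 16L, n_coupled = 8L,
                                    epsilon = 0.9) {
  spec <- synthetic_spec(n_species = n_species, pairs_per_species = m,
                         L_A = L_A, L_B = L_B, n_coupled = n_coupled,
                         epsilon = epsilon)
  filter_and_balance(generate_alignment(spec, rng_seed = seed))
}
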