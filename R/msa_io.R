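# Reading, validating, filtering and subsampling species-annotated paired
# alignments. Sequences are stored as integer matrices with states 1..21
# (20 amino acids in AA_LETTERS order, gap = 21); rownames carry sequence ids.

#' Encode aligned sequence strings as integer state matrices
#'
#' Upper/lower case letters are accepted; '-' and '.' are read as the gap
#' state. Non-standard residue letters (B, Z, X, U, O, J, '*', ...) are mapped
#' to the gap state, with a single warning reporting how many letters were
#' remapped: the statistical model has exactly 21 states.
#'
#' @param seqs character vector of equal-length aligned sequences.
#' @return integer matrix (sequences x sites), values in 1..21.
#' @keywords internal
encode_alignment <- function(seqs) {
  if (length(seqs) == 0L) stop("no sequences to encode")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged alignment: record %d has width %d, expected %d",
                 bad, widths[bad], widths[1L]))
  }
  chars <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE)),
                  nrow = length(seqs), byrow = TRUE)
  chars[chars == "."] <- "-"
  codes <- match(chars, AA_LETTERS)
  n_unknown <- sum(is.na(codes))
  if (n_unknown > 0L) {
    warning(sprintf("%d non-standard residue letter(s) mapped to the gap state",
                    n_unknown))
    codes[is.na(codes)] <- GAP_STATE
  }
  matrix(as.integer(codes), nrow = length(seqs))
}

#' @keywords internal
decode_alignment <- function(mat) {
  apply(mat, 1L, function(r) paste(AA_LETTERS[r], collapse = ""))
}

#' Construct a paired alignment object
#'
#' Container for two aligned protein-family blocks (A and B) in which every
#' record is annotated with a species, plus an optional gold pairing used for
#' benchmarking. Validity requires fixed widths per family, unique ids, and
#' states in 1..21.
#'
#' @param A,B integer matrices (records x sites, states 1..21) with rownames
#'   giving unique sequence ids.
#' @param species_A,species_B character vectors of species labels, one per
#'   record of the corresponding family.
#' @param gold optional data.frame with columns \code{species}, \code{id_A},
#'   \code{id_B}: the true one-to-one pairing.
#' @return object of class \code{paired_alignment} with elements \code{A},
#'   \code{B}, \code{species_A}, \code{species_B}, \code{gold}, \code{L_A},
#'   \code{L_B}, \code{L}.
#' @export
paired_alignment <- function(A, B, species_A, species_B, gold = NULL) {
  stopifnot(is.matrix(A), is.matrix(B),
            length(species_A) == nrow(A), length(species_B) == nrow(B))
  if (is.null(rownames(A)) || is.null(rownames(B)))
    stop("A and B must carry sequence ids as rownames")
  if (anyDuplicated(rownames(A))) stop("duplicated ids in family A")
  if (anyDuplicated(rownames(B))) stop("duplicated ids in family B")
  for (mat in list(A, B))
    if (any(mat < 1L | mat > N_STATES)) stop("state codes must lie in 1..21")
  if (!is.null(gold)) {
    stopifnot(all(c("species", "id_A", "id_B") %in% names(gold)))
    gold <- as.data.frame(gold)[, c("species", "id_A", "id_B")]
  }
  structure(list(A = A, B = B,
                 species_A = as.character(species_A),
                 species_B = as.character(species_B),
                 gold = gold,
                 L_A = ncol(A), L_B = ncol(B), L = ncol(A) + ncol(B)),
            class = "paired_alignment")
}

#' @export
print.paired_alignment <- function(x, ...) {
  cat(sprintf("paired_alignment: %d A (L_A=%d) + %d B (L_B=%d) sequences, %d species\n",
              nrow(x$A), x$L_A, nrow(x$B), x$L_B,
              length(union(x$species_A, x$species_B))))
  if (!is.null(x$gold)) cat(sprintf("  gold pairing: %d pairs\n", nrow(x$gold)))
  invisible(x)
}

# species -> list(A = row indices, B = row indices)
#' @keywords internal
species_index <- function(aln) {
  sp <- sort(union(aln$species_A, aln$species_B))
  idx_A <- split(seq_len(nrow(aln$A)), factor(aln$species_A, levels = sp))
  idx_B <- split(seq_len(nrow(aln$B)), factor(aln$species_B, levels = sp))
  lapply(setNames(sp, sp), function(s) list(A = idx_A[[s]], B = idx_B[[s]]))
}

#' Read a species-annotated paired alignment from two FASTA files
#'
#' Both files must be fixed-width alignments. By default the header dialect is
#' \code{"id|species"}; alternatively a two-column TSV (id, species) can
#' supply the species of every record.
#'
#' @param fasta_A,fasta_B paths to the aligned FASTA files of families A and B.
#' @param species_parser \code{"pipe"} (default, header \code{id|species}) or
#'   \code{"tsv"}.
#' @param species_tsv path to an id/species table, required when
#'   \code{species_parser = "tsv"}.
#' @param gold optional path to a pairing TSV (columns species, id_A, id_B).
#' @return a \code{\link{paired_alignment}}.
#' @export
read_paired_fasta <- function(fasta_A, fasta_B,
                              species_parser = c("pipe", "tsv"),
                              species_tsv = NULL, gold = NULL) {
  species_parser <- match.arg(species_parser)
  read_one <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    ss <- Biostrings::readAAStringSet(path)
    headers <- names(ss)
    seqs <- as.character(ss)
    if (species_parser == "pipe") {
      parts <- strsplit(headers, "|", fixed = TRUE)
      bad <- which(vapply(parts, length, 1L) < 2L)
      if (length(bad))
        stop(sprintf("cannot parse species from header(s) of record(s) %s in %s (expected 'id|species')",
                     paste(head(bad, 5L), collapse = ", "), path))
      ids <- vapply(parts, `[[`, "", 1L)
      sp <- vapply(parts, `[[`, "", 2L)
    } else {
      map <- read.delim(species_tsv, header = FALSE, stringsAsFactors = FALSE)
      ids <- sub("\\s.*$", "", headers)
      sp <- map[[2L]][match(ids, map[[1L]])]
      if (anyNA(sp)) {
        bad <- which(is.na(sp))
        stop(sprintf("no species mapping for record(s) %s in %s",
                     paste(head(bad, 5L), collapse = ", "), path))
      }
    }
    mat <- encode_alignment(seqs)
    rownames(mat) <- ids
    list(mat = mat, species = sp)
  }
  a <- read_one(fasta_A)
  b <- read_one(fasta_B)
  gold_df <- if (!is.null(gold)) read_pairing_tsv(gold) else NULL
  paired_alignment(a$mat, b$mat, a$species, b$species, gold = gold_df)
}

#' Write a paired alignment to two FASTA files (headers \code{id|species})
#' @param aln a \code{\link{paired_alignment}}.
#' @param fasta_A,fasta_B output paths.
#' @param gold optional output path for the gold pairing TSV.
#' @export
write_paired_fasta <- function(aln, fasta_A, fasta_B, gold = NULL) {
  write_one <- function(mat, species, path) {
    ss <- Biostrings::AAStringSet(decode_alignment(mat))
    names(ss) <- paste(rownames(mat), species, sep = "|")
    Biostrings::writeXStringSet(ss, path)
  }
  write_one(aln$A, aln$species_A, fasta_A)
  write_one(aln$B, aln$species_B, fasta_B)
  if (!is.null(gold) && !is.null(aln$gold)) write_pairing_tsv(aln$gold, gold)
  invisible(aln)
}

#' Read / write pairing tables (TSV with columns species, id_A, id_B)
#' @param path file path.
#' @return data.frame with columns species, id_A, id_B.
#' @export
read_pairing_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "id_A", "id_B") %in% names(df)))
  df[, c("species", "id_A", "id_B")]
}

#' @rdname read_pairing_tsv
#' @param pairs data.frame with columns species, id_A, id_B.
#' @export
write_pairing_tsv <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply the standard species filter and balance family sizes
#'
#' Species contributing fewer than \code{min_pairs} matchable pairs are
#' discarded (pairing is unambiguous for singletons, which would act as an
#' implicit training set). Within each retained species the number of
#' matchable pairs is min(#A, #B); excess members of the larger family are
#' dropped deterministically (largest row index first), so the operation is
#' idempotent and reproducible.
#'
#' @param aln a \code{\link{paired_alignment}}.
#' @param min_pairs minimum matchable pairs per species (default 2).
#' @return filtered, balanced \code{paired_alignment}; errors if nothing
#'   survives.
#' @export
filter_and_balance <- function(aln, min_pairs = 2L) {
  idx <- species_index(aln)
  keep_A <- integer(0)
  keep_B <- integer(0)
  for (s in names(idx)) {
    nA <- length(idx[[s]]$A)
    nB <- length(idx[[s]]$B)
    m <- min(nA, nB)
    if (m < min_pairs) next
    keep_A <- c(keep_A, idx[[s]]$A[seq_len(m)])
    keep_B <- c(keep_B, idx[[s]]$B[seq_len(m)])
  }
  if (length(keep_A) == 0L) stop("no species left after filtering")
  keep_A <- sort(keep_A)
  keep_B <- sort(keep_B)
  gold <- aln$gold
  if (!is.null(gold)) {
    gold <- gold[gold$id_A %in% rownames(aln$A)[keep_A] &
                 gold$id_B %in% rownames(aln$B)[keep_B], , drop = FALSE]
    rownames(gold) <- NULL
  }
  paired_alignment(aln$A[keep_A, , drop = FALSE], aln$B[keep_B, , drop = FALSE],
                   aln$species_A[keep_A], aln$species_B[keep_B], gold = gold)
}

#' Subsample a paired alignment by whole species
#'
#' Species are added in uniformly random order until the pair count first
#' reaches or exceeds \code{target_M}, emulating dataset-size titrations built
#' by picking species at random from a full dataset. The gold pairing is
#' restricted accordingly.
#'
#' @param aln a balanced \code{\link{paired_alignment}}.
#' @param target_M target number of pairs (must not exceed the total).
#' @param rng_seed optional integer seed; when NULL the current RNG stream is
#'   used.
#' @return subsampled \code{paired_alignment}.
#' @export
subsample_by_species <- function(aln, target_M, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  idx <- species_index(aln)
  sizes <- vapply(idx, function(x) min(length(x$A), length(x$B)), 1L)
  if (target_M > sum(sizes)) stop("target_M exceeds the number of available pairs")
  if (target_M < min(sizes))
    stop("target_M is smaller than the smallest species; no subsample possible")
  if (target_M == sum(sizes)) return(aln)
  ord <- sample(names(idx))
  csum <- cumsum(sizes[ord])
  chosen <- ord[seq_len(which(csum >= target_M)[1L])]
  sel_A <- sort(unlist(lapply(idx[chosen], `[[`, "A"), use.names = FALSE))
  sel_B <- sort(unlist(lapply(idx[chosen], `[[`, "B"), use.names = FALSE))
  gold <- aln$gold
  if (!is.null(gold)) {
    gold <- gold[gold$species %in% chosen, , drop = FALSE]
    rownames(gold) <- NULL
  }
  paired_alignment(aln$A[sel_A, , drop = FALSE], aln$B[sel_B, , drop = FALSE],
                   aln$species_A[sel_A], aln$species_B[sel_B], gold = gold)
}

#' Build a concatenated alignment matrix from a pairing
#'
#' Joins the A and B sequences of each listed pair into rows of width
#' L = L_A + L_B. Note that family-B records are not stored in partner order
#' (synthetic alignments deliberately shuffle them), so concatenation must go
#' through an explicit pairing, by default the gold one.
#'
#' @param aln a \code{\link{paired_alignment}}.
#' @param pairs data.frame with columns \code{id_A}, \code{id_B} (default:
#'   the gold pairing).
#' @return integer matrix (pairs x L).
#' @export
concatenate_pairs <- function(aln, pairs = aln$gold) {
  if (is.null(pairs)) stop("no pairing given and the alignment has no gold pairing")
  a <- match(pairs$id_A, rownames(aln$A))
  b <- match(pairs$id_B, rownames(aln$B))
  if (anyNA(a) || anyNA(b)) stop("pairing refers to ids absent from the alignment")
  cbind(aln$A[a, , drop = FALSE], aln$B[b, , drop = FALSE])
}

#' Descriptive summary of a paired alignment
#'
#' Reports the dataset descriptives used throughout benchmarking: number of
#' matchable pairs, number of species, mean pairs per species, and the two
#' alignment widths.
#'
#' @param aln a \code{\link{paired_alignment}}.
#' @return list with \code{n_pairs}, \code{n_species},
#'   \code{mean_pairs_per_species}, \code{L_A}, \code{L_B}.
#' @export
alignment_summary <- function(aln) {
  idx <- species_index(aln)
  sizes <- vapply(idx, function(x) min(length(x$A), length(x$B)), 1L)
  sizes <- sizes[sizes > 0L]
  list(n_pairs = sum(sizes),
       n_species = length(sizes),
       mean_pairs_per_species = mean(sizes),
       L_A = aln$L_A, L_B = aln$L_B)
}
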