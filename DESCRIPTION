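Package: miipa
Title: Mutual-Information Iterative Pairing of Interacting Paralogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts which paralogs from two protein families are
    interaction partners within each species, from sequences alone. Candidate
    concatenated sequences are scored by summed inter-protein pointwise
    mutual information, the within-species one-to-one assignment problem is
    solved exactly with the Hungarian algorithm, and the concatenated
    training alignment is grown iteratively with the most confidently
    assigned pairs (the MI-IPA). Includes comparator scores (normalized PMI,
    covariance, mean-field direct-coupling-analysis interaction energies), a
    synthetic paired-alignment generator with a planted gold pairing, and
    benchmarking statistics: true-positive fractions and their random
    baseline, hypergeometric excess of shared predictions, replication
    fractions across stochastic restarts, column-scrambling nulls, and
    finite-size-corrected pairwise mutual information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
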