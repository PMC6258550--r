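# miipa — mutual-information iterative pairing of interacting paralogs

Many interacting protein families come in within-genome paralog sets: a
species has several histidine kinases and several response regulators, or
several copies of each half of an ABC transporter, and each protein of
family A functions with one specific partner of family B. `miipa` answers
the question *which A goes with which B in each species* from two
species-annotated multiple sequence alignments alone — no structures, no
known interactions, optionally no training pairs at all. It is aimed at
researchers studying protein–protein interactions, coevolution, and
two-component signaling, and at anyone who needs paired alignments (e.g. to
feed inter-protein contact prediction) when genome adjacency does not
settle the pairing.

## The method in brief

For a concatenated alignment of M currently assumed pairs, the pointwise
mutual information of states (α, β) at an inter-protein site pair (i, j) is

    PMI_ij(α, β) = log[ f̃_ij(α, β) / ( f̃_i(α) f̃_j(β) ) ]

with similarity-weighted (threshold θ), pseudocounted (weight Λ)
frequencies. A candidate pair AB scores S_AB = Σ_ij PMI_ij(α_i, β_j) over
all inter-protein site pairs, and an assignment X scores S_X = ⟨S_AB⟩,
which for the model's own alignment equals the summed inter-protein mutual
information Σ_ij MI_ij — the quantity being maximized. Within each species
the maximum-score one-to-one assignment is found exactly with the Hungarian
algorithm; each assigned pair gets a confidence ΔS_AB (the drop in the
species total when that pair is forbidden and the assignment re-solved).
The iterative pairing algorithm (IPA) starts from known pairs or from
random within-species pairings, and at iteration n re-scores the whole
dataset and rebuilds the training alignment from the (n−1)·N_increment
most confident pairs, until every protein is paired. Normalized-PMI,
covariance, and mean-field DCA interaction-energy scoring are available as
drop-in comparators, plus the evaluation statistics used to benchmark
partner inference (random baseline, excess shared predictions, replication
fractions, column-scrambling null, finite-size-corrected pairwise MI).

See the methods vignette (`vignettes/mi-ipa-methods.Rmd`) for the model,
parameter meanings and design choices.

## Worked example

Generate a synthetic benchmark with a planted pairing (40 species of 4
pairs, 8 coupled site pairs at coupling strength 0.9), then run the MI-IPA
with no training set:

```r
library(miipa)
spec <- synthetic_spec(n_species = 40, pairs_per_species = 4,
                       L_A = 10, L_B = 12, n_coupled = 8, epsilon = 0.9)
aln <- filter_and_balance(generate_alignment(spec, rng_seed = 1))
aln
#> paired_alignment: 160 A (L_A=10) + 160 B (L_B=12) sequences, 40 species
#>   gold pairing: 160 pairs

random_pairing_expectation(aln)   # random-guessing baseline: #species / M
#> [1] 0.25

res <- run_ipa(aln, ipa_options(mode = "mi", n_increment = 6, rng_seed = 1))
res
#> ipa_result (mi, hungarian): 28 iterations, 160 predicted pairs
#>   final S_X = 128.1575, final TP fraction = 0.794

head(res$final_pairs, 3)
#>   species   id_A   id_B    score confidence is_training is_correct
#> 1  sp0032 A00126 B00126 146.5190   581.0056       FALSE       TRUE
#> 2  sp0004 A00014 B00014 150.6627   560.8886       FALSE       TRUE
#> 3  sp0033 A00132 B00132 137.3348   549.9508       FALSE       TRUE
```

Starting from random pairings (TP fraction 0.25 by chance), the algorithm
ends at a TP fraction of 0.79 on this deliberately small dataset; larger
datasets and smaller increments do better (the 500-pair acceptance
benchmark recovers >99%). `final_pairs` is sorted by decreasing confidence:
the top of the list is almost always correct, so confidence is also a
useful per-pair reliability measure. `res$trajectory` records CA size, S_X
and TP fraction per iteration.

The same pipeline is scriptable from a shell via the thin CLI in
`exec/miipa` (subcommands `simulate`, `pair`, `eval`, `scramble`,
`spectrum`); every run writes a JSON manifest with options and seeds so it
can be reproduced exactly.

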