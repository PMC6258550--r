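---
title: "Pairing interacting paralogs by mutual information: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairing interacting paralogs by mutual information: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two protein families A and B interact: each member of family A binds one
specific member of family B, and the partners live in the same genome. Gene
duplication leaves most species with several paralogs of each family, so
sequencing alone does not reveal which A goes with which B. The classic
benchmark is prokaryotic two-component signaling, where a histidine kinase
(HK, interaction domain of 64 columns) phosphorylates its cognate response
regulator (RR, 112 columns), and a typical genome contains a dozen such
pairs. `miipa` predicts the within-species one-to-one pairing of two
species-annotated multiple sequence alignments, from sequence statistics
alone.

## Scoring model

Work on a concatenated alignment (CA) of M currently assumed pairs, rows of
width $L = L_A + L_B$, each site carrying one of $q = 21$ states (20 amino
acids plus gap). From the CA we estimate one-site frequencies $f_i(\alpha)$
and two-site frequencies $f_{ij}(\alpha,\beta)$. Two corrections, standard
in coevolutionary sequence analysis, regularize them:

* **Similarity weighting.** A row counts $1/m_a$, where $m_a$ is the number
  of rows (itself included) with mean per-site Hamming distance strictly
  below $\theta$; $M_\mathrm{eff} = \sum_a 1/m_a$ replaces M as the
  denominator. Default $\theta = 0.15$; the direct-coupling comparator uses
  its historical $\theta = 0.3$. Distances are measured on the full
  concatenated row with the gap as an ordinary state. $\theta = 0$ turns the
  weighting off.
* **Pseudocount.** $\tilde f_i = \Lambda/q + (1-\Lambda) f_i$ and
  $\tilde f_{ij} = \Lambda/q^2 + (1-\Lambda) f_{ij}$ for $i \ne j$ (and
  $\tilde f_{ii}(\alpha,\beta) = \tilde f_i(\alpha)\,\delta_{\alpha\beta}$
  on the diagonal). Default $\Lambda = 0.15$ for PMI scoring, $\Lambda =
  0.5$ for the comparator. The mixture keeps every joint frequency at or
  above $\Lambda/q^2$, so logarithms are safe. Performance depends only
  weakly on both parameters.

The pointwise mutual information of a state pair at an inter-protein site
pair is

$$\mathrm{PMI}_{ij}(\alpha,\beta) =
  \log\frac{\tilde f_{ij}(\alpha,\beta)}
           {\tilde f_i(\alpha)\tilde f_j(\beta)},$$

in nats throughout (no logarithm base is canonical here and every use is a
ranking, so the natural log is used and reported). A candidate pair AB is
scored by summing PMIs over all $L_A \times L_B$ inter-protein site pairs,

$$S_{AB} = \sum_{i \le L_A}\sum_{j > L_A} \mathrm{PMI}_{ij}(\alpha_i, \beta_j),$$

and an assignment X of M' pairs by the mean $S_X = \frac{1}{M'}\sum S_{AB}$.
With unit weights and no pseudocount, scoring the very CA that produced the
model gives exactly $S_X = \sum_{ij} \mathrm{MI}_{ij}$, the summed
inter-protein mutual information — the quantity the algorithm implicitly
maximizes. The identity is asserted to $10^{-10}$ in the test suite; with
weighting and pseudocounts it holds only approximately, which is expected.

Alternative score tables are provided with identical plumbing: the
normalized PMI $-\mathrm{PMI}_{ij}(\alpha,\beta)/\log \tilde
f_{ij}(\alpha,\beta)$, the covariance $\tilde f_{ij} - \tilde f_i \tilde
f_j$, and mean-field direct-coupling (DCA) effective interaction energies,
obtained by inverting the regularized covariance matrix over all sites with
the gap state dropped (the usual mean-field reduction) and negating the
inter-protein blocks. Energies are compared only within a species, so gauge
offsets cancel and no zero-sum gauge is applied. A site-pair mask (for
example, structural contacts) can zero out chosen $(i,j)$ contributions to
every pair score.

## The iterative pairing algorithm

Each iteration: (1) build the frequency and score models from the current
CA; (2) score every within-species candidate pair of the *full* dataset;
(3) within each species, solve the one-to-one assignment that maximizes the
summed scores — exactly, with the Hungarian algorithm — and give each
assigned pair a confidence $\Delta S_{AB}$: the drop in the species' optimal
total when that pair is forbidden and the assignment re-solved; (4) rank
all assigned pairs by decreasing confidence and rebuild the CA from the top
$(n-1)\,N_\mathrm{increment}$ of them (n the iteration number), plus the
immutable training pairs if any. The run ends at the iteration whose CA
would contain every assigned pair; that assignment is the result. Every
non-training pair is re-selected from scratch each iteration, which lets
early errors be corrected.

Two initializations are supported. With a training set, the first CA holds
$N_\mathrm{start}$ known pairs, which stay in the CA throughout, never enter
the confidence ranking, and are excluded from the assignable pool and from
reported TP fractions. Without one, the first CA pairs every A with a random
B of its species; such a pairing contains on average one correct pair per
species (a random permutation has one fixed point in expectation), i.e. a
TP fraction of (number of species)/M, which is also the random baseline all
results are compared against.

Design choices worth stating:

* **Confidence, not raw score, ranks pairs into the CA.** The two are
  strongly correlated, but the leave-one-out drop measures how unambiguous
  the assignment is within its species, which is the quantity of interest.
* **Assignment ties** are broken by an infinitesimal, consistently applied
  lexicographic (row, column) perturbation, and ranking ties by species and
  id, so equal inputs give identical outputs on every platform. Singleton
  species get a $+\infty$ confidence sentinel (no alternative assignment
  exists; real datasets exclude them anyway, as an unambiguous singleton
  would act as an implicit training pair).
* **Forbidden cells** in the confidence re-solve use a large finite penalty
  rather than $-\infty$, keeping the solver's arithmetic finite.
* **Solver defaults** follow the historical pairing: Hungarian for
  PMI/NPMI/covariance scores, greedy (best remaining cell first) for DCA
  energies; both are selectable. The greedy solver is provably suboptimal on
  adversarial matrices (the test suite carries a 2x2 counterexample) but
  cheap and close to optimal on diagonally dominant ones.
* **$\Lambda = 0$ PMI models** are permitted (they are needed for the
  $S_X = \sum \mathrm{MI}$ identity): zero joint frequencies become
  $-\infty$ table cells with a warning. Rows of the generating CA never
  select such a cell; other candidates may, and then simply score
  $-\infty$.
* **Frequencies are rebuilt from scratch each iteration**; CA membership
  changes non-incrementally between iterations, so there is nothing to
  update in place.

## Synthetic benchmark data

The generator plants a known one-to-one pairing: species blocks of
configurable size, per-site background distributions (uniform by default, or
Dirichlet-drawn), and `n_coupled` inter-protein site pairs — each using an A
column and a B column of its own — where, with probability $\epsilon$, both
members of a *true* pair copy one shared latent state. The joint
distribution of a coupled column pair under the uniform background is the
mixture $p(\alpha,\beta) = \epsilon\,\delta_{\alpha\beta}/q +
(1-\epsilon)/q^2$, whose mutual information has a closed form
(`theoretical_column_mi`), used as an oracle in the tests: 0 at
$\epsilon = 0$, $\log q \approx 3.04$ nats at $\epsilon = 1$. Family-B rows
are shuffled within species so that record order carries no pairing
information.

What the generator emulates: species structure, 21-state columns, tunable
inter-family dependence, gap-free planted signal, and the HK-RR widths
(64/112) as defaults. What it does not emulate: phylogenetic correlations
(rows are independent given the planted coupling; a crude duplication knob
— copy an earlier pair and mutate each site with probability $\mu$ — is off
by default), correlated intra-protein structure, conservation gradients
along the sequence, and gaps. Real alignments carry broad covariation
(functional and phylogenetic) across *many* site pairs; iid synthetic data
concentrates all signal in the planted pairs. Passing the recovery
benchmarks therefore demonstrates the correctness of the machinery — and the
qualitative phenomena: bootstrap from random initializations, bimodal
replication fractions for coupled families, collapse to the random baseline
after column scrambling — not the quantitative TP fractions to expect on
biological data.

This difference dictates the geometry of the recovery benchmark (100
species of 5 pairs, 20 coupled site pairs, $\epsilon = 0.9$, widths 20 and
24). With only 20 informative site pairs, the summed-PMI noise from
uninformative pairs grows as their square root: at the full HK-RR widths
the ~7100 uninformative pairs contribute noise of the same order as the
planted signal (~48 nats at M = 500) and *no* estimator can recover the
pairing, whereas at a planted coupling density of ~4% (20 of 480 site
pairs) recovery is essentially complete. Trend checks (TP non-increasing in
$N_\mathrm{increment}$, non-decreasing in dataset size) run at a further
scaled-down geometry — 15-50 species of 4 pairs, widths 10 and 12, 8
coupled pairs at a deliberately moderate $\epsilon = 0.6$, 10 seeds —
because monotone trends are only visible away from the floor and ceiling of
the TP range, and these sizes keep the whole suite within a desktop run.

## Evaluation statistics

* **TP fraction**: share of predicted pairs matching the planted/gold
  pairing, over non-training pairs; compare to the (number of species)/M
  baseline.
* **Excess shared predictions E** between two algorithms: per species with
  m pairs of which p and q are correctly predicted by each, independent
  predictors share $\langle k\rangle = pq/m$ correct pairs (hypergeometric
  null); $E = \sum_i (k_{\mathrm{obs},i} - \langle k_i\rangle)/\sum_i
  (\min(p_i,q_i) - \langle k_i\rangle)$ is 0 in expectation under
  independence and 1 for identical predictions. Degenerate denominators
  (every species already maximal under the null) are reported as NA rather
  than forced.
* **Replication fractions**: across restarts differing only in the random
  initialization, the fraction of replicates predicting each candidate
  pair. For genuinely coupled families the distribution is strongly
  bimodal (reported descriptively as the histogram mass in
  $[0, 0.1] \cup [0.9, 1]$ — the claim is visual, not a formal test), and
  ranking candidates by replication fraction (ties by mean confidence, then
  id) yields a consensus prediction whose TP fraction exceeds the mean
  single-replicate one.
* **Column scrambling**: permuting each column independently preserves
  one-site frequencies, destroys all inter-sequence correlation, and is the
  null against which interaction signatures are read.
* **Pairwise MI and its finite-size bias**: the naive summed-MI estimator
  (raw frequencies, no weights or pseudocounts — corrections would bias the
  *estimate*, unlike the *scores*, where they regularize a ranking) carries
  a positive bias with leading order $K/M$, $K$ up to $(q-1)^2$ per site
  pair; on iid data its log-log slope against M is $-1$, reproduced by the
  tests over $M \in \{250, \dots, 2000\}$. The `fit` correction subsamples
  the CA at 10 depths spread evenly in $1/M$ down to $M/3$ (3 draws
  averaged per depth), fits a degree-3 polynomial in $1/M$ and reports the
  intercept; it refuses $M < 1000$, where $M \lesssim K$ makes subleading
  terms dominate and the extrapolation unreliable. A named hook for an
  NSB-style Bayesian entropy correction exists but is deliberately not
  implemented.

## Practical parameters

| parameter | default | meaning |
|---|---|---|
| `theta` | 0.15 (0.3 dca) | neighbor threshold of the similarity weighting, per-site Hamming distance |
| `lambda` | 0.15 (0.5 dca) | pseudocount mixture weight, dimensionless in [0, 1] |
| `n_increment` | 6 | pairs added to the CA per iteration; smaller is slower and more accurate |
| `n_start` | 0 | training pairs; 0 starts from random within-species pairings |
| `assignment` | hungarian (greedy dca) | within-species assignment solver |

Run time is dominated by the number of iterations, roughly
$M/N_\mathrm{increment}$; the desk-scale benchmark (M = 500, widths 20/24,
$N_\mathrm{increment} = 6$, 85 iterations) completes in well under a minute,
and full HK-RR widths at the same M take a few minutes.

## Known limitations

Balanced within-species counts are required (`filter_and_balance` keeps
min(#A, #B) records per species, dropping the largest file-order indices for
reproducibility); genuinely injective matching of unequal family sizes is
out of scope. The mean-field DCA comparator inverts an
$L(q-1) \times L(q-1)$ matrix, so memory grows quadratically in total
width. No average-product correction is applied to MI, and no
interaction/non-interaction decision threshold is calibrated — the
replication-fraction and MI-spectrum outputs are the raw material for such
a decision, which requires known positive and negative family pairs to set.
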