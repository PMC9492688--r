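---
title: "Simplex-encoded cleavage-bias estimation: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simplex-encoded cleavage-bias estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(selma)
```

This vignette is the package's account of the science it implements: the
model and its assumptions, the parameters that matter, what the simulators
emulate (and deliberately do not), and the numerical and design choices made
where the problem left them open.

## The model

### Coordinates and cleavage events

All intervals are 0-based half-open internally (BED-native).  A paired
fragment `(chrom, start, end)` records two enzymatic cuts: the 5' base of
the plus-strand read at `start`, and the 5' base of the minus-strand read at
`end - 1`.  The k-mer context of a cut at position `i` is

* plus strand: the forward sequence of `[i - k/2, i + k/2)`;
* minus strand: the reverse complement of `[i - k/2 + 1, i + k/2 + 1)`,

i.e. the window is centered on the cut bond as the enzyme sees it on its own
strand.  The one-base asymmetry between strands follows from the cut sitting
*between* bases; `cleavage_kmer()` documents a worked example.  Windows that
leave a linear contig or contain `N` contribute nothing; circular contigs
(mitochondrial DNA) wrap around the origin, which is why a whole circular
contig of length L has background k-mer mass 2L rather than 2(L − k + 1).

### Naive scores and the simplex fit

The naive bias of k-mer j is `log2((N_j + pseudocount) / M_j)`: cleavage
occurrences over both-strand background occurrences in the same region set.
Scores are kept in log2 space throughout, because the downstream
expected-cleavage model exponentiates them as `2^a`, and because the dimeric
geometric mean becomes a plain average there.

The simplex encoding maps each base to a tetrahedral vertex of the cube
`[-1, 1]^3` and each adjacent dinucleotide to the row-major outer product of
its two base vectors.  Appending the intercept, the four mononucleotide
encodings are rows of an order-4 Hadamard matrix, and the sixteen full k = 2
encodings are rows of an order-16 Hadamard matrix — the feature columns are
exactly orthogonal in the complete design, which is what makes the least-
squares problem so well conditioned.  A k-mer has `12k - 8` features;
`fit_selma()` regresses the naive scores on them and the fitted values are
the model's bias scores, defined for all `4^k` k-mers.

Assumptions worth stating plainly:

* *Additivity*: bias is a sum of per-position base effects and adjacent-pair
  interactions.  Longer-range interactions are not modeled (and the naive
  table is the model's own training data, so systematic lack of fit is
  visible as `glance(fit)$r_squared` on deep data).
* *Stationarity*: one table describes the enzyme everywhere; region choice
  only changes the background composition.
* *Ratio scale*: only relative propensities are identifiable, hence
  `center_scores()` median-centers tables before cross-sample comparison.

### Dimeric transposition

Tn5 binds as a dimer and cuts both strands 9 bp apart, so the observed cut
at `i` (+) was co-generated with a cut at `i + 9` (-).  The dimeric score is
the geometric mean of the two end propensities — the arithmetic mean of the
two log2 scores, implemented in log space to stay well-defined after median
centering:

* `a'+_i = (a+_i + a-_{i+9}) / 2`
* `a'-_i = (a-_i + a+_{i-9}) / 2`

The 9-bp plus/minus cross-correlation peak (`strand_cross_correlation()`,
log2(count + 1) scale, shifts 1–20) is the data-level diagnostic of this
geometry; monomeric DNaseI data shows no preferred shift.

Two published comparison conventions are reproduced verbatim for
benchmarking: the `shifted` method references the **plus-strand** table for
both strands (`a'+_i = a+_{i+5}`, `a'-_i = a+_{i-5}`); the asymmetry is in
the printed source convention and is kept deliberately, flagged in the
documentation rather than "fixed".  The `masked` method scores a gapped
context (`X` = ignored, `N` = informative, `C` = the cut), with its own
mask-trained table via `masked_background_counts()` /
`masked_cleavage_counts()`.

### Bias-expected profiles

For a window of `w = 50` bp centered on `i`, position weights are
`y_i = 2^{a_i} / sum(2^{a_j})` over the window, and the expected cleavage is
the window's **observed total** times `y_i`.  An alternative reading of the
estimator multiplies the position's own observed count by `y_i`; that form
correlates with the observation by construction, so it is available behind
`per_position = TRUE` but is not the default used for observed/expected
comparisons.  Positions whose window leaves the region are undefined, which
also guarantees each window has data.  With a uniform bias the default
reduces exactly to a `w`-window moving average — a useful sanity identity
that the tests assert.

### Footprint bias score

DNaseI consensus footprints carry two recurrent bias spikes 7 bp inside each
footprint boundary.  `FBS = b - c` where `b` is the *mean* bias over the
spike set and `c` the *median* over the remaining footprint positions, both
strands pooled.  "Within the flanking 1 bp of the spikes" is implemented as
the union of `{spike - 1, spike, spike + 1}` for the two spikes (up to 6
positions × 2 strands); pooling the strands, rather than scoring 5' and 3'
spikes separately, was chosen because the spike definition is symmetric —
the phrasing admits alternatives, so the choice is documented here.
Footprints must be longer than 16 bp for the spike sets to be interior.
The occupancy-inference harness uses binary logistic regression (the binary
special case of the multinomial model) with stratified 5-fold
cross-validation and standardized features; partial AUROC (FPR ≤ c) and
AUPRC (recall ≤ c) are normalized by c so a perfect ranking scores 1, and
the rank score is `S = mean(-ln(r_i / (N + 1)))` over the six measures.
Natural log is used in both the raw footprint score and the rank score; the
base only rescales monotonically.

### Single-cell correction

Fragment bias is the mean of the two end scores (dimeric-combined by
default); CBS and PBS are per-barcode and per-peak medians, fragments
assigned to peaks by their midpoint (any-overlap and both-ends rules are
available).  After filtering (cells ≥ 10,000 reads; peaks with 10–4,000
reads), each peak's row is weighted by `W(x) = 12x(1-x)^2` — the Beta(2, 3)
density, zero at both extremes, mode at the 33rd percentile — where `x` is
the peak's PBS percentile mapped as `(rank - 0.5) / n` (so `x` never hits
exactly 0 or 1, and average ranks keep ties symmetric).  The matrix is then
rescaled to preserve the raw total count; `synthesize_integer_counts()`
stochastically rounds for tools requiring integers.  The per-percentile
ANOVA contribution profile (`anova_contribution_profile()`; vectorized
one-way F statistics, p < 0.05 qualification, no multiplicity correction
because the profile is descriptive) is the empirical justification for this
weight shape.

The evaluation pipeline is deliberately plain: per-cell depth normalization
to the median depth, `log1p`, PCA (60 components by default, capped at the
data rank), k-means with restarts, and the adjusted Rand index against
reference labels.  The normalization is fixed so that corrected/uncorrected
comparisons differ only in the correction.

## What the simulators emulate

Every simulator is fully determined by its seed and returns its ground
truth, so downstream tests are closed-loop.

* `sim_truth_bias()` draws either a *simplex-structured* truth (random
  coefficients, rescaled to a target log2-score sd; exactly representable
  by the model) or an i.i.d. *naive-random* table (no low-order structure
  at all; the model's worst case).  Real enzyme bias is, empirically, very
  well captured by mono+di terms — that is the premise of the method — so
  simplex-structured truth is the realistic default for pipeline-level
  experiments, while naive-random truth is used where structure must be
  absent (e.g. uniformity checks) or fully table-driven (single-cell
  composition planting).  The default score sd of 0.5 (log2) gives cut-rate
  ratios up to ~4x between favorable and unfavorable contexts, matching the
  magnitude of real dinucleotide cleavage preferences.
* `sim_dnase()` draws single-base cuts with propensity `2^score`
  (multinomial over in-region position-strand pairs) — the exact generative
  inverse of the estimator.  `sim_atac_dimeric()` samples *insertions* with
  the product propensity of their two cut contexts, sorts them within a
  region and pairs consecutive insertions into fragments, so each insertion
  terminates two adjacent fragments and both of its cuts (at `i` and
  `i + 9`) are observed — reproducing the cross-correlation signature by
  construction, as in the real assay.
* Accessible-region layouts (`sim_regions()`) cover a few percent of the
  simulated genome (100 × 1 kb on 2 Mb in the k-scan experiments), mirroring
  the small accessible fraction over which real analyses run.  This matters
  scientifically: the k-mer-size optimum is a bias/variance trade-off
  between context captured and reads available per k-mer, and both the
  per-position depth and the background k-mer recurrence that set this
  trade-off are properties of the peak-restricted analysis, not of the
  whole genome.  At these settings the observed/expected correlation rises
  with k to 10 and declines at 12 — too few reads per 12-mer — for the
  stated reason the larger context stops paying.
* `sim_footprints()` plants protection (rate × 0.3 inside) and bias spikes
  (`2^spike_amp` at the spike positions) and returns the planted positional
  bias, so FBS recovery can be checked against the amplitude (±5% at 10^4
  footprints in the tests).
* `sim_sc()` builds a genome of peaks where "biased" peaks are *tiled from
  high-truth-score k-mers* (so their estimated PBS is genuinely high, not
  labeled high), cell types differ only in "signal" peaks (fold 2.5 in the
  preferred type), and biased peaks carry per-cell log-normal block noise
  (sd 1.5 over 8 blocks) shared across types — multi-dimensional structured
  noise that pollutes the leading principal components.  Under these
  conditions clustering on signal peaks alone is perfect, clustering on all
  peaks is near-chance, and Beta-weight correction restores accuracy; the
  per-type `exposure` knob additionally shifts CBS between populations.

What the simulators do **not** emulate: sequencing error, mappability and
duplicate structure, fragment-length biology (nucleosome phasing), batch
effects, doublets, or real TF motif grammar.  Passing tests therefore
demonstrate correctness of the estimators and the internal consistency of
the pipelines under the stated generative model — not performance on any
real library.

## Numerical choices

* `fit_selma()` accumulates the normal equations in 200k-row chunks and
  solves by QR on the crossproduct.  The ±1 design is near-orthogonal, so
  this matches an svd-pseudoinverse oracle to 1e-8 (tested) while keeping
  the k = 12 problem (up to ~4M training rows × 136 columns) in memory.
  Rank deficiency is reported by naming the unidentifiable feature blocks.
* Model evaluation is positional wherever possible (`predict`-style lookups
  per position from the coefficient blocks), so `4^k` tables are only
  materialized when explicitly requested (`selma_bias_table()`, capped at
  k = 12).
* Pseudocount 1.0 (on the cleavage count only) and `min_background = 5` are
  the reporting defaults; neither has a canonical published value, so both
  are exposed.  The k-size scan uses `min_background = 1` because the scan
  must let large-k tables be trained on sparse backgrounds for the
  reads-per-k-mer penalty to be measured rather than imposed.
* Bias tables serialize scores at 17 significant digits and re-parse via
  the correctly-rounded C `strtod`, so write/read round trips are bitwise.
* Cross-correlation drops shift pairs that cross region boundaries rather
  than zero-padding (padding manufactures correlation at edges); zero
  variance yields `NA`, never an error.
* All seeded functions save and restore the caller's RNG state, and every
  stochastic experiment in tests and the acceptance script derives its
  seeds from a single integer.

## Problem sizes

The test suite and acceptance script run on 0.08–2 Mb genomes, 2 × 10^4 to
2 × 10^6 events, 10^2–10^4 footprints, and 120–200 peaks × 90–180 cells —
sizes chosen so every closed-loop property (estimator consistency,
split-half robustness, k-optimum, mtDNA sufficiency, ARI improvement) is
measurable with comfortable margins while a full run stays in the minutes
range on one core.

## Known limitations

* The fit is unweighted least squares by default; `weighting = "background"`
  downweights rare k-mers but no robust-loss option exists.
* Trinucleotide and longer-range interactions are out of model.
* The masked (gapped) method supports a single mask per table.
* `peak_removal_experiment()` is O(percentages × random subsets) clusterings
  and is meant for scaled-down designs.
* The CLI is a thin convenience wrapper; programmatic use through the
  package functions is the primary interface.
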