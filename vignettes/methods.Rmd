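---
title: "Models and methods behind pbodyscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pbodyscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbodyscreen)
library(dplyr)
```

pbodyscreen implements the quantitative analysis chain used to dissect how
cytoplasmic P-bodies protect budding yeast from hydroxyurea (HU)-induced DNA
replication stress: a colony-array suppressor screen in P-body-mutant
backgrounds, filtering of differential-expression (DE) tables to define
drug-specific response sets, integration of the two into a candidate-target
funnel, growth-curve fitness and multiplicative-model genetic interactions,
and a Bliss-style two-drug synergy analysis. This vignette describes each
model, the tunable parameters and their defaults, the synthetic-data
generators used to validate the chain, and the numerical choices made where
the underlying procedures left room for interpretation.

## Screen scoring

A screen plates every double mutant as a block of adjacent replicate colonies
(quadruplicate blocks on a 32 × 48 = 1536-position array by default), on
paired plates with and without drug, across replicate plate pairs (three by
default). Scoring proceeds in five steps:

1. **Block collapse.** Each complete block is averaged to one colony size
   (`collapse_replicate_colonies()`; arithmetic mean by default, median by
   option). Incomplete blocks are flagged and excluded rather than averaged,
   because a partial block usually reflects a pinning failure, not biology.
2. **Fitness in drug.** `compute_fitness()` takes the ratio of drug to
   no-drug colony size per strain. A zero no-drug size excludes the record.
3. **Small-colony filter.** Strains that grow poorly without drug have
   unstable ratios; `filter_small_colonies()` removes strains below a
   threshold. The published procedure states the filter but not the cutoff,
   so the default is 50% of the no-drug plate median, with an absolute
   override. At the default the filter is scale-free per plate.
4. **Per-plate Z-scores.** Within each plate, `zscore_per_plate()` centers
   and scales fitness by the plate mean and sample (n − 1) standard
   deviation. Because the Z-score is invariant to any affine rescaling of a
   plate's values, multiplicative plate effects and shared pinning artefacts
   cancel here — this is the normalization's entire purpose. The published
   description mixes "fitness" and "colony size" in one sentence; this
   package z-scores the fitness ratio by default (`zscore_on = "fitness"`)
   and offers raw drug-plate size as an alternative for comparison.
   Zero-variance plates are flagged degenerate and yield missing Z-scores
   with a warning, never silent zeros.
5. **Hit calls.** `call_hits()` averages Z over replicate plates and calls
   suppressors at mean Z ≥ +1 and synthetic-sick strains at mean Z ≤ −1,
   the thresholds used in the original screens. Strains with fewer than
   `min_replicates = 2` usable replicates are reported uncalled (one screen
   arm in the study ran two rather than three replicates, so two is the
   floor at which averaging is still meaningful).

Because individual suppressor screens validate poorly (~27% in the study's
re-construction tests), `intersect_screens()` restricts attention to
suppressors recovered in both genetic backgrounds.

## Expression filtering and the candidate funnel

DE tables carry one row per gene × contrast × timepoint with a log2 ratio, a
p-value and a Benjamini–Hochberg q-value; `call_differential()` recomputes q
per contrast × timepoint family when absent and calls hits at q < 0.05 with
direction from the sign of the log2 ratio. Each contrast × timepoint table is
its own BH family, matching how DE tools emit per-comparison statistics.
Genes with q below threshold but a ratio of exactly zero are assigned to
neither direction.

`consecutive_upregulation()` keeps genes called up at ≥ 2 *adjacent*
positions of the ordered HU timepoints (1 h, 2 h, 4 h by default): 1 h & 2 h
or 2 h & 4 h qualify; 1 h & 4 h alone does not. The sampling grid is uneven
and the source text never defines adjacency over it, so adjacency in
sampling order is the package's reading. The drug-core sets
(`define_hu_core()`) additionally require no DE in the untreated contrast —
strictly at any sampled untreated timepoint by default, or only at the first
one in `mode = "lenient"`. `remove_gene_list()` then strips general
environmental-stress-response genes with full provenance, and
`candidate_funnel()` intersects the dual-screen suppressors with the
consecutively upregulated genes. Every derived set is a `gene_set` carrying
the filter chain that produced it.

## Growth fitness and genetic interactions

Fitness from liquid growth is the area under the OD600 curve
(`growth_auc()`, trapezoidal rule — the source describes only "area under
the curve" and the trapezoid is the assumption-free choice at 15-minute
sampling, where it is accurate to well under 0.1% for logistic growth).
No smoothing or blank subtraction is applied by default. Curves of unequal
duration within a condition raise an error rather than silently comparing
integrals over different windows. `relative_fitness()` normalizes to the
mean control AUC per condition, so the measure is dimensionless and
invariant to OD rescaling.

Genetic interactions use the multiplicative null: the expected fitness of a
double mutant is the product of its single-mutant fitness values
(`expected_double_fitness()`), and epsilon is observed minus expected.
`score_interaction()` builds expected values per replicate by pairing
single-mutant replicates in index order (all-pairs products by option) and
tests observed against expected with a two-sided Student t-test —
pooled-variance by default, since the original analysis names only
"Student's t-test"; Welch is selectable. A negative interaction requires
epsilon < 0 and p < 0.05. `test_exacerbation()` asks, one-sided, whether the
double mutant's relative fitness is lower in drug than untreated; the edge
weight reported for network display is the difference of condition means.
`count_condition_dependent_negatives()` counts pairs that are negative in
drug *and* significantly exacerbated. No multiple-testing correction is
applied across the handful of tested pairs, matching the original
reporting; a BH flag is available upstream via `bh_adjust()`.

With constant (noiseless) replicates the t-statistic is undefined; the
package then reports p = 1 when means agree and p = 0 (one-sided: only for
the hypothesized direction) when they differ, so noiseless closed-loop runs
behave sensibly instead of erroring.

## Two-drug synergy

`build_synergy_matrix()` scores a complete concentration grid (6 × 6 in the
study: five serial dilutions of each drug plus the no-drug control) under
Bliss independence: expected combination fitness is the product of the
single-drug fitness values, and the interaction score is **observed minus
expected**, so negative values indicate synergy. Descriptions of this
score sometimes state the subtraction in the opposite order; the
convention that negative values mean synergy is what fixes the direction
used here, and it is stated prominently wherever the score is reported.
All fitness values are normalized to the no-drug well, which forces the
zero-concentration row and column of the interaction grid to zero by
construction — a useful structural check on real data.

## Enrichment and quantification statistics

`interaction_enrichment()` tests whether a gene set interacts within itself
more than the network's overall density predicts: the within-set edge count
is binomially tested with n = the number of unordered pairs in the set and
success probability = the global edge density. The published construction
is ambiguous about whether edges with one or both endpoints in the set are
counted; both modes are implemented (`mode = "both"` default) and the mode
is recorded in the result. Self-edges and duplicate undirected edges are
dropped on load. `hypergeometric_overlap()` gives the upper-tail overlap
p-value; the universe defaults to the genes present in the expression table
in pipeline use and is always explicit in the API. `ranksum_compare()` is
the unpaired two-sided Wilcoxon test, exact by enumeration for untied
samples of ≤ 10 each and the tie-corrected normal approximation otherwise.

qPCR quantification uses the pure ΔCt method with amplification efficiency
fixed at 2 (as in the source): fold change = 2^−ΔΔCt against a reference
transcript, with technical-replicate ΔCt values averaged *before*
exponentiation (the order matters; averaging fold changes would bias
upward). Fluorescence quantification divides median signal by median marker
intensity per segmented object, excluding zero-marker objects with a reason.

## Synthetic data: what it emulates and what it does not

Every pipeline input has a generator with planted, exhaustively logged
ground truth, so the chain is testable end to end without any external data.

* **Plates** (`simulate_plate_set()`): colony sizes are baseline ×
  per-plate log-normal multiplier (plate effects) × border boost (edge
  effects) × strain factor × log-normal noise parameterized by its CV.
  Colony sizes are arbitrary units, as the sizes emitted by colony-imaging
  tools carry no absolute scale. Multiplicative log-normal noise keeps
  colonies positive and makes the CV interpretable. Planted suppressors are
  boosted only on the drug plate, so the no-drug small-colony filter is
  untouched; the boost is calibrated as 1 + effect × cv_fitness with
  cv_fitness = noise_cv × √(2 / replicate_sets), which makes the expected
  suppressor Z equal the requested displacement (the ratio picks up noise
  from both plates; block collapse averages `replicate_sets` colonies).
  With noise_cv = 0 that displacement would vanish, so a fixed 5% boost per
  Z unit keeps planted truth separable in noiseless runs. Defaults mirror
  the study design: 32 × 48 quadruplicate arrays, three replicate plates,
  20-suppressor plantings at Z = 2.5 with noise_cv = 0.15 in the validation
  runs.
* **Expression** (`simulate_expression_table()`): null genes draw
  log2 ratios from N(0, 0.25) and p from Uniform(0, 1); planted genes draw
  a ±2 log2 shift and p from Beta(a, 1), the standard one-parameter
  alternative. The default a = 0.01 gives per-timepoint detection power
  ≈ 0.94 under BH at q < 0.05 with 5% planted genes in 1000 — strong but
  not trivial alternatives, so joint consecutive-timepoint recovery is a
  meaningful test (≈ 0.93 expected recall). Planted consecutive genes are
  up at every HU timepoint and null untreated. With null_log2_sd = 0 the
  table is deterministic (planted p = 1e-9, null p = 1) so planted sets are
  recovered exactly in closed-loop checks; those checks also set the
  scattered DE fractions to zero so the planted intersection is the whole
  truth.
* **Growth** (`simulate_growth_curves()`, `simulate_synergy_curves()`):
  three-parameter logistic curves (K = 1.5 OD, r = 0.35 h⁻¹, 2 h lag,
  15-minute sampling over 24 h) with additive Gaussian OD noise truncated
  at zero. A planted fitness value scales the growth rate for shape and the
  curve is then rescaled so the realized trapezoid-AUC fitness equals the
  planted value exactly; planted fitness is therefore *defined* on the AUC
  scale, which is what the downstream estimators measure. Doubles are
  planted at the product of singles plus epsilon; synergy grids at the
  product of single-drug fitness plus the planted deviation.
* **Networks** (`simulate_interaction_network()`): Erdős–Rényi background
  with within-module edge probability multiplied by the enrichment factor;
  no self or duplicate edges.

What the generators do **not** emulate: spatial gradients within plates
beyond a uniform border boost, colony-size dependence between neighbours,
count-based DE statistics (p-values are modelled directly, not derived from
reads), diauxic or multi-phase growth, and dose–response curvature beyond
the planted grid values. Passing tests therefore demonstrate that the
estimators recover what the models plant under realistic noise — not that
the models capture every artefact of real arrays or readers.

## Validation summary and problem sizes

The test suite exercises, among others: exact agreement of BH,
hypergeometric, rank-sum and t-test results with independent
enumeration/closed-form oracles (100 randomized small instances each);
screen recovery under the study conditions (20 planted suppressors,
Z = 2.5, noise_cv = 0.15, three replicates, full 1536 format) with recall
≥ 0.90 and false-positive rate ≤ 0.05 averaged over 20 simulated screens;
noiseless closed loops in which the candidate funnel, interaction epsilons
(to 1e-6) and the synergy grid equal planted truth; uniformity of null
enrichment and rank-sum p-values (Kolmogorov–Smirnov at α = 0.01 over 100
simulated networks of 500 genes at density 0.1, where the binomial tail is
near-continuous); and the per-family false-discovery proportion of the DE
caller under the global null staying at the nominal 5% within binomial
sampling error over 50 seeds. These problem sizes keep the full suite and
the reproduction script to a couple of minutes on a single core while
leaving the Monte-Carlo estimates well-determined.

## Known limitations

* The exact small-colony cutoff and the fitness-vs-size Z-score choice of
  the original analysis are unrecoverable from its description; both are
  configurable and the defaults are stated above.
* Epsilon pairing of single-mutant replicates in index order assumes
  replicates are exchangeable across strains; the all-pairs option relaxes
  this at the cost of non-independent expected values.
* The synergy model is Bliss independence only; Loewe additivity and
  dose-response fitting are out of scope.
* Gene identifiers are opaque strings; no alias resolution is attempted.
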