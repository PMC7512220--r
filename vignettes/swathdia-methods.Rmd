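---
title: "Methods: SWATH/DIA quantification, stratification and classification in swathdia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SWATH/DIA quantification, stratification and classification in swathdia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swathdia)
```

swathdia implements the computational core of a SWATH-MS (DIA) case/control
proteome study on PBMC samples: fragment-ion intensities are rolled up to
protein intensities, normalized and replicate-averaged; differential
abundance is assessed per protein with a two-sample t-test and a
p-value/fold-change threshold grammar; unsupervised PCA stratifies the
cohort and isolates the case subgroup that actually separates from
controls; a principal-component logistic regression, validated by
leave-one-out cross-validation (LOOCV) and a label-permutation test,
quantifies how well the proteome predicts disease status; and a
size-matched random-panel test asks whether an annotated protein set (for
example, mitochondrial proteins) is *specifically* predictive. A
fragment-level synthetic cohort generator with known ground truth makes
every stage testable.

This vignette records the model assumptions, the parameters that matter,
and the design decisions taken where the methodology was genuinely open.

## Quantification model

**Rollup.** A protein's intensity in a run is the sum of the peak
intensities of its 6 strongest fragment ions from each of its 10 strongest
peptides. "Strongest" is not self-defining, and we fix it as the
*cross-run summed intensity*, computed once per protein: a peptide's
strength is the sum of all its fragment intensities over all runs, a
fragment's strength its own cross-run sum. Selecting per-run instead would
let different features quantify different runs and make columns
incomparable. Ties in strength are broken by lexicographic feature
identifier so the selection is deterministic. Fragments missing from a run
contribute zero to the sum — in extraction-based DIA quantification the
absence of a matched peak is a measurement of (approximately) zero
intensity, not an unknown; the choice is deliberate and flagged for
sensitivity analysis, since re-extraction behavior of the original
toolchain is not documented. A protein with *no* observed selected
fragment in a run receives 0 with a warning.

**Normalization.** Total-sum ("global") normalization rescales every run
so all run totals equal the mean of the original totals. The mean (rather
than 1) keeps values on the instrument's intensity scale; any positive
target is equivalent downstream because every later stage is either
scale-free or ratio-based. Within-run ratios are preserved exactly. A run
with zero total intensity is a degenerate input and is rejected by name.

**Replicate averaging.** Technical replicates (triplicates in the study
design) are collapsed by the arithmetic mean into one column per sample.
All statistics run on the averaged matrix.

One property worth knowing: total-sum normalization is compositional. If
the planted (or real) differential proteins do not balance exactly, the
normalization transfers a small group-correlated global factor onto *all*
proteins. On strongly separated synthetic cohorts this lets even random
protein panels classify above chance — visible in the specificity test as
ties at zero LOOCV errors, which is why that test also carries a tie-aware
log-loss statistic.

## Differential abundance

Per protein, a two-sided two-sample Student t-test with pooled variance
compares case and control averaged intensities. The original toolchain's
test scale is not documented; we compute the statistic on log10
intensities by default because MS intensities are approximately log-normal
and the companion effect size is defined in log10 units. Both choices are
switchable (`log_transform = FALSE`, `var_equal = FALSE`) for sensitivity
checks. The reported effect is always `log10(mean_case / mean_control)` of
the linear-scale averaged intensities.

Two filters form the reporting grammar, both with strict inequalities:

* primary: p < 0.01 and log10 fold-change > 0.2 or < −0.2;
* relaxed: p < 0.05 and fold-change > 1.3 or < 0.75.

No multiple-testing correction is applied on the primary path — the
grammar is raw-p by design, mirroring discovery-stage practice for this
kind of small-cohort study — but Benjamini–Hochberg q-values are always
attached as an informational column.

**Rounded published tables.** When the filter is applied to a *published*
table transcription, the effect columns have been rounded to 2 decimals,
and a value printed exactly at a gate (0.20 against a `> 0.2` gate) may
well have passed before rounding. `apply_filter(..., rounding = 0.01)`
gives every strict comparison half-quantum slack for exactly this case.
Computed values use `rounding = 0` (the strict grammar). The fixture
consistency checker applies the same logic and compares `10^log10_fc`
against the printed fold-change at a 2% *relative* tolerance, since the
two columns were rounded independently.

## PCA stratification

The averaged matrix (samples as rows) is square-root transformed, each
protein mean-centered and divided by the square root of its standard
deviation (Pareto scaling — the standard compromise between no scaling and
unit-variance scaling for MS data; both steps independently switchable).
The decomposition is an SVD computed through the sample-space
crossproduct, since samples are few and proteins many; tests verify it
against a covariance eigendecomposition oracle. Percent variance is of the
total transformed-scaled variance. Numerical conventions: component signs
are fixed by making the largest-magnitude loading positive;
proteins with zero variance after the transform are dropped from the
decomposition (with a warning) but stay in the matrix; eigenvalues below
`max(d) * 1e-12` are treated as null space.

**Subgroup selection.** The original analysis selected the separating case
subgroup by visual inspection of the score plot. Reproducibility demands
an algorithmic rule, so swathdia replaces inspection with a deterministic
2-means partition of the score coordinates on components 1–2: centers are
initialized at the two samples with extreme PC2 scores (the axis on which
the subgroup separates) and run to convergence. The cluster holding the
majority of controls is "control-like"; cases in it are the excluded,
signal-free cases. The rule and its parameters are recorded in the
assignment's `method_record`. Cluster quality is summarized by the mean
silhouette width; below 0.5 — the conventional boundary under which
2-cluster structure is considered weak or artificial — the assignment is
flagged unstable and the excluded set should not be interpreted. On
synthetic cohorts with the planted 9-of-11 structure the silhouette sits
around 0.7–0.8; on null cohorts around 0.25–0.5.

## Classification and permutation inference

Samples are represented by their first k = 3 principal component scores
and classified by logistic regression. Two leakage policies are
first-class, because the original description is ambiguous about whether
the PCA was refitted within cross-validation folds:

* `refit_per_fold` (default): the Sqrt/Pareto PCA is refitted on each
  fold's 19 training samples and the held-out sample is projected with the
  training center/scale/loadings — no information leakage;
* `global`: the PCA is fitted once on all samples and only the regression
  is refitted per fold, matching the most literal reading.

The choice is recorded in the result object and in pipeline outputs.

**Ridge penalty.** Twenty-sample folds in a k-dimensional score space
frequently separate perfectly, where maximum-likelihood logistic
coefficients diverge. The fit therefore always uses a fixed small ridge
penalty, λ = 1e-3, on the slope coefficients (never the intercept), with
PC scores standardized within each training fold so the penalty scale is
comparable across folds and cohorts. Applying it always — not only upon
detected separation — keeps per-fold models comparable. The decision
threshold is fixed at probability 0.5.

**Permutation test.** The null distribution of the LOOCV error count is
built by shuffling case/control labels over samples (preserving group
sizes) and re-running the complete LOOCV per shuffle. "As extreme or more"
means a null error ≤ the observed error. When the number of distinct
label arrangements `choose(n, n_cases)` is at most 20000, all arrangements
are enumerated and the p-value is exact — the fraction of arrangements,
the observed one included, performing as well or better. Otherwise 2000
random shuffles (by default) give the add-one-smoothed estimate
`(1 + #{null ≤ observed}) / (B + 1)`, which can never be exactly zero. At
the study design (20 samples, 11 cases) there are 167960 arrangements, so
the sampled path is the operative one. Because PCA is unsupervised, the
per-fold score geometry is computed once and shared across all
permutations; only the penalized regression is refitted, which makes the
test cheap without changing its value.

## Panel specificity test

For an annotated panel (say, all mitochondrion-flagged proteins), the
matrix is restricted to the panel and the LOOCV error recomputed; the same
is done for `n_draws` random panels of the same size drawn uniformly
without replacement from the *non-flagged* proteins ("other" proteins;
drawing from all proteins is available as a sensitivity switch). The
one-sided empirical p is the add-one-smoothed fraction of random panels
doing as well or better on error count. Because error counts are small
integers that tie easily — especially under the compositional leakage
noted above — the mean held-out log-loss is reported alongside as the
tie-aware secondary statistic.

## The synthetic cohort generator

The generator emulates the study's design at fragment-ion resolution, and
its defaults are the study conditions: 11 cases and 9 controls in
technical triplicate, a 9-of-11 case subgroup carrying the signal (the two
remaining cases are drawn from the control distribution, reproducing the
geometry in which two patients co-cluster with controls), 2970 proteins
with 99 planted differential proteins, effect magnitudes uniform in
0.2–0.5 log10 units with half the effects increases, fragment-level
biological CV 0.20, technical replicate CV 0.10, per-run depth factor with
sd 0.10 log10 units (what normalization must remove), and 5% missing
fragments per run. Where the study reports no value (feature-tree shape,
noise magnitudes), values were chosen once as typical for SWATH-style data
and not revisited.

Mechanically: expected log10 intensity of a fragment is the sum of a
protein baseline (normal, mean 5, sd 1 in log10), a peptide ionization
term (sd 0.5) and a fragment share (sd 0.4) — exponentiation makes
intensities long-tailed, so top-N feature selection is non-trivial.
Planted effects shift all fragments of a differential protein in
signal-carrying case samples. Replicate runs share the sample-level
expectation and add technical noise and the run depth factor; linear-scale
CVs are converted to log-normal sigma by `sqrt(log(1 + cv^2))`. Missing
fragments are *absent rows*, not zeros, forcing the downstream
missing-data policy to be explicit. One seed drives everything through a
per-stage stream split, and standard-normal draws are scaled (rather than
drawn at parameter sd) so that setting a spread parameter to zero does not
desynchronize the stream — cohorts differing only in one parameter are
otherwise draw-for-draw identical.

What the generator does **not** emulate: identification dropout between
spectral library and quantified set, m/z or retention-time structure,
peak-boundary errors, correlated protein modules, batch drift within runs,
or heavy-tailed outlier samples. Passing tests therefore demonstrate
correctness of the pipeline's algorithms and calibration under a clean
log-normal world, not robustness to every artifact of real instrument
data.

## Problem sizes in tests and the acceptance script

Test cohorts use the study's sample design (11/9 in triplicate) with
reduced feature counts — typically 120–200 proteins, 3 peptides per
protein, 4 fragments per peptide — which keeps the full suite fast while
leaving every code path (selection, missingness, degenerate cells)
exercised. The acceptance script runs the headline analysis at the full
2970-protein scale with the reduced feature tree, 1999 permutations and
100 random panels, and estimates the subgroup recovery rate over 30
independent cohorts of 200 proteins.

## Known limitations

* The t-test assumes (log-scale) normality and equal variances; no
  moderated/empirical-Bayes variance estimation is offered, matching the
  method being reproduced rather than current best practice.
* Raw-p filtering ignores multiplicity; q-values are informational only.
* The 2-means subgroup rule assumes exactly two clusters; more complex
  cohort structure will be folded into them.
* Total-sum normalization is compositional (see above); strongly
  unbalanced differential signal bleeds a small global factor into all
  proteins.
* The exhaustive permutation p and the sampled (+1-smoothed) p differ by
  design near their lower bounds; results record which path produced them.
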