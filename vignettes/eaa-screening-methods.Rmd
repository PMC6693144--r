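---
title: "Methods: screening for epigenetic age acceleration in blood methylomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening for epigenetic age acceleration in blood methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eaascreen)
```

## The problem

Linear epigenetic clocks predict an "epigenetic age" (DNAmAge) from the
methylation fractions (beta values) of a fixed set of CpG probes. In a cohort
of patients with a developmental disorder, the question is whether their
blood epigenome is systematically older or younger than expected for their
chronological age. `eaascreen` implements that screen end to end for
450K-style array data: clock evaluation, correction of technical and
cell-composition confounders, per-disorder hypothesis tests, and the
downstream characterization of the methylation changes involved (entropy,
mitotic scores, differentially methylated positions, genomic context).

## The model

**Age transform.** Clocks of the Horvath family work on a transformed age
scale: `F(age) = log((age+1)/(adult_age+1))` below the anchor age
(`adult_age`, 20 years) and `(age - adult_age)/(adult_age+1)` above it. `F`
is continuous with continuous derivative `1/(adult_age+1)` at the anchor;
`transform_age()` / `inverse_transform_age()` implement the pair exactly.
A clock is `raw = intercept + sum_j w_j beta_j`, mapped to years by the
inverse transform (`evaluate_clock()`).

**Control models.** The central estimator (`control_model()`, with
`eaa_model()` for DNAmAge) is an ordinary least-squares fit on healthy
controls:

```
DNAmAge ~ Age + Sex + PC1 + ... + PCK                       (without CCC)
DNAmAge ~ Age + Sex + Gran + CD4T + CD8T + B + Mono + NK
          + PC1 + ... + PCK                                 (with CCC)
```

Controls receive their residuals as epigenetic age acceleration (EAA); cases
receive observed minus predicted under the control coefficients, without
refitting. Calibration is summarized by the median absolute control residual
(MAE, years). The same machinery with the response swapped gives entropy and
mitotic-score acceleration (`fit_acceleration()`).

**Technical PCs.** Array control probes carry only technical variance, so
principal components of their raw intensities (centered, not scaled;
`fit_control_pca()`) act as batch covariates. The number of PCs is chosen at
the scree elbow: the point with maximum perpendicular distance to the chord
joining the first and last scree points (`choose_n_pcs()`), ties broken
toward fewer PCs, with a manual override for users who want a fixed K (17 is
the appropriate value for the large multi-batch blood compendium this
methodology was developed on).

**Cell composition.** Reference-based deconvolution
(`estimate_cell_composition()`) minimizes `||beta - R p||^2` subject to
`p >= 0` and either `sum(p) <= 1` (default, matching common Houseman-style
implementations) or `sum(p) = 1`. No quadratic-programming dependency is
used: the relaxed problem is solved by nonnegative least squares and, when
the sum constraint binds, the simplex-face optimum is found exactly by
enumerating active sets and solving each KKT system (deterministic, exact
for the at-most-15 cell types supported; blood panels use 6).

**The screen.** Disorders enter with at least 5 samples of which at least 2
are adults (`filter_disorders()`). Case EAA distributions are compared with
control EAAs by a two-sided Wilcoxon rank-sum test; p-values are Bonferroni
multiplied by the number of disorders tested in the current run and flagged
at alpha = 0.01. The exact null distribution is enumerated when the smaller
group has at most 10 observations and there are no ties; otherwise the
normal approximation with continuity correction is used. The
`EAA ~ Age` slope within a group (`eaa_age_slope()`) supports leave-one-out
sensitivity checks.

**Entropy and mitotic score.** Shannon methylation entropy is the normalized
mean binary entropy of the betas, 1 at beta = 0.5 and 0 at beta in {0, 1};
terms at exactly 0 or 1 use the `0 log 0 = 0` convention rather than epsilon
clipping, which keeps the boundary values exact (an optional clip exists for
noisy inputs). The mitotic score (`pcgt_age()`) is the unweighted mean beta
over a fixed probe set. Both are fit with the with-CCC acceleration model.
Entropy is highly sensitive to batch structure, especially over small probe
sets; results should be compared within batches before interpretation.

**DMPs.** `find_dmps()` fits, per probe, `beta ~ Age + Sex + cells + PCs`
(aging, on controls) or `beta ~ Disease_status + Age + Sex + cells + PCs`
(case/control), extracting the target coefficient and its two-sided t-test
p-value, Bonferroni-corrected over the probes actually tested. The models
are plain OLS with per-probe variance — no empirical-Bayes moderation — so a
probe's test depends only on its own data. Directions follow the coefficient
sign (case = 1 coding, so probes hypomethylated in the disorder are
negative). Direction-stratified intersections (`intersect_dmps()`) partition
the shared universe; the hypo-hypo subset (hypomethylated both with age and
in the disorder) is the one of main mechanistic interest.
`fit_clock_site_profiles()` adds an `Age^2` term to capture the curvature of
clock-site trajectories and reports per-case deviations on the beta scale.

**Annotation.** Continuous tracks are summarized as the per-base mean in a
+/-200 bp window around each CpG (401 bases; uncovered bases inside the
track extent count as 0, the bedGraph sparsity convention, with a
covered-bases-only mode available), then z-scored with the sample sd;
replicates aggregate by the mean of z-scores (NFC), and RNA strand tracks
combine as `log2(1 + sur+ + sur-)` before scaling (NRE). CpG-island context
uses boundary distances: island inside, shore at 0-2 kb (2 kb inclusive),
shelf at 2-4 kb (4 kb inclusive), open sea beyond. Enrichment uses the 2x2
table of subset vs universe-minus-subset; the two-sided Fisher p sums
hypergeometric point probabilities no larger than the observed table's
(stated because two-sided Fisher conventions differ), and the reported odds
ratio is the sample OR, Haldane-corrected (+0.5 everywhere) only when a cell
is zero. Strand is ignored throughout: CpG sites are treated as coordinates.

## The synthetic cohort generator

`simulate_cohort()` produces data with the statistical structure the
analysis assumes, plus a full ground-truth record, so every stage can be
tested by parameter recovery rather than against fixtures:

* **Clock probes** are bounded *linear* functions of a per-sample
  transformed-age score `s = F(age) + (delta + batch offset)/(adult_age+1) +
  noise`, with coefficients chosen so the bundled clock definition inverts
  the construction exactly: noise-free cohorts evaluate back to
  chronological age to numerical precision. A logistic squash would be
  marginally more array-like but cannot be inverted exactly by a linear
  clock, and the exact-inversion contract is what makes construction oracles
  possible.
* **Acceleration** `delta` (years) is injected on the transformed scale as
  `delta/(adult_age+1)`, which equals a years-scale shift of exactly `delta`
  above the anchor age. "X years accelerated" is ambiguous for children
  (the transform is logarithmic there); case ages therefore default to
  20-55, where median EAA = delta holds exactly.
* **Noise** is injected on the transformed scale with sd
  `resid_sd_years/(adult_age+1)` (default 2 years): adult residuals have
  exactly the configured years-scale sd, child residuals shrink with the
  slope of the inverse transform, and DNAmAge stays above -1 without
  truncation.
* **Batch structure**: equally spaced years-scale offsets scaled to the
  configured sd (deterministic spacing guarantees separation at any seed),
  plus per-batch control-probe intensity mean vectors strong enough that the
  top PCs recover batch membership.
* **Cell composition**: mean proportions drift linearly with age (granulocytes
  up, lymphocyte subsets down) with Dirichlet noise; cell-sensitive probes
  are convex mixtures of a bundled purified-cell reference.
* **DMPs**: aging DMPs drift linearly at the configured slope *toward* 0.5
  (hypermethylating sites start low, hypomethylating sites start high), the
  erosion pattern that makes genome-wide entropy rise with age; disease DMPs
  shift in cases of the first-named disorder only. Null probes follow the
  bimodal beta distribution of real arrays.
* **Annotation**: one synthetic chromosome with non-overlapping enhancer,
  gene-body and CGI blocks; hypomethylated DMPs fall inside enhancers at a
  designed odds ratio (default 4) against a base rate of 0.1.

What the generator does **not** emulate: probe-type chemistry, SNP-affected
and cross-reactive probes, spatially correlated methylation, non-linear
batch-by-age interactions, and the absolute level of methylome entropy
(directions and orderings are reproduced; absolute entropy means are higher
than on real arrays because the simulated beta distribution is simpler).
Passing recovery tests therefore demonstrates the correctness of the
estimators under the stated generative model, not performance on real data.

## Numerical and design choices

* Default counts used throughout the tests: 300 controls (ages 0-55), 20
  cases per disorder (ages 20-55), 30 clock probes, 120 aging + 68 disease
  DMPs, 60 cell probes, 250 null probes, 120 control-probe features, 3
  batches. These sizes keep any single check within seconds while leaving
  every test statistic far from its decision boundary.
* PCA signs are fixed by making each loading's largest-magnitude entry
  positive, so scores are reproducible across BLAS implementations.
* Under sum-to-one compositions one cell-type column is dropped from model
  designs (reported via message) to keep the design full rank; screen
  results are invariant to which column is dropped.
* Rank-deficient designs are an error naming the collinear columns;
  zero-variance probes are excluded from DMP scans with a message, and the
  Bonferroni divisor is the number of probes actually tested.
* Missing betas are excluded pairwise; entropy and clock results report the
  per-sample probe count or coverage used, and clock evaluation warns
  whenever coverage is below 1 because missing probes offset predictions.
* The QC intensity statistic raises zeros to a configurable floor (default
  1) before log2; upstream handling of zero intensities is not standardized,
  so the floor is explicit.
* Published clock coefficient sets are input files
  (`read_clock_definition()`), not embedded constants; only synthetic clocks
  ship with the package. No internal renormalization of betas is performed,
  so predictions from published clocks may carry an offset — present in both
  cases and controls, hence harmless to the screen.

## Known limitations

* Batch offsets injected on the transformed-age scale have a years-scale
  effect attenuated by `(age+1)/(adult_age+1)` in children, while the
  control model corrects with one constant coefficient per PC. Correction is
  therefore exact only above the anchor age; on cohorts spanning childhood a
  residual batch-by-age interaction remains (an `Age x PC` interaction term,
  which the standard model does not include, would be needed). The
  batch-correction recovery experiment accordingly uses an adult cohort, and
  a separate check verifies that PCs never increase the MAE on full-age
  cohorts.
* Case EAA uses control-model coefficients without refitting and without
  prediction intervals; a control set whose age range does not match the
  cases induces systematic case EAA even under the null — match age ranges
  before screening.
* Exact Wilcoxon enumeration is capped at the smaller group size of 10; above
  it (or under ties) the continuity-corrected normal approximation is used.
* The active-set deconvolution solver is exponential in the number of cell
  types and is capped at 15; it is exact and deterministic within that range.
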