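---
title: "Metabolic fingerprinting of biofluids: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic fingerprinting of biofluids: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluidprint)
```

## Overview

`fluidprint` implements an untargeted ^1^H-NMR metabolic-fingerprinting
pipeline for urine, plasma, and cerebrospinal fluid (CSF): biofluid-specific
spectral bucketing, supervised PCA/CA classification validated by
Monte-Carlo cross-validation (MCCV), per-bin Kruskal–Wallis screening, and
quantitative metabolite-set enrichment analysis (QEA). A synthetic-cohort
generator produces Lorentzian-lineshape spectra with matched metabolite
concentration tables for three-class severity designs (`HEALTHY`, `G12.0`
severe, `G12.1` mild-to-moderate — the ICD-10 grouping used in spinal
muscular atrophy), so every stage can be exercised and calibrated without
patient data. This vignette is the package's account of what each stage
computes, the tunable parameters and their defaults, and the numerical and
design choices made where conventions were open.

## The synthetic cohort generator

### Spectra

A simulated spectrum is a sum of unit-area Lorentzian lines plus white
Gaussian noise:

$$ I(\delta) \;=\; \sum_m c_m \sum_{k \in \mathrm{peaks}(m)} w_{mk}\,
\frac{\gamma_{mk}/\pi}{(\delta - \delta_{mk})^2 + \gamma_{mk}^2}
\;+\; \varepsilon(\delta), \qquad \varepsilon \sim N(0, \sigma^2), $$

where $c_m$ is the metabolite concentration (mmol/L), $w_{mk}$ the
normalized relative multiplet intensities ($\sum_k w_{mk} = 1$), and
$\gamma_{mk}$ the half width at half maximum. Because the lineshapes have
unit area, each metabolite contributes total spectral area equal to its
concentration — which is what makes region integrals meaningful for the
downstream bucketing. Lorentzian (pure absorption) lineshapes are the
first-order physical model for liquid-state NMR; the choice versus
Gaussian/Voigt is immaterial at 0.01-ppm bucket resolution.

The default axis is 0–10 ppm at 9,000 points (≈0.0011 ppm per point), so
a 0.01-ppm bucket averages at least 9 grid points. The default linewidth in
the bundled library is 0.004 ppm FWHM (≈2.4 Hz at 600 MHz), about four
grid points across — deliberately on the broad side of realistic so the
discrete quadrature sees every line.

### Cohorts

Per-sample concentrations are drawn log-normally around
`base_concentration × fold_change`, with a configurable log-scale standard
deviation (`conc_sdlog`, default 0.25). Log-normal noise is the natural
model for concentrations: positive, right-skewed, multiplicative. Class
effects are multiplicative fold-changes per metabolite; `HEALTHY` is always
at fold 1.

For urine, a per-sample dilution factor drawn uniformly from (0.3, 3)
multiplies the whole concentration vector before both the table and the
spectrum are produced, emulating spot-urine concentration variability.
This makes the urine scaling step downstream *necessary* (raw urine bucket
rows differ by up to 10× between samples) and *testable* (after
min-baseline scaling they must agree exactly).

The bundled library holds 30 metabolites commonly quantified in biofluid
NMR panels with literature-plausible (not spectroscopically exact) shift
positions and per-fluid base concentrations; positions are mutually
distinct and documented in `default_metabolite_library()`. Creatinine is
always present so urine tables support creatinine normalization.

What the generator does **not** emulate: J-coupling fine structure and
peak-position drift with pH/ionic strength (so no alignment step is needed
or provided), the broad protein/lipoprotein background of plasma, baseline
roll, and instrument artifacts other than the water/EDTA regions injected
by `inject_artifacts()`. Consequently, passing tests demonstrate the
*statistical machinery* is correct and calibrated — not that real spectra
of a given disease would classify at any particular accuracy.

## Spectral bucketing

`default_binning_config()` encodes the three biofluid dialects:

| fluid  | scaling                      | range (ppm) | width | exclusions |
|--------|------------------------------|-------------|-------|------------|
| urine  | min-baseline over 1.0–4.3    | 0.8–9.0     | 0.01  | 4.5–6.5 |
| plasma | absolute concentration       | 0.3–10.0    | 0.01  | 3.04–3.31, 3.59–3.66, 4.5–5.5 |
| CSF    | absolute concentration       | 0.8–4.55    | 0.02  | 4.5–6.5 |

The exclusions remove the residual water signal (all fluids) and the EDTA
chelate signals of plasma collected in K^+^-EDTA tubes.

Numerical conventions, stated once:

* **Bins** are consecutive left-closed/right-open intervals
  $[\mathrm{low} + kw, \mathrm{low} + (k+1)w)$ on an ascending ppm grid; a
  trailing partial interval is dropped (the CSF range 0.8–4.55 is not a
  multiple of 0.02, leaving a 0.01-ppm remainder that is discarded rather
  than padded). Columns are reported in ascending ppm order regardless of
  the display convention.
* **Bin values** are trapezoidal integrals of the intensity over the
  interval, computed by splitting the grid at every bin edge — exact for
  the piecewise-linear interpolant on any grid, so the sum of bin values
  equals the integral over the binned range to machine precision
  (conservation), and binning is exactly linear in the spectrum.
* **Exclusion rule**: a bin is removed if it overlaps an exclusion
  interval with positive length (not center-in-region), guaranteeing zero
  artifact leakage. A 10⁻⁹-ppm tolerance ignores floating-point slivers
  where accumulated bin edges touch an exclusion boundary.
* With these rules the dialects retain **620** (urine), **836** (plasma),
  and **185** (CSF) bins.

"Minimum baseline scale" for urine is implemented as: subtract the 5th
percentile of the intensity inside the scaling region (a robust baseline
floor; percentile configurable), then divide the whole spectrum by the
integral of the floored signal over 1.0–4.3 ppm, making that integral 1.
Any global multiplicative dilution factor then cancels exactly — this is
the stated purpose of the step, and the property is asserted to 10⁻⁹ in
the tests. Whether the original procedure normalized by an integral or a
vector norm is not determinable from its one-line description; the
integral convention is flagged here as the package's choice, and
`scaling_mode` is extensible. The 4.5–4.55-ppm sliver where the CSF range
meets the water exclusion is removed by the overlap rule.

Degenerate inputs: an all-zero (or negative-integral) scaling region is a
hard error ("degenerate scaling region"), never a silent division; an axis
not covering the bucketing range errors with the gap; per-sample failures
in `build_bucket_table()` abort naming the sample.

## PCA/CA classification with MCCV

`fit_pca()` mean-centers columns (no unit-variance scaling: buckets share
an intensity scale, and autoscaling would inflate noise bins) and takes the
SVD basis. The retained dimension is the smallest count reaching a
cumulative explained-variance threshold (default 0.95, configurable and
surfaced everywhere), capped at $\min(n-1, p)$.

`fit_canonical()` solves the between- versus within-class generalized
eigenproblem on PC scores. Directions are normalized to unit pooled
within-class variance ($a^\top S_w a = 1$), so Euclidean distance in
canonical space is the within-class Mahalanobis distance — the metric the
nearest-center rule should use. The discriminant dimension is selected by
sequential MANOVA tests on residual Wilks' $\Lambda$ with the Bartlett
chi-square approximation: dimension $k+1$ is retained while the test of
"no separation beyond $k$ directions" rejects at `alpha` (default 0.05).
On null data the first-dimension p-value is uniform; the tests verify the
rejection rate at 200 simulated datasets. When the within-class scatter is
ill-conditioned (condition number > 10¹⁰, as happens when bins ≫ samples
before PCA reduction), a ridge $10^{-6}\,\mathrm{tr}(W)/p \cdot I$ is
added with a warning. Each basis vector's largest-magnitude coefficient is
made positive for reproducible output.

Two classification rules are provided: `nearest_center` (assign to the
closest class center in canonical space — the default, as the final
prediction rule) and `knn` (majority vote among the k nearest training
projections, default k = 5). Ties are broken by class-label lexicographic
order and flagged in the output. One deliberate deviation from a literal
reading of the dimension-selection contract: *classification* always uses
at least one canonical direction (`min_dim = 1`) even when the MANOVA
selects zero. With zero directions every sample would project to a single
point and the nearest-center rule would collapse to the lexicographically
first class — structurally biasing null-calibration runs. The fitted
`n_canonical = 0` (with warning) is still reported.

`mccv()` repeats, per iteration: a stratified random split holding out
`test_fraction` (default 0.2) of each class, a **full refit** — centering,
PCA, and CA estimated on the training portion only, so no information from
held-out samples leaks into the model — classification of the held-out
samples, and pooling of truth × assignment counts. Defaults are 500
iterations (100 in the bundled calibration tests, which is enough for the
3-SE bands used there); splits leaving a class with fewer than 2 training
samples are redrawn and counted. The pooled counts give the confusion
matrix whose row-normalized diagonal is the per-class probability of true
classification; pooled sensitivity/specificity against a chosen positive
subset are derived from the same counts.

A calibration note: pooled held-out counts reuse the same samples across
iterations and are strongly correlated, so chance-level bands for the
diagonal are computed with the binomial standard error at the number of
*distinct samples per class* (the exchangeable units), not at the pooled
count. With 20 samples per class the 3-SE band around 1/3 is ±0.32.

The end-to-end two-class pipeline with all PCs retained is mathematically
Fisher's linear discriminant; the tests assert equality (projections up to
sign/scale, assignments identical) against a brute-force LDA oracle
implemented independently in the test helpers.

## Univariate screening

Every retained bin is tested with the Kruskal–Wallis H test (tie-corrected,
chi-square p with groups − 1 degrees of freedom, delegated to
`stats::kruskal.test`); the all-identical-values case is defined as H = 0,
p = 1 (no information). **No multiple-testing adjustment is applied by
default** — bins are flagged at the raw per-bin p < 0.05 level, matching
the conventional highlighting of fingerprint screens; a Benjamini–Hochberg
option (`adjust = "BH"`) is available and its absence from the default is
deliberate and documented. Per-group medians and 5–95% percentile bands
use linear-interpolation quantiles (type 7); the convention matters at
small n and is stated here once. The screen is per-bin; aggregating to
coarser spectral regions is a possible extension, not implemented.

## Quantitative enrichment analysis

Normalization follows the biofluid: urine concentrations are divided by
same-sample creatinine (reported as mmol/mol creatinine; the creatinine
column is then dropped), plasma/CSF are used as absolute mmol/L; all are
then autoscaled per metabolite (mean 0, SD 1). Zero-variance metabolites
are dropped with a warning.

For a metabolite set with member matrix $X$ (samples × m, autoscaled) and
centered two-class outcome $z$, the global-test statistic is

$$ Q \;=\; \frac{z^\top X X^\top z}{m \, \hat{z}^2}, \qquad
\hat{z}^2 = z^\top z / n, $$

the average squared member–outcome covariance on the standardized scale.
$Q$ depends on $X$ only through $XX^\top$, so it is invariant to member
order and sign flips (asserted as a property test). The p-value uses an
outcome-permutation null, $p = (1 + \#\{Q_\pi \ge Q_{\mathrm{obs}}\}) /
(1 + n_\pi)$ with 1,999 permutations by default — exact at any sample size
with no distributional assumptions. The **enrichment ratio** is defined
as $Q_{\mathrm{obs}} / \mathbb{E}[Q_\pi]$ (observed over mean permutation
null), ≈1 on null data by construction; this definition is the package's
own, chosen so the dot-size quantity of the usual QEA summary plot is
reproducible from first principles, and may differ from other QEA
implementations. Three-class designs are analyzed pairwise; the default
contrast is the severe versus the mild class. Sets with fewer than 2
measured members (case-insensitive, punctuation-stripped name matching)
are skipped with a message.

A frozen GMT fixture of 30 KEGG-style human pathway sets (members drawn
from the bundled metabolite library) ships with the package so tests and
examples never touch the network; it is a synthetic stand-in for a live
pathway database, adequate for exercising the machinery but not for
biological interpretation. Venn overlaps across biofluids are exact
inclusion–exclusion region counts with membership lists; heatmap ordering
uses Euclidean distances between metabolite columns and average-linkage
leaf order.

## Baseline statistics

Numeric cohort variables are gated per group by Shapiro–Wilk at α = 0.05
(groups with fewer than 3 values are treated as non-normal): all-normal →
mean ± SD with a two-sample t-test; otherwise median (IQR) with
Mann–Whitney U (2 groups) or Kruskal–Wallis (>2 groups). Categorical
variables get counts and percentages of the group size. The Mann–Whitney
implementation reports U (pair counting via mid-ranks), the complement
U′ = n₁n₂ − U, and the rank-sum W, because published tables use all three
conventions without saying which; the two-sided p is by exhaustive
assignment enumeration for total n ≤ 8 (exact under ties) and the
tie-corrected, continuity-corrected normal approximation otherwise.

## Problem sizes in the bundled tests

The test-suite and acceptance-script study conditions, chosen once as
realistic desk-scale instances: null and strong cohorts use 20 samples per
class on the full 9,000-point axis with 100 MCCV iterations;
Kruskal–Wallis type-I calibration pools 600 independent null metabolite
columns (20 cohorts × 30 metabolites — table columns are independent by
construction, unlike bucket columns within a multiplet); global-test
calibration uses 200 replicates at 199 permutations; fold-change recovery
uses 50 samples per class. The strong-signal cohort is a severity
gradient: one five-metabolite pathway elevated 25-fold in the severe class
and 5-fold in the mild class at low spectral noise, which separates all
three classes along a single canonical axis. (An earlier down-regulation
design for the mild class was abandoned: a 5-fold *decrease* of
trace-level metabolites carries very little absolute spectral signal
relative to background biological variation, a real phenomenon worth
remembering when reasoning about detectability of down-regulation in
fingerprinting.)

## Known limitations

* No peak alignment, phasing, or baseline correction: the generator does
  not produce misaligned or rolled baselines, and real spectra must be
  preprocessed before `fluidprint` sees them.
* The asymptotic (non-permutation) global-test p-value is not implemented;
  permutation is the only null.
* Pathway annotation is name-based against a user-supplied GMT; no live
  database access, no topology/impact scoring.
* MANOVA dimension selection relies on the Bartlett chi-square
  approximation, which is anticonservative at very small n; the null
  calibration test bounds, but does not remove, this.
* The classifier offers exactly the PCA/CA/k-NN-or-nearest-center family —
  no probabilistic posteriors, ROC curves, or alternative learners.
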