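# fluidprint

Untargeted ^1^H-NMR metabolic fingerprinting of biofluids (urine, plasma,
cerebrospinal fluid), for studies that classify disease groups from whole
spectra rather than from named metabolites — e.g. severity stratification in
spinal muscular atrophy cohorts (`HEALTHY` vs. `G12.0`, the severe ICD-10
group, vs. `G12.1`, the mild-to-moderate group). The package is aimed at
analysts who have 1D spectra plus sample metadata and want the full
fingerprinting stack with honest validation, and at methodologists who want
a calibrated synthetic test bed for it.

## What it computes

* **Bucketing** — biofluid-specific spectral segmentation: urine scaled by a
  minimum-baseline rule over 1.0–4.3 ppm (removing spot-urine dilution
  exactly), then 0.01-ppm bins over 0.8–9 ppm excluding water (4.5–6.5 ppm);
  plasma 0.01-ppm bins over 0.3–10 ppm excluding EDTA (3.04–3.31,
  3.59–3.66 ppm) and water (4.5–5.5 ppm); CSF 0.02-ppm bins over
  0.8–4.55 ppm. Bin values are exact trapezoidal integrals; the dialects
  retain 620 / 836 / 185 bins respectively.
* **Classification** — PCA (SVD, mean-centered, cumulative-variance
  retention) followed by canonical discriminant analysis with the dimension
  chosen by sequential MANOVA tests on residual Wilks' Λ; assignment by
  nearest class center in the within-class Mahalanobis metric (or k-NN);
  validation by Monte-Carlo cross-validation with stratified splits and a
  full refit per split, pooled into a confusion matrix with derived
  sensitivity/specificity.
* **Screening** — per-bin Kruskal–Wallis H across groups with 5–95%
  percentile band summaries and the fraction of significant spectral
  regions.
* **Enrichment (QEA)** — creatinine normalization (urine) and autoscaling,
  then per pathway set the global-test statistic
  `Q = zᵀXXᵀz / (m·zᵀz/n)` with permutation p-values, enrichment ratios
  (observed Q over mean null Q), three-way Venn overlaps across biofluids,
  and Euclidean-distance heatmap ordering.
* **Baseline statistics** — Shapiro–Wilk-gated summaries (mean ± SD + t-test
  vs. median (IQR) + Mann–Whitney U / Kruskal–Wallis) and categorical
  count/percentage breakdowns.
* **Synthetic cohorts** — a generator of Lorentzian-lineshape spectra and
  matched concentration tables (log-normal biological variation, spot-urine
  dilution, water/EDTA artifacts, per-class fold-changes) that makes every
  stage testable and calibratable without patient data.

## Worked example

```r
library(fluidprint)

design <- read_cohort_design(system.file("extdata", "demo_design.yaml",
                                         package = "fluidprint"))
cohort <- generate_cohort(design)          # 20 urine samples per class
bt <- build_bucket_table(cohort$spectra)   # scale + bin, urine dialect
bt
#> <bucket_table> urine: 60 samples x 620 bins (0.81-9.00 ppm, width 0.01)

cm <- mccv(bt, cohort$metadata$class_label, n_iterations = 100, seed = 42)
cm
#> <confusion_matrix> truth (rows) x assigned (columns), proportions:
#>          assigned
#> truth     G12.0 G12.1 HEALTHY
#>   G12.0   0.787 0.212   0.000
#>   G12.1   0.065 0.752   0.182
#>   HEALTHY 0.000 0.288   0.713

scr <- screen_bins(bt, cohort$metadata$class_label)
sprintf("significant bins: %.1f%%", 100 * significant_fraction(scr))
#> "significant bins: 4.5%"

gmt <- read_gmt(system.file("extdata", "kegg_hsa_subset.gmt",
                            package = "fluidprint"))
qea <- run_qea(cohort$table, cohort$metadata$class_label, gmt,
               biofluid = "urine", contrast = c("G12.0", "G12.1"), seed = 42)
head(qea[, c("pathway", "Q", "p_value", "enrichment_ratio")], 3)
#>                          pathway        Q p_value enrichment_ratio
#>  Arginine and proline metabolism 372.6976  0.0005         9.229537
#>             Galactose metabolism 330.3282  0.0005         8.454701
#>     Glycolysis / Gluconeogenesis 216.7346  0.0075         5.253930
```

Reading the output: the confusion diagonal is the MCCV probability of true
classification per class — the demo design's moderate fold-changes (2.5×
creatine and 1.8× glucose in the severe class, graded in the mild class)
give ~71–79% correct assignment with the misassignments falling into the
adjacent severity group, while only 4.5% of spectral bins individually pass
the Kruskal–Wallis screen. The QEA correctly surfaces the pathways
containing the perturbed metabolites (creatine/creatinine → arginine and
proline metabolism; glucose → galactose metabolism and glycolysis), each
with its permutation p-value and enrichment ratio (dot size in the usual
summary plot). `run_pipeline()` chains all stages, writes every table plus
a provenance log, and is byte-reproducible from its seed.

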