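#' Run the whole fingerprinting pipeline on a cohort
#'
#' Orchestrates the stages in the canonical order — bucketing, MCCV
#' classification, per-bin Kruskal-Wallis screening, and (when a pathway
#' library and concentration table are given) quantitative enrichment
#' analysis — writing every stage's outputs plus a provenance log to
#' `out_dir`. Stage seeds are derived deterministically from the master
#' seed, so adding iterations to one stage cannot change another, and the
#' whole run is byte-reproducible from `(inputs, seed, config)`.
#'
#' @param spectra List of `nmr_spectrum` objects (one biofluid).
#' @param metadata Data frame with `sample_id` and `class_label` columns,
#'   aligned by id to the spectra.
#' @param out_dir Output directory (created).
#' @param conc_table Optional samples x metabolites matrix for the QEA
#'   stage (urine tables must include creatinine).
#' @param pathway_library Optional named list `pathway -> members` (see
#'   [read_gmt()]); required for the QEA stage.
#' @param binning Optional [binning_config()] override.
#' @param classifier List of MCCV settings (`n_iterations`,
#'   `test_fraction`, `variance_threshold`, `alpha`, `rule`, `k`).
#' @param screen_alpha Significance level for the univariate screen.
#' @param qea List of QEA settings (`contrast`, `n_perm`, `min_set_size`,
#'   `alpha`).
#' @param seed Master seed (mandatory).
#' @return Invisible list with the stage results (`bucket_table`,
#'   `confusion`, `screen`, `qea`, `baseline`) and `out_dir`.
#' @export
run_pipeline <- function(spectra, metadata, out_dir,
                         conc_table = NULL, pathway_library = NULL,
                         binning = NULL,
                         classifier = list(), screen_alpha = 0.05,
                         qea = list(), seed) {
  if (missing(seed)) stop("a seed is mandatory for a pipeline run", call. = FALSE)
  known <- c("n_iterations", "test_fraction", "variance_threshold", "alpha",
             "rule", "k")
  bad <- setdiff(names(classifier), known)
  if (length(bad) > 0L) stop("unknown classifier option(s): ",
                             paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(names(qea), c("contrast", "n_perm", "min_set_size", "alpha"))
  if (length(bad) > 0L) stop("unknown qea option(s): ",
                             paste(bad, collapse = ", "), call. = FALSE)
  stopifnot(is.data.frame(metadata),
            all(c("sample_id", "class_label") %in% names(metadata)))
  ids <- vapply(spectra, `[[`, character(1L), "sample_id")
  if (!setequal(ids, metadata$sample_id)) {
    stop("metadata sample_ids do not match the spectra", call. = FALSE)
  }
  labels <- metadata$class_label[match(ids, metadata$sample_id)]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  stage_seed <- function(offset) (as.integer(seed) + offset) %% .Machine$integer.max
  logf("fluidprint run: %d samples, biofluid=%s, master seed=%d",
       length(spectra), spectra[[1L]]$biofluid, as.integer(seed))

  # stage 1: bucketing
  config <- binning %||% default_binning_config(spectra[[1L]]$biofluid)
  bt <- build_bucket_table(spectra, config)
  write_bucket_table(bt, file.path(out_dir, "bucket_table.csv"))
  logf("bucketing: %d bins retained (width %.3g ppm, mode %s)",
       ncol(bt$values), config$bin_width_ppm, config$scaling_mode)

  # stage 2: MCCV classification
  cls <- utils::modifyList(
    list(n_iterations = 500L, test_fraction = 0.2, variance_threshold = 0.95,
         alpha = 0.05, rule = "nearest_center", k = 5L),
    classifier)
  logf("mccv: %d iterations, %.0f%% held out, rule=%s, seed=%d",
       cls$n_iterations, 100 * cls$test_fraction, cls$rule, stage_seed(1L))
  cm <- mccv(bt, labels, n_iterations = cls$n_iterations,
             test_fraction = cls$test_fraction,
             variance_threshold = cls$variance_threshold, alpha = cls$alpha,
             rule = cls$rule, k = cls$k, seed = stage_seed(1L))
  utils::write.csv(cm$counts, file.path(out_dir, "confusion_counts.csv"))
  utils::write.csv(round(cm$proportions, 6),
                   file.path(out_dir, "confusion_proportions.csv"))
  model <- suppressWarnings(fit_fingerprint(
    bt, labels, variance_threshold = cls$variance_threshold,
    alpha = cls$alpha, rule = cls$rule, k = cls$k))
  coords <- classify_samples(bt, model)
  coords <- data.frame(sample_id = bt$sample_ids, truth = labels, coords)
  utils::write.csv(coords, file.path(out_dir, "canonical_coordinates.csv"),
                   row.names = FALSE)
  metrics <- list(diagonal = as.list(stats::setNames(diag(cm$proportions),
                                                     cm$class_labels)),
                  n_redraws = attr(cm, "n_redraws"))
  if (length(cm$class_labels) > 2L || all(c("HEALTHY") %in% cm$class_labels)) {
    pos <- setdiff(cm$class_labels, "HEALTHY")
    if (length(pos) > 0L && length(pos) < length(cm$class_labels)) {
      ss <- sensitivity_specificity(cm, pos)
      metrics$sensitivity <- unname(ss["sensitivity"])
      metrics$specificity <- unname(ss["specificity"])
    }
  }
  jsonlite::write_json(metrics, file.path(out_dir, "classification_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("mccv: diagonal %s", paste(sprintf("%s=%.3f", cm$class_labels,
                                          diag(cm$proportions)), collapse = " "))

  # stage 3: univariate screen
  scr <- screen_bins(bt, labels, alpha = screen_alpha)
  utils::write.table(scr, file.path(out_dir, "screen.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  logf("screen: %.1f%% of %d bins significant at alpha=%.3g",
       100 * significant_fraction(scr), nrow(scr), screen_alpha)

  # stage 4: enrichment (optional)
  qres <- NULL
  if (!is.null(conc_table) && !is.null(pathway_library)) {
    qcfg <- utils::modifyList(
      list(contrast = c("G12.0", "G12.1"), n_perm = 1999L,
           min_set_size = 2L, alpha = 0.05), qea)
    qres <- run_qea(conc_table, labels, pathway_library,
                    biofluid = spectra[[1L]]$biofluid,
                    contrast = qcfg$contrast, n_perm = qcfg$n_perm,
                    seed = stage_seed(2L), min_set_size = qcfg$min_set_size)
    utils::write.table(qres, file.path(out_dir, "qea.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    logf("qea: %d sets tested, %d significant at alpha=%.3g (seed=%d)",
         nrow(qres), sum(qres$p_value < qcfg$alpha), qcfg$alpha, stage_seed(2L))
  }

  # stage 5: baseline descriptives
  base_vars <- intersect(c("age_years", "sex"), names(metadata))
  baseline <- if (length(base_vars) > 0L) {
    summarize_baseline(metadata, base_vars, "class_label")
  }
  if (!is.null(baseline)) {
    jsonlite::write_json(baseline, file.path(out_dir, "baseline.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  logf("done")
  invisible(list(bucket_table = bt, confusion = cm, screen = scr, qea = qres,
                 baseline = baseline, out_dir = out_dir))
}
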