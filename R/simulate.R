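#' Simulate a 1D NMR spectrum from metabolite concentrations
#'
#' Each metabolite contributes a sum of unit-area Lorentzian lines
#' \eqn{L(x; c, \gamma) = \gamma / (\pi ((x-c)^2 + \gamma^2))} with
#' \eqn{\gamma} = half width at half maximum, weighted by its normalized
#' relative peak intensities and multiplied by its concentration, so the
#' total area contributed by a metabolite equals its concentration.
#' Independent Gaussian noise is added per grid point.
#'
#' @param concentrations Named numeric vector, metabolite -> mmol/L.
#' @param library Named list of [metabolite_definition()] objects.
#' @param axis_spec Numeric `c(ppm_min, ppm_max, n_points)`; default
#'   0-10 ppm at 9000 points (~0.0011 ppm per point).
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (intensity units).
#' @param biofluid Biofluid tag stored on the returned spectrum.
#' @param sample_id Sample identifier.
#' @return An [new_spectrum()] object (decreasing ppm axis).
#' @details Uses the current RNG state; seed with [set.seed()] for
#'   reproducibility. A warning is raised if any peak center of a requested
#'   metabolite lies outside the axis (the truncated line is still evaluated
#'   on the covered range, never silently dropped without notice).
#' @export
simulate_spectrum <- function(concentrations, library,
                              axis_spec = c(0, 10, 9000),
                              noise_sd = 0, biofluid = "urine",
                              sample_id = "sim") {
  stopifnot(length(axis_spec) == 3L, axis_spec[3L] >= 2L)
  conc_names <- names(concentrations)
  if (is.null(conc_names)) stop("concentrations must be a named vector", call. = FALSE)
  unknown <- setdiff(conc_names, names(library))
  if (length(unknown) > 0L) {
    stop("unknown metabolite(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  ppm <- seq(axis_spec[1L], axis_spec[2L], length.out = axis_spec[3L])
  intensity <- numeric(length(ppm))
  for (m in conc_names) {
    conc <- concentrations[[m]]
    if (conc == 0) next
    pk <- library[[m]]$peaks
    if (any(pk$center_ppm < axis_spec[1L] | pk$center_ppm > axis_spec[2L])) {
      warning("peak(s) of '", m, "' fall outside the simulated axis and are truncated",
              call. = FALSE)
    }
    for (j in seq_len(nrow(pk))) {
      gamma <- pk$linewidth_ppm[j] / 2
      intensity <- intensity + conc * pk$rel_intensity[j] *
        (gamma / pi) / ((ppm - pk$center_ppm[j])^2 + gamma^2)
    }
  }
  if (noise_sd > 0) {
    intensity <- intensity + stats::rnorm(length(ppm), sd = noise_sd)
  }
  new_spectrum(sample_id, biofluid, ppm, intensity)
}

#' Specify a synthetic cohort design
#'
#' @param biofluid One of `"urine"`, `"plasma"`, `"csf"`.
#' @param n_per_class Named counts for `HEALTHY`, `G12.0`, `G12.1`.
#' @param effect_sizes Named list `class -> named vector metabolite -> fold
#'   change` applied multiplicatively to base concentrations. `HEALTHY`
#'   defaults to fold 1 everywhere.
#' @param noise_sd Spectral noise standard deviation (intensity units).
#' @param conc_sdlog Log-scale standard deviation of per-sample
#'   concentration noise (log-normal; default 0.25).
#' @param dilution_range Min/max of the uniform multiplicative spot-urine
#'   dilution factor (urine only; default `c(0.3, 3)`).
#' @param seed Integer seed making the cohort fully reproducible.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(biofluid,
                          n_per_class = c(HEALTHY = 20, G12.0 = 20, G12.1 = 20),
                          effect_sizes = list(),
                          noise_sd = 1,
                          conc_sdlog = 0.25,
                          dilution_range = c(0.3, 3),
                          seed = 1L) {
  biofluid <- match_biofluid(biofluid)
  if (!all(names(n_per_class) %in% CLASS_LABELS)) {
    stop("n_per_class names must be among ", paste(CLASS_LABELS, collapse = ", "),
         call. = FALSE)
  }
  n <- stats::setNames(integer(length(CLASS_LABELS)), CLASS_LABELS)
  n[names(n_per_class)] <- as.integer(n_per_class)
  if (any(n < 0)) stop("class counts must be >= 0", call. = FALSE)
  if (!all(names(effect_sizes) %in% CLASS_LABELS)) {
    stop("effect_sizes names must be class labels", call. = FALSE)
  }
  for (cl in names(effect_sizes)) {
    if (any(effect_sizes[[cl]] <= 0)) stop("fold changes must be > 0", call. = FALSE)
  }
  if (length(dilution_range) != 2L || any(dilution_range <= 0) ||
      dilution_range[1L] > dilution_range[2L]) {
    stop("dilution_range must be positive with min <= max", call. = FALSE)
  }
  structure(
    list(biofluid = biofluid, n_per_class = n, effect_sizes = effect_sizes,
         noise_sd = noise_sd, conc_sdlog = conc_sdlog,
         dilution_range = dilution_range, seed = as.integer(seed)),
    class = "cohort_design"
  )
}

#' Read a cohort design from a YAML config file
#'
#' Schema (see the shipped example
#' `system.file("extdata", "demo_design.yaml", package = "fluidprint")`):
#' top-level keys `biofluid`, `n_per_class`, `effect_sizes`, `noise_sd`,
#' `conc_sdlog`, `dilution_range`, `seed`. Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A [cohort_design()].
#' @export
read_cohort_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("biofluid", "n_per_class", "effect_sizes", "noise_sd",
             "conc_sdlog", "dilution_range", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0L) {
    stop("unknown design key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cohort_design(
    biofluid = cfg$biofluid,
    n_per_class = unlist(cfg$n_per_class),
    effect_sizes = lapply(cfg$effect_sizes %||% list(), unlist),
    noise_sd = cfg$noise_sd %||% 1,
    conc_sdlog = cfg$conc_sdlog %||% 0.25,
    dilution_range = unlist(cfg$dilution_range %||% c(0.3, 3)),
    seed = cfg$seed %||% 1L
  )
}

#' Generate a synthetic biofluid cohort
#'
#' Draws per-sample metabolite concentrations log-normally around
#' base concentration x class fold-change, simulates the matching 1D NMR
#' spectrum for every sample, and returns mutually consistent spectra,
#' metadata, and a concentration table. For urine, a per-sample dilution
#' factor drawn uniformly from `design$dilution_range` multiplies the whole
#' concentration vector (and therefore the spectrum), emulating spot-urine
#' variability; the recorded urine table is the diluted, pre-normalization
#' concentration.
#'
#' @param design A [cohort_design()].
#' @param library Named list of metabolite definitions
#'   (default [default_metabolite_library()]).
#' @param axis_spec Axis passed to [simulate_spectrum()].
#' @return List with `spectra` (list of spectra), `metadata` (data frame:
#'   sample_id, class_label, biofluid, age_years, sex), and `table`
#'   (matrix samples x metabolites, mmol/L) — same sample order throughout.
#' @export
generate_cohort <- function(design, library = default_metabolite_library(),
                            axis_spec = c(0, 10, 9000)) {
  stopifnot(inherits(design, "cohort_design"))
  met_names <- names(library)
  base <- vapply(library, function(d) d$base_concentration[[design$biofluid]],
                 numeric(1L))
  labels <- rep(CLASS_LABELS, times = design$n_per_class[CLASS_LABELS])
  n <- length(labels)
  if (n == 0L) stop("design has no samples", call. = FALSE)
  sample_ids <- sprintf("%s_%03d", design$biofluid, seq_len(n))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(design$seed)

  conc <- matrix(NA_real_, n, length(met_names),
                 dimnames = list(sample_ids, met_names))
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    fold <- stats::setNames(rep(1, length(met_names)), met_names)
    es <- design$effect_sizes[[labels[i]]]
    if (!is.null(es)) {
      bad <- setdiff(names(es), met_names)
      if (length(bad) > 0L) {
        stop("effect size names not in library: ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
      fold[names(es)] <- es
    }
    ci <- base * fold * exp(stats::rnorm(length(met_names), sd = design$conc_sdlog))
    if (design$biofluid == "urine") {
      dil <- stats::runif(1L, design$dilution_range[1L], design$dilution_range[2L])
      ci <- ci * dil
    }
    conc[i, ] <- ci
    spectra[[i]] <- simulate_spectrum(
      stats::setNames(ci, met_names), library, axis_spec,
      noise_sd = design$noise_sd, biofluid = design$biofluid,
      sample_id = sample_ids[i]
    )
  }
  metadata <- data.frame(
    sample_id = sample_ids,
    class_label = labels,
    biofluid = design$biofluid,
    age_years = round(stats::runif(n, 0, 40), 2),
    sex = sample(c("female", "male"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  list(spectra = spectra, metadata = metadata, table = conc)
}

#' Inject solvent and EDTA artifacts into a spectrum
#'
#' Adds a broad water hump over 4.5-5.5 ppm to any biofluid; for plasma,
#' additionally adds sharp EDTA peaks inside 3.04-3.31 and 3.59-3.66 ppm.
#' Amplitudes are randomized (current RNG state). Because all artifact
#' regions lie inside the standard bucketing exclusions, downstream bucket
#' tables are invariant to the injected signal.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param biofluid Biofluid determining which artifacts apply (defaults to
#'   the spectrum's own tag).
#' @return The spectrum with artifacts added.
#' @export
inject_artifacts <- function(spectrum, biofluid = spectrum$biofluid) {
  biofluid <- match_biofluid(biofluid)
  asc <- spectrum_ascending(spectrum)
  ppm <- asc$ppm; y <- asc$intensity
  # broad water hump: Gaussian centered at 5.0 ppm, sd 0.15; support kept
  # strictly inside the 4.5-5.5 ppm exclusion so no bucket can see it
  amp <- stats::runif(1L, 50, 500)
  hump <- amp * exp(-(ppm - 5.0)^2 / (2 * 0.15^2))
  hump[ppm <= 4.52 | ppm >= 5.48] <- 0
  y <- y + hump
  if (biofluid == "plasma") {
    # sharp EDTA lines, support strictly inside 3.04-3.31 and 3.59-3.66 ppm
    for (ctr in c(3.10, 3.22, 3.625)) {
      a <- stats::runif(1L, 1, 20)
      g <- 0.003
      pk <- a * (g / pi) / ((ppm - ctr)^2 + g^2)
      pk[ppm <= ctr - 0.015 | ppm >= ctr + 0.015] <- 0
      y <- y + pk
    }
  }
  new_spectrum(spectrum$sample_id, spectrum$biofluid, ppm, y)
}
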