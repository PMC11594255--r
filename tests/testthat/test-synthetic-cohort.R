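test_that("simulated spectra have unit-area metabolite lines and scale linearly", {
  lib <- list(one = metabolite_definition(
    "one", data.frame(center_ppm = 3.0, rel_intensity = 1, linewidth_ppm = 0.02),
    c(urine = 1, plasma = 1, csf = 1)))

  # zero concentration, zero noise -> flat zero
  sp0 <- simulate_spectrum(c(one = 0), lib, noise_sd = 0)
  expect_true(all(sp0$intensity == 0))

  # unit concentration -> spectrum integrates to ~1 (unit-area Lorentzian)
  sp1 <- simulate_spectrum(c(one = 1), lib, axis_spec = c(0, 10, 9000),
                           noise_sd = 0)
  asc_ppm <- rev(sp1$ppm); asc_y <- rev(sp1$intensity)
  area <- sum(diff(asc_ppm) * (asc_y[-1] + asc_y[-length(asc_y)]) / 2)
  expect_equal(area, 1, tolerance = 0.01)

  # doubling concentration doubles the peak-region integral, leaves a
  # disjoint region untouched
  lib2 <- c(lib, list(two = metabolite_definition(
    "two", data.frame(center_ppm = 7.0, rel_intensity = 1, linewidth_ppm = 0.02),
    c(urine = 1, plasma = 1, csf = 1))))
  spa <- simulate_spectrum(c(one = 1, two = 1), lib2, noise_sd = 0)
  spb <- simulate_spectrum(c(one = 2, two = 1), lib2, noise_sd = 0)
  region_int <- function(sp, lo, hi) {
    p <- rev(sp$ppm); y <- rev(sp$intensity)
    sel <- p >= lo & p <= hi
    sum(diff(p[sel]) * (y[sel][-1] + y[sel][-sum(sel)]) / 2)
  }
  expect_equal(region_int(spb, 2.5, 3.5) / region_int(spa, 2.5, 3.5), 2,
               tolerance = 1e-3)
  # distant regions see only the Lorentzian tail of the doubled line
  # (O(gamma/distance^2) of its area), so they change by well under 0.1%
  expect_equal(region_int(spb, 6.5, 7.5), region_int(spa, 6.5, 7.5),
               tolerance = 1e-3)
})

test_that("unknown metabolites and truncated peaks are reported", {
  lib <- default_metabolite_library()
  expect_error(simulate_spectrum(c(unobtainium = 1), lib), "unobtainium")
  expect_warning(
    simulate_spectrum(c(formate = 1), lib, axis_spec = c(0, 5, 500)),
    "truncated")
})

test_that("cohort generation is reproducible and internally consistent", {
  d <- cohort_design("csf", c(HEALTHY = 4, G12.0 = 3, G12.1 = 3),
                     noise_sd = 0.5, seed = 99L)
  a <- generate_cohort(d, axis_spec = c(0, 10, 400))
  b <- generate_cohort(d, axis_spec = c(0, 10, 400))
  expect_identical(a, b)
  expect_length(a$spectra, 10L)
  expect_equal(nrow(a$metadata), 10L)
  expect_equal(nrow(a$table), 10L)
  ids <- vapply(a$spectra, `[[`, character(1), "sample_id")
  expect_identical(ids, a$metadata$sample_id)
  expect_identical(ids, rownames(a$table))
  expect_true(all(a$table >= 0))
  expect_true(all(a$table[, "creatinine"] > 0))
})

test_that("injected fold-changes are recovered from the concentration table", {
  es <- list(G12.0 = c(citrate = 3.0))
  d <- cohort_design("csf", c(HEALTHY = 50, G12.0 = 50, G12.1 = 50),
                     effect_sizes = es, noise_sd = 0, seed = 31L)
  ch <- generate_cohort(d, axis_spec = c(0, 10, 50))
  med <- tapply(ch$table[, "citrate"], ch$metadata$class_label, median)
  expect_equal(unname(med[["G12.0"]] / med[["HEALTHY"]]), 3.0, tolerance = 0.1)
  # the unspiked class ratio is 1 up to median sampling noise: the log
  # median SE is ~1.25 * sdlog / sqrt(n) per group, so 3 SE ~ 0.19
  expect_equal(unname(med[["G12.1"]] / med[["HEALTHY"]]), 1.0, tolerance = 0.2)
})

test_that("artifact injection is local to the excluded regions", {
  lib <- default_metabolite_library()
  conc <- vapply(lib, function(x) x$base_concentration[["urine"]], numeric(1))
  sp <- simulate_spectrum(conc, lib, noise_sd = 0, biofluid = "urine")
  set.seed(5)
  spa <- inject_artifacts(sp)
  outside <- sp$ppm < 4.5 | sp$ppm > 5.5
  expect_identical(spa$intensity[outside], sp$intensity[outside])
  expect_gt(sum(abs(spa$intensity - sp$intensity)), 0)

  # plasma also gets EDTA signal inside 3.04-3.31 ppm
  spp <- simulate_spectrum(conc, lib, noise_sd = 0, biofluid = "plasma")
  set.seed(6)
  spb <- inject_artifacts(spp)
  edta <- spp$ppm > 3.04 & spp$ppm < 3.31
  expect_gt(sum(abs(spb$intensity[edta] - spp$intensity[edta])), 0)
})

test_that("bucket tables are invariant to injected artifacts", {
  d <- cohort_design("plasma", c(HEALTHY = 3, G12.0 = 3, G12.1 = 3),
                     noise_sd = 0, seed = 17L)
  ch <- fixture_cohort("plasma_clean9", d)
  bt_clean <- build_bucket_table(ch$spectra)
  set.seed(123)
  dirty <- lapply(ch$spectra, inject_artifacts)
  bt_dirty <- build_bucket_table(dirty)
  expect_equal(bt_clean$values, bt_dirty$values, tolerance = 1e-12)
})

test_that("cohort design validates its inputs", {
  expect_error(cohort_design("saliva"), "unknown biofluid")
  expect_error(cohort_design("urine", c(HEALTHY = -1)), ">= 0")
  expect_error(cohort_design("urine", effect_sizes = list(G12.0 = c(citrate = 0))),
               "> 0")
  expect_error(cohort_design("urine", dilution_range = c(3, 0.3)), "min <= max")
})

test_that("a design round-trips through the YAML config reader", {
  path <- system.file("extdata", "demo_design.yaml", package = "fluidprint")
  d <- read_cohort_design(path)
  expect_s3_class(d, "cohort_design")
  expect_identical(d$biofluid, "urine")
  expect_equal(unname(d$n_per_class[c("HEALTHY", "G12.0", "G12.1")]),
               c(20L, 20L, 20L))
  expect_equal(d$effect_sizes$G12.0[["creatine"]], 2.5)

  bad <- tempfile(fileext = ".yaml")
  writeLines(c("biofluid: urine", "typo_key: 1"), bad)
  expect_error(read_cohort_design(bad), "typo_key")
})
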