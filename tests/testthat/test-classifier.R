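test_that("PCA recovers degenerate geometry and round-trips the data", {
  # points on a diagonal line -> one component, loading (1,1)/sqrt(2)
  t_vals <- seq(-2, 2, length.out = 10)
  x <- cbind(t_vals, t_vals)
  p <- fit_pca(x, variance_threshold = 0.95)
  expect_equal(p$n_pcs, 1L)
  expect_equal(p$explained_variance[1], 1)
  expect_equal(abs(p$pca_basis[, 1]), c(1, 1) / sqrt(2), tolerance = 1e-10)

  set.seed(8)
  x <- matrix(rnorm(60), 10, 6)
  p <- fit_pca(x, variance_threshold = 1)
  expect_equal(sum(p$explained_variance), 1, tolerance = 1e-12)
  # orthonormal basis
  expect_equal(crossprod(p$pca_basis), diag(p$n_pcs), tolerance = 1e-8)
  # reconstruction from all components reproduces the centered data
  xc <- sweep(x, 2, p$column_means)
  expect_equal(p$scores %*% t(p$pca_basis), xc, tolerance = 1e-8,
               ignore_attr = TRUE)

  expect_error(fit_pca(matrix(1, 5, 3)), "zero total variance")
})

test_that("canonical analysis recovers a planted separation direction", {
  set.seed(19)
  x <- rbind(matrix(rnorm(40 * 3), 40, 3),
             cbind(rnorm(40, mean = 6), rnorm(40), rnorm(40)))
  lab <- rep(c("A", "B"), each = 40)
  ca <- fit_canonical(x, lab)
  expect_equal(ca$n_canonical, 1L)
  dir <- ca$canonical_basis[, 1]
  cosine <- abs(dir[1]) / sqrt(sum(dir^2))
  expect_gt(cosine, 0.95)
  expect_equal(rownames(ca$class_centers), c("A", "B"))
})

test_that("canonical dimension is bounded by classes minus one", {
  set.seed(3)
  x <- matrix(rnorm(45 * 6), 45, 6)
  lab <- rep(c("A", "B", "C"), each = 15)
  ca <- suppressWarnings(fit_canonical(x, lab))
  expect_lte(ca$n_canonical, 2L)
  expect_equal(ncol(ca$canonical_basis), 2L)
})

test_that("MANOVA dimension test is calibrated on null data", {
  set.seed(77)
  reject <- vapply(seq_len(200), function(i) {
    x <- matrix(rnorm(40 * 3), 40, 3)
    lab <- rep(c("A", "B"), each = 20)
    ca <- suppressWarnings(fit_canonical(x, lab))
    ca$manova_pvalues[1] < 0.05
  }, logical(1))
  se3 <- 3 * sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(mean(reject) - 0.05), se3 + 1e-12)
})

test_that("classification honors centers, ties, and knn identity", {
  set.seed(12)
  x <- rbind(matrix(rnorm(20, sd = 0.2), 10, 2),
             matrix(rnorm(20, mean = 4, sd = 0.2), 10, 2))
  lab <- rep(c("A", "B"), each = 10)
  m <- suppressWarnings(fit_fingerprint(x, lab, variance_threshold = 1))

  # the class-A mean projects exactly onto the A center: label A, distance 0
  res <- classify_samples(colMeans(x[1:10, , drop = FALSE]), m)
  expect_identical(res$label, "A")
  expect_equal(res$dist_A, 0, tolerance = 1e-10)

  # equidistant point -> lexicographic tie, flagged
  mid <- (m$class_centers["A", ] + m$class_centers["B", ]) / 2
  # invert: find bin-space point projecting to mid (use training mean +
  # pseudo-inverse direction)
  v <- m$pca_basis %*% m$canonical_basis[, 1]
  pt <- m$column_means + drop(v) * (mid / sum(v * v))
  res_mid <- classify_samples(pt, m)
  expect_identical(res_mid$label, "A")
  expect_true(res_mid$tie)

  # knn with k = 1 returns a training point's own label
  mk <- suppressWarnings(fit_fingerprint(x, lab, variance_threshold = 1,
                                         rule = "knn", k = 1))
  res_k <- classify_samples(x[15, ], mk)
  expect_identical(res_k$label, "B")

  expect_error(classify_samples(c(1, 2, 3), m), "dimensionality")
})

test_that("the two-class pipeline equals a brute-force Fisher LDA oracle", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    n <- 18; p <- 10
    x <- rbind(matrix(rnorm(n / 2 * p), n / 2, p),
               matrix(rnorm(n / 2 * p, mean = 1.5), n / 2, p))
    lab <- rep(c("A", "B"), each = n / 2)
    m <- suppressWarnings(fit_fingerprint(x, lab, variance_threshold = 1))
    res <- classify_samples(x, m)
    oracle <- oracle_fisher_lda(x, lab)
    expect_gt(abs(cor(res$can1, oracle$projection)), 1 - 1e-6)
    expect_identical(res$label, oracle$assigned)
  }
})

test_that("MCCV confusion matrices are row-stochastic and reproducible", {
  d <- null_urine_design(seed = 11L, n = 8L)
  ch <- fixture_cohort("null_small", d, axis_spec = c(0, 10, 2000))
  bt <- build_bucket_table(ch$spectra)
  cm1 <- mccv(bt, ch$metadata$class_label, n_iterations = 20, seed = 7)
  cm2 <- mccv(bt, ch$metadata$class_label, n_iterations = 20, seed = 7)
  expect_identical(cm1$counts, cm2$counts)
  expect_equal(unname(rowSums(cm1$proportions)), rep(1, 3), tolerance = 1e-12)
  recs <- attr(cm1, "iteration_records")
  expect_equal(sum(cm1$counts), sum(recs$n_test))
})

test_that("MCCV accuracy is monotone in the injected effect size", {
  accs <- vapply(c(1, 2, 5), function(fold) {
    es <- list(G12.0 = stats::setNames(rep(fold, 5), spike_metabolites),
               G12.1 = stats::setNames(rep(1 / fold, 5), spike_metabolites))
    d <- cohort_design("csf", c(HEALTHY = 12, G12.0 = 12, G12.1 = 12),
                       effect_sizes = es, noise_sd = 0.2, seed = 41L)
    ch <- generate_cohort(d, axis_spec = c(0, 10, 4000))
    bt <- build_bucket_table(ch$spectra)
    cm <- mccv(bt, ch$metadata$class_label, n_iterations = 60, seed = 13)
    mean(diag(cm$proportions))
  }, numeric(1))
  expect_gte(accs[2], accs[1] - 0.02)
  expect_gte(accs[3], accs[2] - 0.02)
})

test_that("sensitivity and specificity pool classes correctly", {
  cm <- confusion_matrix(matrix(c(94, 16, 6, 84), 2, 2,
                                dimnames = list(c("HEALTHY", "SMA"),
                                                c("HEALTHY", "SMA"))))
  ss <- sensitivity_specificity(cm, "SMA")
  expect_equal(unname(ss["sensitivity"]), 0.84)
  expect_equal(unname(ss["specificity"]), 0.94)

  perfect <- confusion_matrix(diag(3) * 10)
  ss2 <- sensitivity_specificity(perfect, "class1")
  expect_equal(unname(ss2), c(1, 1))

  expect_error(sensitivity_specificity(cm, c("HEALTHY", "SMA")), "proper subset")
  empty <- confusion_matrix(matrix(c(5, 0, 5, 0), 2, 2,
                                   dimnames = list(c("a", "b"), c("a", "b"))))
  expect_warning(sensitivity_specificity(empty, "b"), "undefined")
})

test_that("uniform random assignment over two classes gives ~0.5 for both metrics", {
  set.seed(10)
  truth <- rep(c("neg", "pos"), each = 4000)
  assigned <- sample(c("neg", "pos"), 8000, replace = TRUE)
  counts <- table(truth, assigned)
  cm <- confusion_matrix(unclass(counts))
  ss <- sensitivity_specificity(cm, "pos")
  expect_equal(unname(ss["sensitivity"]), 0.5, tolerance = 0.05)
  expect_equal(unname(ss["specificity"]), 0.5, tolerance = 0.05)
})
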