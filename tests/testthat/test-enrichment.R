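make_conc_table <- function(n = 20, mets = c("creatinine", "citrate", "alanine",
                                             "glucose", "taurine")) {
  x <- matrix(rlnorm(n * length(mets)), n, length(mets),
              dimnames = list(sprintf("s%02d", seq_len(n)), mets))
  x
}

test_that("autoscaling yields zero means and unit sds; urine uses creatinine", {
  set.seed(30)
  x <- make_conc_table()
  s <- normalize_for_qea(x, "plasma")
  expect_equal(unname(colMeans(s)), rep(0, ncol(s)), tolerance = 1e-10)
  expect_equal(unname(apply(s, 2, sd)), rep(1, ncol(s)), tolerance = 1e-10)
  expect_true("creatinine" %in% colnames(s))

  su <- normalize_for_qea(x, "urine")
  expect_false("creatinine" %in% colnames(su))
  expect_equal(unname(colMeans(su)), rep(0, ncol(su)), tolerance = 1e-10)
})

test_that("urine normalization cancels a shared dilution factor", {
  set.seed(31)
  x <- make_conc_table(n = 10)
  doubled <- x
  doubled[1, ] <- x[1, ] * 2        # sample 1 twice as concentrated overall
  s1 <- normalize_for_qea(x, "urine")
  s2 <- normalize_for_qea(doubled, "urine")
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("degenerate tables are handled explicitly", {
  set.seed(32)
  x <- make_conc_table(n = 8)
  x[, "alanine"] <- 3
  expect_warning(s <- normalize_for_qea(x, "plasma"), "alanine")
  expect_false("alanine" %in% colnames(s))

  x2 <- make_conc_table(n = 4)
  x2[2, "creatinine"] <- 0
  expect_error(normalize_for_qea(x2, "urine"), "s02")
  expect_error(normalize_for_qea(x2[, setdiff(colnames(x2), "creatinine")],
                                 "urine"), "creatinine")
})

test_that("the global test Q-statistic behaves at its analytic anchors", {
  outcome <- rep(c("a", "b"), each = 10)
  zeros <- matrix(0, 20, 3)
  gt <- globaltest_q(zeros, outcome, n_perm = 99, seed = 1)
  expect_equal(gt$Q, 0)
  expect_equal(gt$p_value, 1, tolerance = 0.05)

  # a member equal to the centered outcome is maximally associated
  z <- ifelse(outcome == "b", 1, -1)
  x <- cbind(z / sd(z))
  gt2 <- globaltest_q(x, outcome, n_perm = 999, seed = 2)
  expect_lte(gt2$p_value, 3 / 1000)

  # sign flips of member columns leave Q unchanged (Q depends on X X')
  set.seed(33)
  xm <- matrix(rnorm(60), 20, 3)
  q_a <- globaltest_q(xm, outcome, n_perm = 9, seed = 3)$Q
  xm[, 2] <- -xm[, 2]
  q_b <- globaltest_q(xm, outcome, n_perm = 9, seed = 3)$Q
  expect_equal(q_a, q_b, tolerance = 1e-12)

  # member column order is irrelevant
  q_c <- globaltest_q(xm[, c(3, 1, 2)], outcome, n_perm = 9, seed = 3)$Q
  expect_equal(q_b, q_c, tolerance = 1e-12)

  expect_error(globaltest_q(xm, rep("a", 20)), "2 levels")
})

test_that("permutation p-values are valid under the null", {
  set.seed(34)
  outcome <- rep(c("a", "b"), each = 10)
  ps <- vapply(seq_len(200), function(i) {
    x <- matrix(rnorm(20 * 4), 20, 4)
    globaltest_q(x, outcome, n_perm = 199)$p_value
  }, numeric(1))
  rej <- mean(ps < 0.05)
  expect_lte(rej, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
  expect_equal(mean(ps), 0.5, tolerance = 0.1)
})

test_that("run_qea ranks a spiked set first and skips unmeasurable sets", {
  set.seed(35)
  n <- 15
  mets <- c("creatinine", "citrate", "alanine", "glucose", "valine", "leucine")
  x <- matrix(rlnorm(2 * n * length(mets)), 2 * n, length(mets),
              dimnames = list(NULL, mets))
  lab <- rep(c("G12.0", "G12.1"), each = n)
  x[lab == "G12.0", c("valine", "leucine")] <-
    x[lab == "G12.0", c("valine", "leucine")] * 6
  lib <- list(
    "Branched chain" = c("valine", "leucine"),
    "Energy" = c("citrate", "glucose"),
    "Unmeasured" = c("tryptophan", "kynurenine")
  )
  expect_message(
    res <- run_qea(x, lab, lib, biofluid = "plasma", n_perm = 499, seed = 9),
    "Unmeasured")
  expect_equal(res$pathway[1], "Branched chain")
  expect_false("Unmeasured" %in% res$pathway)
  expect_equal(res$n_members_measured[res$pathway == "Branched chain"], 2L)

  expect_error(run_qea(x, lab, list(none = c("foo", "bar")), "plasma",
                       n_perm = 9), "measured members")
})

test_that("enrichment ratios are ~1 on null data", {
  set.seed(36)
  n <- 14
  mets <- sprintf("m%02d", 1:12)
  ratios <- replicate(25, {
    x <- matrix(rlnorm(2 * n * 12), 2 * n, 12, dimnames = list(NULL, mets))
    lab <- rep(c("a", "b"), each = n)
    lib <- list(s1 = mets[1:4], s2 = mets[5:8], s3 = mets[9:12])
    res <- run_qea(x, lab, lib, biofluid = "plasma", n_perm = 199, seed = 1)
    mean(res$enrichment_ratio)
  })
  expect_equal(mean(ratios), 1, tolerance = 0.15)
})

test_that("Venn regions follow set algebra and a brute-force oracle", {
  same <- list(u = letters[1:5], p = letters[1:5], c = letters[1:5])
  v <- venn_overlap(same)
  expect_equal(unname(v$counts["all_three"]), 5L)
  expect_equal(sum(v$counts), 5L)

  disjoint <- list(u = letters[1:3], p = letters[4:6], c = letters[7:9])
  expect_equal(unname(venn_overlap(disjoint)$counts["all_three"]), 0L)

  set.seed(37)
  for (i in 1:10) {
    sets <- lapply(1:3, function(j) sample(letters[1:10], sample(0:8, 1)))
    names(sets) <- c("u", "p", "c")
    v <- venn_overlap(sets)
    expect_equal(sum(v$counts), length(Reduce(union, sets)))
    # brute force: classify each union element by membership pattern
    for (el in Reduce(union, sets)) {
      pattern <- vapply(sets, function(s) el %in% s, logical(1))
      region <- if (all(pattern)) "all_three"
        else if (sum(pattern) == 1) paste0(names(sets)[pattern], "_only")
        else paste(names(sets)[pattern], collapse = "_")
      expect_true(el %in% v$members[[region]])
    }
  }
})

test_that("heatmap ordering reflects Euclidean column distances", {
  set.seed(38)
  x <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  x <- cbind(x, e = x[, "b"])          # identical twin column
  h <- heatmap_order(x)
  dm <- as.matrix(h$dist)
  expect_equal(dm["b", "e"], 0)
  expect_equal(abs(match("b", h$order) - match("e", h$order)), 1L)
  expect_equal(unname(diag(dm)), rep(0, 5))
  expect_equal(dm, t(dm))
  # brute-force distances
  for (i in colnames(x)) for (j in colnames(x)) {
    expect_equal(dm[i, j], sqrt(sum((x[, i] - x[, j])^2)), tolerance = 1e-12)
  }
})
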