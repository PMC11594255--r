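# Independent oracles and shared fixtures. Oracles deliberately take a
# different computational route than the package code they check.

# Fisher LDA by direct scatter algebra on the raw feature space.
oracle_fisher_lda <- function(x, labels) {
  classes <- sort(unique(labels))
  stopifnot(length(classes) == 2L)
  x1 <- x[labels == classes[1L], , drop = FALSE]
  x2 <- x[labels == classes[2L], , drop = FALSE]
  mu1 <- colMeans(x1); mu2 <- colMeans(x2)
  sw <- (crossprod(sweep(x1, 2L, mu1)) + crossprod(sweep(x2, 2L, mu2))) /
    (nrow(x) - 2L)
  w <- solve(sw, mu2 - mu1)
  proj <- drop(x %*% w)
  c1 <- mean(proj[labels == classes[1L]])
  c2 <- mean(proj[labels == classes[2L]])
  assigned <- ifelse(abs(proj - c1) <= abs(proj - c2), classes[1L], classes[2L])
  list(projection = proj, assigned = assigned, direction = w)
}

# Mann-Whitney U by direct pair counting (no ranks), and the exact
# two-sided p by enumerating value assignments.
oracle_mw_u <- function(x, y) {
  cmp <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  sum(cmp)
}

oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  combos <- utils::combn(length(pooled), nx)
  center <- nx * length(y) / 2
  u_obs <- oracle_mw_u(x, y)
  devs <- apply(combos, 2L, function(ix) {
    abs(oracle_mw_u(pooled[ix], pooled[-ix]) - center)
  })
  mean(devs >= abs(u_obs - center) - 1e-12)
}

# Exact permutation p for Kruskal-Wallis on tiny inputs, enumerating all
# distinct assignments of pooled values to groups.
oracle_kw_perm_p <- function(groups) {
  pooled <- unlist(groups)
  sizes <- lengths(groups)
  h_obs <- fluidprint::kruskal_wallis(groups)[["H"]]
  perms <- combinat_assignments(length(pooled), sizes)
  hs <- vapply(perms, function(idx) {
    fluidprint::kruskal_wallis(split(pooled, idx))[["H"]]
  }, numeric(1L))
  mean(hs >= h_obs - 1e-12)
}

# All assignments of n items into groups of the given sizes, as an index
# vector (1..k) per assignment.
combinat_assignments <- function(n, sizes) {
  assignments <- list()
  build <- function(remaining, sizes_left, acc) {
    if (length(sizes_left) == 1L) {
      acc[remaining] <- max(acc) + 1L
      assignments[[length(assignments) + 1L]] <<- acc
      return(invisible())
    }
    for (sel in utils::combn(remaining, sizes_left[1L], simplify = FALSE)) {
      acc2 <- acc
      acc2[sel] <- max(acc) + 1L
      build(setdiff(remaining, sel), sizes_left[-1L], acc2)
    }
  }
  build(seq_len(n), sizes, integer(n))
  assignments
}

# Cached synthetic cohorts shared across test files (built once per run).
.fixture_env <- new.env(parent = emptyenv())

fixture_cohort <- function(key, design, axis_spec = c(0, 10, 9000)) {
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_cohort(design, axis_spec = axis_spec)
  }
  .fixture_env[[key]]
}

null_urine_design <- function(seed = 11L, n = 20L) {
  cohort_design("urine",
                n_per_class = c(HEALTHY = n, G12.0 = n, G12.1 = n),
                effect_sizes = list(), noise_sd = 1, seed = seed)
}

# Five spiked metabolites forming the "Valine, leucine and isoleucine
# degradation" set of the bundled pathway fixture.
spike_metabolites <- c("valine", "leucine", "isoleucine",
                       "3-hydroxybutyrate", "acetone")

# Severity-gradient design: the spiked pathway is elevated 5-fold in the
# mild class and 25-fold in the severe class, so all three classes separate
# along one severity axis at low spectral noise.
strong_urine_design <- function(seed = 21L, n = 20L) {
  cohort_design("urine",
                n_per_class = c(HEALTHY = n, G12.0 = n, G12.1 = n),
                effect_sizes = list(
                  G12.0 = stats::setNames(rep(25, 5), spike_metabolites),
                  G12.1 = stats::setNames(rep(5, 5), spike_metabolites)),
                noise_sd = 0.1, seed = seed)
}

gmt_fixture_path <- function() {
  system.file("extdata", "kegg_hsa_subset.gmt", package = "fluidprint")
}
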