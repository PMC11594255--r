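#' Mann-Whitney U test with exact small-sample enumeration
#'
#' U is computed from mid-ranks. For small pooled samples
#' (total n <= `exact_limit`, default 8) the two-sided p-value is obtained
#' by exhaustive enumeration of all group assignments of the pooled values
#' (exact even under ties); otherwise the normal approximation with tie
#' correction and continuity correction is used. Both U and the
#' complementary statistic U' = n_x n_y - U are reported, together with
#' the rank-sum W of the first sample, because the literature uses all
#' three conventions interchangeably.
#'
#' @param x,y Numeric vectors (non-empty).
#' @param method `"auto"` (exact when total n <= `exact_limit`),
#'   `"exact"`, or `"approx"`.
#' @param exact_limit Auto-mode cutoff for enumeration (default 8).
#' @return Named numeric `c(U, U_prime, W, p_value)` where `U` counts
#'   pairs (x_i, y_j) with x_i > y_j (plus half-ties).
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "approx"),
                           exact_limit = 8L) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  w_x <- sum(r[seq_len(nx)])
  u <- w_x - nx * (nx + 1) / 2          # pairs with x > y (ties count 1/2)
  u_prime <- nx * ny - u
  if (method == "auto") method <- if (n <= exact_limit) "exact" else "approx"
  if (method == "exact") {
    # enumerate every assignment of nx pooled values to the first group
    combos <- utils::combn(n, nx)
    center <- nx * ny / 2
    dev_obs <- abs(u - center)
    devs <- apply(combos, 2L, function(ix) {
      abs(sum(r[ix]) - nx * (nx + 1) / 2 - center)
    })
    p <- mean(devs >= dev_obs - 1e-12)
  } else {
    mu <- nx * ny / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      zstat <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(max(zstat, 0), lower.tail = FALSE))
    }
  }
  c(U = u, U_prime = u_prime, W = w_x, p_value = p)
}

#' Distribution-gated baseline summaries of a cohort table
#'
#' For each numeric variable, per-group normality is checked with the
#' Shapiro-Wilk test at alpha = 0.05 (groups with fewer than 3 values are
#' treated as non-normal). When all groups pass, the summary is mean +/- SD
#' and the test is a two-sample t-test (2 groups); otherwise the summary is
#' median (IQR) and the test is Mann-Whitney U (2 groups) or
#' Kruskal-Wallis (> 2 groups). Categorical variables are summarized as
#' counts and percentages of the group size.
#'
#' @param metadata Data frame.
#' @param variables Character vector of column names to summarize.
#' @param group_var Name of the grouping column.
#' @return Named list, one entry per variable, each a list with `type`
#'   (`"numeric"`/`"categorical"`), `groups` (per-group summaries),
#'   `test_used`, `statistic`, `p_value`.
#' @export
summarize_baseline <- function(metadata, variables, group_var) {
  stopifnot(is.data.frame(metadata), group_var %in% names(metadata))
  missing_vars <- setdiff(variables, names(metadata))
  if (length(missing_vars) > 0L) {
    stop("variable(s) not in metadata: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  grp <- as.character(metadata[[group_var]])
  groups <- sort(unique(grp))
  out <- list()
  for (v in variables) {
    col <- metadata[[v]]
    if (is.numeric(col)) {
      by_g <- lapply(groups, function(g) col[grp == g & !is.na(col)])
      names(by_g) <- groups
      normal <- vapply(by_g, function(z) {
        if (length(z) < 3L || length(unique(z)) == 1L) return(FALSE)
        stats::shapiro.test(z)$p.value >= 0.05
      }, logical(1L))
      summaries <- lapply(by_g, function(z) {
        list(n = length(z), mean = mean(z), sd = stats::sd(z),
             median = stats::median(z), iqr = stats::IQR(z),
             min = min(z), max = max(z))
      })
      nonempty <- lengths(by_g) > 0L
      if (sum(nonempty) < 2L) {
        test_used <- "none"; statistic <- NA_real_; p_value <- NA_real_
      } else if (length(groups) == 2L && all(normal)) {
        tt <- stats::t.test(by_g[[1L]], by_g[[2L]])
        test_used <- "t_test"; statistic <- unname(tt$statistic)
        p_value <- tt$p.value
      } else if (length(groups) == 2L) {
        mw <- mann_whitney_u(by_g[[1L]], by_g[[2L]])
        test_used <- "mann_whitney"; statistic <- unname(mw["U"])
        p_value <- unname(mw["p_value"])
      } else {
        kw <- kruskal_wallis(by_g[nonempty])
        test_used <- "kruskal_wallis"; statistic <- unname(kw["H"])
        p_value <- unname(kw["p_value"])
      }
      out[[v]] <- list(type = "numeric", groups = summaries,
                       test_used = test_used, statistic = statistic,
                       p_value = p_value)
    } else {
      col <- as.character(col)
      summaries <- lapply(groups, function(g) {
        z <- col[grp == g]
        tab <- table(z, useNA = "no")
        data.frame(level = names(tab), count = as.integer(tab),
                   percent = round(100 * as.integer(tab) / length(z), 1),
                   stringsAsFactors = FALSE)
      })
      names(summaries) <- groups
      out[[v]] <- list(type = "categorical", groups = summaries,
                       test_used = "none", statistic = NA_real_,
                       p_value = NA_real_)
    }
  }
  out
}

#' Percentage of a count within a group total
#'
#' One-line convenience for printed-table style breakdowns
#' (count / total x 100, rounded to one decimal).
#'
#' @param count,total Non-negative numbers, `total > 0`.
#' @return Percentage rounded to one decimal place.
#' @export
count_percent <- function(count, total) {
  stopifnot(total > 0, count >= 0)
  round(100 * count / total, 1)
}
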