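#' Kruskal-Wallis H test
#'
#' Thin wrapper over [stats::kruskal.test()] returning the tie-corrected H
#' statistic and the chi-square p-value (df = groups - 1). The degenerate
#' all-identical case (tie-correction divisor zero) is treated as carrying
#' no information: H = 0, p = 1.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, each
#'   non-empty, total n >= 3).
#' @return Named numeric `c(H, p_value)`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) == 0L)) stop("every group must be non-empty", call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  if (length(pooled) < 3L) stop("need total n >= 3", call. = FALSE)
  if (length(unique(pooled)) == 1L) return(c(H = 0, p_value = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(pooled, g)
  c(H = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Per-bin Kruskal-Wallis screen of a bucket table
#'
#' Each retained bin is tested across the groups; no multiple-testing
#' adjustment is applied by default (each bin is flagged at the raw
#' per-bin level), matching the conventional per-bin p < 0.05 highlighting
#' of fingerprint screens. Per-group medians and 5-95% percentile bands
#' (linear-interpolation quantiles, type 7) are attached for plotting.
#'
#' @param table A `bucket_table` or numeric matrix (samples x bins).
#' @param labels Group labels aligned to rows (>= 2 groups).
#' @param alpha Significance level (default 0.05).
#' @param adjust P-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`; `"BH"` available).
#' @return Data frame with one row per bin: `bin_center_ppm`, `H`,
#'   `p_value`, `significant`, and per-group `median_`, `p5_`, `p95_`
#'   columns.
#' @export
screen_bins <- function(table, labels, alpha = 0.05, adjust = "none") {
  if (inherits(table, "bucket_table")) {
    x <- table$values
    centers <- table$bin_centers_ppm
  } else {
    x <- as.matrix(table)
    centers <- suppressWarnings(
      as.numeric(sub("^bin_", "", colnames(x) %||% character(0))))
    if (length(centers) != ncol(x) || anyNA(centers)) centers <- seq_len(ncol(x))
  }
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("need >= 2 groups to screen", call. = FALSE)
  res <- t(apply(x, 2L, function(col) {
    kruskal_wallis(split(col, labels))
  }))
  p_adj <- stats::p.adjust(res[, "p_value"], method = adjust)
  out <- data.frame(bin_center_ppm = centers, H = res[, "H"],
                    p_value = p_adj, significant = p_adj < alpha,
                    row.names = NULL)
  for (gl in groups) {
    xg <- x[labels == gl, , drop = FALSE]
    q <- apply(xg, 2L, stats::quantile, probs = c(0.05, 0.5, 0.95),
               names = FALSE, type = 7)
    out[[paste0("median_", gl)]] <- q[2L, ]
    out[[paste0("p5_", gl)]] <- q[1L, ]
    out[[paste0("p95_", gl)]] <- q[3L, ]
  }
  out
}

#' Fraction of significant bins in a screen
#'
#' @param results Data frame from [screen_bins()].
#' @return `count(significant) / count(all)`.
#' @export
significant_fraction <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) > 0L,
            "significant" %in% names(results))
  mean(results$significant)
}

#' Plot a screened spectrum overlay
#'
#' Draws the per-group median lines with shaded 5-95% percentile bands and
#' highlights significant bins, the standard way fingerprint screens are
#' displayed.
#'
#' @param results Data frame from [screen_bins()].
#' @param xlim Optional ppm window `c(low, high)`.
#' @param ... Passed to [plot()].
#' @export
plot_screen <- function(results, xlim = NULL, ...) {
  groups <- sub("^median_", "", grep("^median_", names(results), value = TRUE))
  ord <- order(results$bin_center_ppm)
  r <- results[ord, ]
  if (!is.null(xlim)) r <- r[r$bin_center_ppm >= min(xlim) & r$bin_center_ppm <= max(xlim), ]
  cols <- grDevices::hcl.colors(max(3L, length(groups)), "Dark 3")
  ymax <- max(vapply(groups, function(g) max(r[[paste0("p95_", g)]]), numeric(1L)))
  plot(NA, xlim = rev(range(r$bin_center_ppm)), ylim = c(0, ymax),
       xlab = "chemical shift (ppm)", ylab = "bin intensity", ...)
  sig <- r$bin_center_ppm[r$significant]
  if (length(sig) > 0L) {
    w <- stats::median(diff(sort(unique(r$bin_center_ppm))))
    graphics::rect(sig - w / 2, 0, sig + w / 2, ymax, col = "#ffd6e7",
                   border = NA)
  }
  for (i in seq_along(groups)) {
    g <- groups[i]
    graphics::polygon(c(r$bin_center_ppm, rev(r$bin_center_ppm)),
                      c(r[[paste0("p5_", g)]], rev(r[[paste0("p95_", g)]])),
                      col = grDevices::adjustcolor(cols[i], 0.25), border = NA)
    graphics::lines(r$bin_center_ppm, r[[paste0("median_", g)]], col = cols[i])
  }
  graphics::legend("topleft", legend = groups, col = cols[seq_along(groups)],
                   lty = 1, bty = "n")
  invisible(results)
}
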