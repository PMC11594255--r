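# Internal numeric helpers shared across modules.

BIOFLUIDS <- c("urine", "plasma", "csf")
CLASS_LABELS <- c("HEALTHY", "G12.0", "G12.1")

match_biofluid <- function(biofluid) {
  if (!is.character(biofluid) || length(biofluid) != 1L || !(biofluid %in% BIOFLUIDS)) {
    stop("unknown biofluid: ", paste(biofluid, collapse = ", "),
         " (expected one of ", paste(BIOFLUIDS, collapse = ", "), ")", call. = FALSE)
  }
  biofluid
}

# Trapezoidal integral of y over x; x must be sorted ascending.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

# Trapezoidal integral restricted to [lo, hi], interpolating the endpoints
# so the result is exact for piecewise-linear signals on any grid.
trapz_interval <- function(x, y, lo, hi) {
  if (hi <= lo) return(0)
  lo <- max(lo, x[1L]); hi <- min(hi, x[length(x)])
  if (hi <= lo) return(0)
  inside <- x > lo & x < hi
  xs <- c(lo, x[inside], hi)
  ys <- c(stats::approx(x, y, xout = lo)$y, y[inside], stats::approx(x, y, xout = hi)$y)
  trapz(xs, ys)
}

# Interval overlap with positive length; a small tolerance ignores
# floating-point slivers when accumulated bin edges touch an exclusion
# boundary (1e-9 ppm is ~1e-7 of a bin width).
overlaps_open <- function(a_lo, a_hi, b_lo, b_hi, tol = 1e-9) {
  pmin(a_hi, b_hi) - pmax(a_lo, b_lo) > tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
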