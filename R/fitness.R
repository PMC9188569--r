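#' Competition-assay ratio series
#'
#' Holds per-time-point strain counts from classified cytometry acquisitions
#' and the derived log-odds of the focal (numerator) strain. Log-odds are
#' defined only where both counts are positive; other points are kept but
#' flagged unusable.
#'
#' @param times sampling times, h.
#' @param counts_focal,counts_other event counts per time point (>= 0).
#' @return A `ratio_series` data.frame with columns `t`, `focal`, `other`,
#'   `logodds`, `usable`.
#' @export
ratio_series <- function(times, counts_focal, counts_other) {
  if (length(times) != length(counts_focal) ||
      length(times) != length(counts_other))
    stop("times and counts must have equal length", call. = FALSE)
  if (any(counts_focal < 0) || any(counts_other < 0))
    stop("counts must be >= 0", call. = FALSE)
  usable <- counts_focal > 0 & counts_other > 0
  lo <- rep(NA_real_, length(times))
  lo[usable] <- log(counts_focal[usable] / counts_other[usable])
  out <- data.frame(t = times, focal = counts_focal, other = counts_other,
                    logodds = lo, usable = usable)
  class(out) <- c("ratio_series", "data.frame")
  out
}

#' Detect the steady-state window of a competition assay
#'
#' At steady state the log of the strain ratio evolves linearly in time, so
#' linearity over at least `min_points` consecutive samples marks when the
#' culture (and residual nutrient) has equilibrated. The rule: among suffix
#' windows of the usable points with at least `min_points` members, return
#' the longest whose least-squares line has maximum absolute residual below
#' `tolerance` (log-odds units). An empty result means no steady state was
#' reached.
#'
#' @param series a [ratio_series()].
#' @param min_points minimum window size (default 3).
#' @param tolerance max absolute residual allowed, log-odds units
#'   (default 0.05).
#' @return List with `index` (integer positions into `series`, empty if no
#'   window qualifies) and `status` (`"ok"`, `"no steady state"`, or
#'   `"insufficient data"`).
#' @export
detect_steady_window <- function(series, min_points = 3L, tolerance = 0.05) {
  use <- which(series$usable)
  if (length(use) < min_points) {
    return(list(index = integer(0), status = "insufficient data"))
  }
  t <- series$t[use]; y <- series$logodds[use]
  n <- length(use)
  for (start in seq_len(n - min_points + 1L)) {
    idx <- start:n
    fit <- stats::lm.fit(cbind(1, t[idx]), y[idx])
    if (max(abs(fit$residuals)) < tolerance + 1e-12) {
      return(list(index = use[idx], status = "ok"))
    }
  }
  list(index = integer(0), status = "no steady state")
}

#' Estimate the growth-rate difference from a ratio series
#'
#' The slope of log-odds versus time over the steady window equals the
#' growth-rate difference between the competitors (numerator strain minus
#' denominator strain, 1/h): exponential odds growth at rate delta-mu.
#' Ordinary least squares supplies the slope and its standard error from the
#' residual variance (SE = 0 for an exactly linear series).
#'
#' @param series a [ratio_series()].
#' @param window integer index vector into `series` (e.g. from
#'   [detect_steady_window()]); defaults to all usable points.
#' @return List with `delta_mu` (1/h), `se`, `n` (points used), and
#'   `dropped` (points in the window unusable due to zero counts).
#' @export
estimate_fitness_difference <- function(series, window = NULL) {
  if (is.null(window)) window <- which(series$usable)
  dropped <- sum(!series$usable[window])
  window <- window[series$usable[window]]
  if (length(window) < 3L)
    stop("need at least 3 usable points in the window", call. = FALSE)
  t <- series$t[window]; y <- series$logodds[window]
  fit <- stats::lm(y ~ t)
  # suppress the "essentially perfect fit" note: exact series are expected
  sm <- suppressWarnings(summary(fit))$coefficients
  se <- if (nrow(sm) >= 2L) sm["t", "Std. Error"] else NA_real_
  resid <- stats::residuals(fit)
  if (sum(resid^2) < 1e-20) se <- 0     # exactly linear input
  list(delta_mu = unname(stats::coef(fit)[2L]), se = unname(se),
       n = length(window), dropped = dropped)
}
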