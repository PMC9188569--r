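#' Sigmoidal model of the OD-dependent growth-rate difference
#'
#' The steady-state growth-rate difference between the two consortium members
#' (auxotroph minus slow prototroph) as a function of the turbidostat OD
#' setpoint:
#' \deqn{\Delta\mu(OD) = c_0 - c_1 / (1 + e^{-(OD - c_2)/c_3}),}
#' in 1/h. At low OD ample residual histidine leaves the auxotroph faster
#' (positive offset `c0`); as the setpoint rises, consumption depletes
#' histidine and the difference falls by up to `c1`, crossing zero at an
#' interior OD — the handle that makes ratio steering by OD possible.
#'
#' @param c0 offset, 1/h. @param c1 amplitude, 1/h (>= 0 for a non-increasing
#'   curve). @param c2 OD midpoint. @param c3 OD width (> 0).
#' @return A `ratio_model_params` object; `delta_mu(params, od)` evaluates it.
#' @export
ratio_model_params <- function(c0, c1, c2, c3) {
  if (c3 <= 0) stop("c3 (OD width) must be > 0", call. = FALSE)
  structure(list(c0 = c0, c1 = c1, c2 = c2, c3 = c3),
            class = "ratio_model_params")
}

#' @rdname ratio_model_params
#' @param params a `ratio_model_params`.
#' @param od OD values.
#' @export
delta_mu <- function(params, od) {
  params$c0 - params$c1 / (1 + exp(-(od - params$c2) / params$c3))
}

#' Fit the sigmoidal growth-rate-difference model
#'
#' Bounded least squares with seeded multi-starts on characterization pairs
#' `(OD setpoint, measured delta-mu)`. Constant data are a degenerate sigmoid
#' (any midpoint fits): they are detected up front and returned as
#' `c1 = 0`, `c0 = mean`, with zero residual.
#'
#' @param od OD setpoints (>= 4 distinct values for the 4 parameters).
#' @param dmu measured growth-rate differences, 1/h.
#' @param n_starts,seed multi-start control.
#' @return List with `params` ([ratio_model_params()]), `residuals`, `rss`.
#' @export
fit_ratio_model <- function(od, dmu, n_starts = 20L, seed = 0L) {
  if (length(unique(od)) < 4L)
    stop("need at least 4 distinct OD values to fit 4 parameters",
         call. = FALSE)
  if (length(od) != length(dmu)) stop("od and dmu lengths differ", call. = FALSE)
  if (stats::sd(dmu) < 1e-12) {
    par <- ratio_model_params(mean(dmu), 0, mean(range(od)), diff(range(od)) / 4)
    return(list(params = par, residuals = dmu - mean(dmu), rss = 0))
  }
  rng <- diff(range(od))
  lower <- c(min(dmu) - 0.5, 0, min(od) - rng, 1e-3)
  upper <- c(max(dmu) + 0.5, 2 * diff(range(dmu)) + 1, max(od) + rng, rng)
  objective <- function(p) {
    sum((delta_mu(ratio_model_params(p[1], p[2], p[3], p[4]), od) - dmu)^2)
  }
  ms <- multistart_optim(objective, lower, upper, n_starts = n_starts,
                         seed = seed)
  p <- ms$runs[[ms$best]]$par
  par <- ratio_model_params(p[1], p[2], p[3], p[4])
  list(params = par, residuals = delta_mu(par, od) - dmu,
       rss = ms$values[ms$best])
}

#' Two-strain ratio dynamics under an OD profile
#'
#' In co-culture the odds of the focal (auxotroph) strain grow exponentially
#' at the instantaneous growth-rate difference:
#' `d/dt log(r / (1 - r)) = delta_mu(OD(t))`. For a piecewise-constant OD
#' profile the log-odds integral is exact (no numerical stepping). Ratios 0
#' and 1 are absorbing: the trajectory stays constant there.
#'
#' @param r0 initial auxotroph fraction in `[0, 1]`.
#' @param od_times,od_values step OD profile: `OD(t) = od_values[i]` for
#'   `t in [od_times[i], od_times[i+1])`; the last value extends to the end.
#' @param params a [ratio_model_params()].
#' @param times output times, h (>= `od_times[1]`).
#' @return data.frame with `t`, `ratio`, `logodds` (`+-Inf` at the absorbing
#'   states).
#' @export
ratio_dynamics <- function(r0, od_times, od_values, params, times) {
  if (r0 < 0 || r0 > 1) stop("r0 must lie in [0, 1]", call. = FALSE)
  if (length(od_times) != length(od_values))
    stop("od_times and od_values lengths differ", call. = FALSE)
  if (is.unsorted(od_times)) stop("od_times must be increasing", call. = FALSE)
  if (r0 %in% c(0, 1)) {
    return(data.frame(t = times, ratio = r0,
                      logodds = if (r0 == 0) -Inf else Inf))
  }
  l0 <- log(r0 / (1 - r0))
  t0 <- od_times[1]
  # cumulative integral of delta_mu(OD(t)) from t0 to each output time
  integral_to <- function(tt) {
    ends <- c(od_times[-1], Inf)
    dt <- pmax(0, pmin(tt, ends) - pmax(t0, od_times))
    sum(delta_mu(params, od_values) * dt)
  }
  lo <- l0 + vapply(times, integral_to, numeric(1))
  data.frame(t = times, ratio = stats::plogis(lo), logodds = lo)
}

#' OD-setpoint planning for consortium-ratio control
#'
#' Optimizes a vector of future OD setpoints (one per `block_h`-hour block
#' over the horizon; by default changing every 2 h for the next 10 h) so
#' that the predicted ratio — propagated through [ratio_dynamics()] — tracks
#' the target at the block ends. Bounded gradient-based search with seeded
#' multi-starts; on total optimizer failure the previous plan is returned
#' with an `error` field (fail-safe).
#'
#' @param current,target auxotroph fractions in (0, 1).
#' @param params a [ratio_model_params()].
#' @param n_blocks number of setpoint blocks (default 5).
#' @param block_h block duration, h (default 2).
#' @param od_bounds setpoint bounds (default `c(0.1, 0.8)`, the explored
#'   characterization range).
#' @param n_starts,seed multi-start control.
#' @param warm_start optional previous plan (fallback on failure).
#' @return List with `setpoints`, `predicted` (ratio at block ends),
#'   `objective`, `error`.
#' @export
plan_od <- function(current, target, params, n_blocks = 5L, block_h = 2,
                    od_bounds = c(0.1, 0.8), n_starts = 10L, seed = 0L,
                    warm_start = NULL) {
  if (current <= 0 || current >= 1 || target <= 0 || target >= 1)
    stop("current and target ratios must lie in (0, 1)", call. = FALSE)
  block_ends <- seq_len(n_blocks) * block_h
  objective <- function(od) {
    tr <- ratio_dynamics(current, od_times = (seq_len(n_blocks) - 1) * block_h,
                         od_values = od, params = params, times = block_ends)
    sum((tr$ratio - target)^2)
  }
  extra <- list(rep(mean(od_bounds), n_blocks),
                rep(od_bounds[1], n_blocks), rep(od_bounds[2], n_blocks))
  if (!is.null(warm_start)) extra <- c(list(warm_start), extra)
  ms <- tryCatch(
    multistart_optim(objective, lower = rep(od_bounds[1], n_blocks),
                     upper = rep(od_bounds[2], n_blocks),
                     n_starts = n_starts, seed = seed, extra_starts = extra),
    error = function(e) e)
  if (inherits(ms, "error")) {
    fb <- if (is.null(warm_start)) rep(mean(od_bounds), n_blocks) else warm_start
    return(list(setpoints = fb, predicted = NA_real_, objective = NA_real_,
                error = conditionMessage(ms)))
  }
  od <- ms$runs[[ms$best]]$par
  tr <- ratio_dynamics(current, (seq_len(n_blocks) - 1) * block_h, od,
                       params, block_ends)
  list(setpoints = od, predicted = tr$ratio, objective = ms$values[ms$best],
       error = NULL)
}
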