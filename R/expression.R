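#' Parameters of the light-driven gene expression model
#'
#' The two-variable model of EL222-driven expression:
#' \deqn{dm/dt = \sigma L(t) - \gamma_m m, \qquad
#'       dFP/dt = k_m m - \gamma_{FP} FP,}
#' with `L(t)` in {0, 1} the instantaneous blue-light state. mRNA units are
#' arbitrary (only `k_m * m` is observable from protein medians), so by
#' default `k_m` is tied to `gamma_m`, which fixes the units and makes the
#' three remaining parameters identifiable. Fitted reference values are
#' `gamma_m = 2.09 1/h`, `sigma = 0.64 RPU/h`, `gamma_FP = 0.475 1/h`
#' (mRNA half-life about 20 min, protein about 1.46 h, mostly dilution).
#'
#' @param gamma_m mRNA decay rate, 1/h.
#' @param sigma maximal transcription rate, RPU/h.
#' @param gamma_FP protein decay/dilution rate, 1/h.
#' @param k_m translation rate constant, 1/h; `NULL` (default) ties it to
#'   `gamma_m`.
#' @return An `expression_params` object with element `k_m_tied` recording
#'   whether the tie is in force.
#' @export
expression_params <- function(gamma_m = 2.09, sigma = 0.64, gamma_FP = 0.475,
                              k_m = NULL) {
  tied <- is.null(k_m)
  if (tied) k_m <- gamma_m
  if (gamma_m <= 0 || sigma < 0 || gamma_FP <= 0 || k_m <= 0)
    stop("rates must be positive (sigma may be 0)", call. = FALSE)
  structure(list(gamma_m = gamma_m, sigma = sigma, gamma_FP = gamma_FP,
                 k_m = k_m, k_m_tied = tied),
            class = "expression_params")
}

#' @export
print.expression_params <- function(x, ...) {
  cat(sprintf(
    "<expression_params: gamma_m=%.4g /h, sigma=%.4g RPU/h, gamma_FP=%.4g /h, k_m=%.4g /h%s>\n",
    x$gamma_m, x$sigma, x$gamma_FP, x$k_m,
    if (x$k_m_tied) " (tied to gamma_m)" else ""))
  invisible(x)
}

#' Expression state
#'
#' @param mRNA mRNA level, model units (>= 0).
#' @param FP fluorescent protein level, RPU (>= 0).
#' @param t time, h.
#' @export
expression_state <- function(mRNA = 0, FP = 0, t = 0) {
  if (mRNA < 0 || FP < 0)
    stop("initial state must be non-negative", call. = FALSE)
  structure(list(mRNA = mRNA, FP = FP, t = t), class = "expression_state")
}

#' Duty-cycled light program
#'
#' Piecewise-constant light actuation: time is split into cycles of fixed
#' period; within cycle `k` the light is ON for `duty[k] * period` at the
#' start of the cycle and OFF for the remainder (ON-first convention; at a
#' 30-min period relative to the ~29-min mRNA lifetime the integrated
#' response depends only weakly on within-cycle placement). Light is OFF
#' before `t_start` and after the program ends.
#'
#' @param duty numeric vector of duty fractions in `[0, 1]`, one per cycle.
#' @param period_min cycle period in minutes (default 30).
#' @param t_start program start time, h.
#' @return A `light_program` object.
#' @export
light_program <- function(duty, period_min = 30, t_start = 0) {
  if (any(duty < -1e-12 | duty > 1 + 1e-12))
    stop("duty fractions must lie in [0, 1]", call. = FALSE)
  if (period_min <= 0) stop("period must be positive", call. = FALSE)
  structure(list(duty = pmin(pmax(as.numeric(duty), 0), 1),
                 period_h = period_min / 60, t_start = t_start),
            class = "light_program")
}

# piecewise-constant segments (start, end, L) covering [t_start, program end]
light_segments <- function(light) {
  P <- light$period_h
  k <- length(light$duty)
  if (k == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0), L = numeric(0)))
  }
  t0 <- light$t_start + (seq_len(k) - 1L) * P
  on_end <- t0 + light$duty * P
  seg <- rbind(
    data.frame(start = t0, end = on_end, L = 1),
    data.frame(start = on_end, end = t0 + P, L = 0))
  seg <- seg[order(seg$start), , drop = FALSE]
  seg[seg$end - seg$start > 1e-15, , drop = FALSE]
}

#' Instantaneous light state of a program
#'
#' @param light a [light_program()].
#' @param t times, h.
#' @return 0/1 vector: light state at each time (OFF outside the program).
#' @export
light_state <- function(light, t) {
  P <- light$period_h
  rel <- t - light$t_start
  k <- floor(rel / P + 1e-12) + 1
  inside <- rel >= -1e-12 & k >= 1 & k <= length(light$duty)
  out <- numeric(length(t))
  ki <- pmin(pmax(k[inside], 1), length(light$duty))
  phase <- rel[inside] - (ki - 1) * P
  out[inside] <- as.numeric(phase < light$duty[ki] * P - 1e-12)
  out
}

# exact advance of (m, FP) over dt under constant light L
advance_expression <- function(m0, FP0, L, dt, par) {
  gm <- par$gamma_m; gf <- par$gamma_FP; km <- par$k_m
  ms <- par$sigma * L / gm
  em <- exp(-gm * dt)
  ef <- exp(-gf * dt)
  m1 <- ms + (m0 - ms) * em
  FPs <- km * ms / gf
  cross <- if (abs(gf - gm) > 1e-9 * max(gf, gm)) {
    km * (m0 - ms) * (em - ef) / (gf - gm)
  } else {
    km * (m0 - ms) * dt * em
  }
  FP1 <- FPs + (FP0 - FPs) * ef + cross
  c(m = m1, FP = FP1)
}

#' Simulate the expression model under a light program
#'
#' Integrates the linear ODE exactly on each constant-light segment (no
#' numerical stepping): on a segment with light `L`, mRNA relaxes
#' exponentially towards `sigma * L / gamma_m` and FP follows the standard
#' two-exponential solution. Light is OFF after the program ends.
#'
#' @param params an [expression_params()].
#' @param state0 an [expression_state()]; its `t` is the simulation start.
#' @param light a [light_program()].
#' @param times increasing numeric vector of output times, h, all
#'   `>= state0$t`.
#' @return data.frame with columns `t`, `mRNA`, `FP`, `L` (light state).
#' @examples
#' par <- expression_params()
#' lp <- light_program(rep(1, 20))  # constant light for 10 h
#' tail(simulate_expression(par, expression_state(), lp, seq(0, 10, 0.5)), 1)
#' # steady state: sigma / gamma_FP
#' par$sigma / par$gamma_FP
#' @export
simulate_expression <- function(params, state0, light, times) {
  stopifnot(inherits(params, "expression_params"),
            inherits(state0, "expression_state"),
            inherits(light, "light_program"))
  if (is.unsorted(times, strictly = FALSE))
    stop("times must be increasing", call. = FALSE)
  if (length(times) && times[1] < state0$t - 1e-12)
    stop("times must not precede the initial state", call. = FALSE)
  seg <- light_segments(light)
  brk <- sort(unique(c(state0$t, times,
                       seg$start[seg$start > state0$t],
                       seg$end[seg$end > state0$t])))
  brk <- brk[brk >= state0$t - 1e-12]
  m <- state0$mRNA; FP <- state0$FP
  out_m <- numeric(length(times)); out_f <- numeric(length(times))
  want <- 1L
  # record any output equal to the start time
  while (want <= length(times) && times[want] <= state0$t + 1e-12) {
    out_m[want] <- m; out_f[want] <- FP; want <- want + 1L
  }
  for (i in seq_len(length(brk) - 1L)) {
    t0 <- brk[i]; t1 <- brk[i + 1L]
    L <- light_state(light, (t0 + t1) / 2)
    st <- advance_expression(m, FP, L, t1 - t0, params)
    m <- st[["m"]]; FP <- st[["FP"]]
    while (want <= length(times) && times[want] <= t1 + 1e-12) {
      out_m[want] <- m; out_f[want] <- FP; want <- want + 1L
    }
  }
  data.frame(t = times, mRNA = pmax(out_m, 0), FP = pmax(out_f, 0),
             L = light_state(light, times))
}
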