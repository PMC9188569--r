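#' Light MPC configuration
#'
#' Receding-horizon settings for duty-cycled light control: by default 10
#' cycles of 30 min (a 5-h horizon), re-planned every hour when fresh
#' cytometry data arrive.
#'
#' @param n_cycles number of duty cycles in the horizon (default 10).
#' @param period_min cycle period, min (default 30).
#' @param grid_step_min objective evaluation grid step, min (default 6).
#' @param replan_interval_h re-planning interval, h (default 1).
#' @param n_starts number of seeded random multi-starts added to the warm /
#'   boundary starts (default 5).
#' @param seed integer seed for the random starts.
#' @export
light_mpc_config <- function(n_cycles = 10L, period_min = 30,
                             grid_step_min = 6, replan_interval_h = 1,
                             n_starts = 5L, seed = 0L) {
  stopifnot(n_cycles >= 1, period_min > 0, grid_step_min > 0,
            replan_interval_h > 0)
  structure(list(n_cycles = as.integer(n_cycles), period_min = period_min,
                 grid_step_min = grid_step_min,
                 replan_interval_h = replan_interval_h,
                 horizon_h = n_cycles * period_min / 60,
                 n_starts = as.integer(n_starts), seed = as.integer(seed)),
            class = "light_mpc_config")
}

# vectorized exact advance: (m0, FP0) scalars, constant light L, tau vector
advance_expression_vec <- function(m0, FP0, L, tau, par) {
  gm <- par$gamma_m; gf <- par$gamma_FP; km <- par$k_m
  ms <- par$sigma * L / gm
  em <- exp(-gm * tau)
  ef <- exp(-gf * tau)
  m <- ms + (m0 - ms) * em
  FPs <- km * ms / gf
  cross <- if (abs(gf - gm) > 1e-9 * max(gf, gm)) {
    km * (m0 - ms) * (em - ef) / (gf - gm)
  } else {
    km * (m0 - ms) * tau * em
  }
  list(m = m, FP = FPs + (FP0 - FPs) * ef + cross)
}

# mean squared deviation of predicted FP from target over the horizon grid.
# Dedicated fast path (called thousands of times inside the planner): exact
# closed-form propagation cycle by cycle; agrees with simulate_expression to
# rounding (property-tested).
light_mpc_objective <- function(duty, state, target, params, config) {
  P <- config$period_min / 60
  step <- config$grid_step_min / 60
  k <- length(duty)
  grid <- seq(step, k * P, by = step)      # relative to state$t
  ci <- pmin(ceiling(grid / P - 1e-12), k) # cycle index per grid point
  off <- grid - (ci - 1) * P               # offset within its cycle
  m <- state$mRNA; FP <- state$FP
  sq <- 0
  for (j in seq_len(k)) {
    ton <- duty[j] * P
    idx <- which(ci == j)
    o <- off[idx]
    on_pts <- o <= ton + 1e-12
    if (any(on_pts)) {
      v <- advance_expression_vec(m, FP, 1, o[on_pts], params)
      sq <- sq + sum((v$FP - target)^2)
    }
    end_on <- advance_expression_vec(m, FP, 1, ton, params)
    if (any(!on_pts)) {
      v <- advance_expression_vec(end_on$m, end_on$FP, 0,
                                  o[!on_pts] - ton, params)
      sq <- sq + sum((v$FP - target)^2)
    }
    end <- advance_expression_vec(end_on$m, end_on$FP, 0, P - ton, params)
    m <- end$m; FP <- end$FP
  }
  sq / length(grid)
}

#' Plan duty-cycled light by model-predictive control
#'
#' Finds the sequence of duty fractions minimizing the mean squared deviation
#' of model-predicted FP from the target over the horizon, by bounded
#' gradient-based search (L-BFGS-B) from a deterministic start set: the
#' supplied warm start (the previous plan shifted by one cycle is the usual
#' choice), all-OFF, all-ON, and seeded random starts. If every start fails,
#' the warm start (previous plan) is returned with an `error` field — the
#' fail-safe contract for unattended runs.
#'
#' @param state current [expression_state()] (typically from
#'   [estimate_state()]).
#' @param target FP target, RPU (>= 0). Targets at or above the maximal
#'   steady state `sigma / gamma_FP` saturate all duties at 1 and set the
#'   `saturated` flag.
#' @param params an [expression_params()].
#' @param config a [light_mpc_config()].
#' @param warm_start optional duty vector used both as a start and as the
#'   fail-safe fallback.
#' @return List with `duty` (length `n_cycles`), `objective`, `saturated`
#'   (all duties at a bound) and `error` (NULL unless all starts failed).
#' @export
plan_light <- function(state, target, params, config = light_mpc_config(),
                       warm_start = NULL) {
  stopifnot(inherits(state, "expression_state"), target >= 0)
  k <- config$n_cycles
  objective <- function(u) light_mpc_objective(u, state, target, params, config)
  extra <- list(rep(0, k), rep(1, k))
  if (!is.null(warm_start)) {
    stopifnot(length(warm_start) == k)
    extra <- c(list(pmin(pmax(warm_start, 0), 1)), extra)
  }
  ms <- tryCatch(
    multistart_optim(objective, lower = rep(0, k), upper = rep(1, k),
                     n_starts = config$n_starts, seed = config$seed,
                     extra_starts = extra,
                     control = list(maxit = 200L, factr = 1e7)),
    error = function(e) e)
  if (inherits(ms, "error")) {
    fallback <- if (is.null(warm_start)) rep(0, k) else warm_start
    return(list(duty = fallback, objective = NA_real_, saturated = FALSE,
                error = conditionMessage(ms)))
  }
  duty <- pmin(pmax(ms$runs[[ms$best]]$par, 0), 1)
  list(duty = duty, objective = ms$values[ms$best],
       saturated = all(duty > 1 - 1e-6) || all(duty < 1e-6),
       error = NULL)
}

#' Closed-loop light MPC on the model plant
#'
#' Simulates the full hourly loop of the light-control experiment against a
#' noise-free model plant: sample FP, estimate the state (open-loop mRNA +
#' measured FP, advanced through the data delay), re-plan the duty sequence
#' with a one-cycle-shifted warm start, and apply the first cycles until the
#' next measurement. This is the package-internal reference loop; the same
#' behavior is expressible through the orchestrator's event system.
#'
#' @param target FP target, RPU.
#' @param params plant and controller parameters (identical here: the
#'   noise-free case).
#' @param duration_h total experiment duration, h.
#' @param config a [light_mpc_config()].
#' @param delay_h data-arrival delay fed to [estimate_state()].
#' @return data.frame with one row per measurement time: `t`, `FP_measured`,
#'   plus the applied duty for the following interval (list column `duty`).
#' @export
closed_loop_light <- function(target, params, duration_h = 10,
                              config = light_mpc_config(), delay_h = 0) {
  per_h <- config$period_min / 60
  cyc_per_replan <- max(1L, round(config$replan_interval_h / per_h))
  applied <- numeric(0)           # duty fractions applied so far, one per cycle
  plan <- NULL
  t <- 0
  rows <- list()
  plant <- expression_state()
  while (t < duration_h - 1e-9) {
    # measurement at time t from the plant (noise-free)
    measurement <- plant$FP
    hist_lp <- light_program(if (length(applied)) applied else numeric(0),
                             period_min = config$period_min)
    est <- estimate_state(measurement, hist_lp, params, t_sample = t,
                          delay = delay_h)
    warm <- if (!is.null(plan)) c(plan$duty[-seq_len(cyc_per_replan)],
                                  rep(utils::tail(plan$duty, 1), cyc_per_replan))
            else NULL
    plan <- plan_light(est, target, params, config, warm_start = warm)
    rows[[length(rows) + 1L]] <-
      data.frame(t = t, FP_measured = measurement,
                 duty1 = plan$duty[1])
    apply_now <- plan$duty[seq_len(cyc_per_replan)]
    applied <- c(applied, apply_now)
    # advance the plant through the applied cycles
    seg_lp <- light_program(apply_now, period_min = config$period_min,
                            t_start = t)
    t_next <- min(t + cyc_per_replan * per_h, duration_h)
    sim <- simulate_expression(params, plant, seg_lp, t_next)
    plant <- expression_state(sim$mRNA[1], sim$FP[1], t_next)
    t <- t_next
  }
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(t = t, FP_measured = plant$FP, duty1 = NA_real_))
  attr(out, "final_FP") <- plant$FP
  out
}
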