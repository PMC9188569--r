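#' Full cytometry processing pipeline
#'
#' Chains the per-sample processing performed on the fly during experiments:
#' gate, deconvolve, normalize to RPU, and optionally classify genotypes.
#'
#' @param events an [event_table()].
#' @param sig a [spectral_signature()].
#' @param ref an [rpu_reference()].
#' @param config a [gate_config()].
#' @param rules optional [genotype_rules()].
#' @param nonneg passed to [deconvolve()].
#' @return List with `mask` (gate keep-mask), `amounts` (gated, deconvolved),
#'   `rpu` (gated, FSC-normalized, RPU), `medians` (per-fluorophore median
#'   RPU), and, with rules, `labels` and `fractions`.
#' @export
process_events <- function(events, sig, ref, config = gate_config(),
                           rules = NULL, nonneg = FALSE) {
  mask <- gate(events, config)
  kept <- as.data.frame(events)[as.logical(mask), , drop = FALSE]
  class(kept) <- c("event_table", "data.frame")
  dec <- deconvolve(kept, sig, nonneg = nonneg)
  rpu <- to_rpu(dec$amounts, kept$fsc, ref)
  out <- list(mask = as.logical(mask), amounts = dec$amounts, rpu = rpu,
              medians = apply(rpu, 2L, stats::median))
  if (!is.null(rules)) {
    cl <- classify(rpu, rules)
    out$labels <- cl$labels
    out$fractions <- cl$fractions
  }
  out
}

#' Build the virtual light-controlled reactor endpoint
#'
#' A turbidostat-grown optogenetic strain as an instrument: the endpoint owns
#' the expression-model plant and the applied light history. Operations:
#' `tick` (advance one cycle, consuming the pending duty queue, light OFF
#' when the queue is empty), `actuate` (replace the pending duty queue),
#' `measure` (return the plant FP — exact, or the median of a simulated
#' cytometry acquisition when `measurement = "cytometry"`).
#'
#' @param params an [expression_params()] (the plant truth).
#' @param period_min duty-cycle period, min; `tick` advances one period.
#' @param measurement `"exact"` or `"cytometry"`.
#' @param cytometry for `"cytometry"`: list with `signature`, `ref`,
#'   `fluorophore`, `n_events`, `noise_sd`, `fsc_meanlog`, `fsc_sdlog`.
#' @param seed base seed for simulated acquisitions.
#' @return An [instrument_endpoint()] named `"reactor"`.
#' @export
light_reactor_endpoint <- function(params, period_min = 30,
                                   measurement = c("exact", "cytometry"),
                                   cytometry = NULL, seed = 1L) {
  measurement <- match.arg(measurement)
  st <- new.env(parent = emptyenv())
  st$plant <- expression_state()
  st$applied <- numeric(0)
  st$pending <- numeric(0)
  st$period_h <- period_min / 60
  st$params <- params
  st$acq <- 0L
  ops <- list(
    tick = function(state, p) {
      duty <- if (length(state$pending)) state$pending[1] else 0
      state$pending <- if (length(state$pending)) state$pending[-1] else numeric(0)
      lp <- light_program(duty, period_min = state$period_h * 60,
                          t_start = state$plant$t)
      t1 <- state$plant$t + state$period_h
      sim <- simulate_expression(state$params, state$plant, lp, t1)
      state$applied <- c(state$applied, duty)
      state$plant <- expression_state(sim$mRNA[1], sim$FP[1], t1)
      list(t = t1, FP = state$plant$FP)
    },
    actuate = function(state, p) {
      state$pending <- as.numeric(p$duty)
      list(n_pending = length(state$pending))
    },
    measure = function(state, p) {
      state$acq <- state$acq + 1L
      fp <- state$plant$FP
      if (measurement == "cytometry") {
        cy <- cytometry
        sp <- population_spec(
          strains = list(opto = list(
            fraction = 1,
            meanlog = stats::setNames(
              fp_to_meanlog(fp, cy$ref$medians[[cy$fluorophore]],
                            cy$fsc_meanlog %||% log(1000)),
              cy$fluorophore),
            sdlog = stats::setNames(cy$sdlog %||% 0.25, cy$fluorophore))),
          signature = cy$signature, n_events = cy$n_events %||% 2000L,
          noise_sd = cy$noise_sd %||% 0.05,
          fsc_meanlog = cy$fsc_meanlog %||% log(1000),
          seed = seed + state$acq)
        g <- generate_events(sp)
        pr <- process_events(g$events, cy$signature, cy$ref)
        fp <- unname(pr$medians[[cy$fluorophore]])
      }
      list(FP = fp, t = state$plant$t)
    },
    applied_history = function(state, p) list(duty = state$applied),
    state_digest = function(state, p) list(t = state$plant$t,
                                           FP = state$plant$FP))
  instrument_endpoint("reactor", ops, state = st)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a closed-loop light-control experiment through the event system
#'
#' Wires the Fig-3-style loop purely as orchestrator events: a periodic MPC
#' event acquires a measurement from the reactor endpoint, estimates the
#' model state from it and the logged light history, re-plans the duty
#' sequence, and actuates the first interval. Everything the loop does is in
#' the experiment log and replayable.
#'
#' @param target FP target, RPU.
#' @param params controller model parameters (also the plant truth for the
#'   noise-free run).
#' @param duration_h experiment duration, h.
#' @param config a [light_mpc_config()].
#' @param reactor optional pre-built endpoint from
#'   [light_reactor_endpoint()].
#' @param seed experiment seed.
#' @return List with `experiment` (log, instruments), `trajectory`
#'   (data.frame of measurement times and FP) and `final_FP`.
#' @export
run_light_control <- function(target, params, duration_h = 10,
                              config = light_mpc_config(),
                              reactor = NULL, seed = 1L) {
  if (is.null(reactor)) reactor <- light_reactor_endpoint(params, config$period_min)
  ex <- new_experiment(list(reactor = reactor), seed = seed)
  per_h <- config$period_min / 60
  cyc <- max(1L, round(config$replan_interval_h / per_h))
  ex$data$plan <- NULL
  ex$data$traj <- list()
  mpc <- experiment_event(
    name = "mpc",
    condition = function(ctx) TRUE,
    action = function(ctx) {
      meas <- invoke_logged(ctx, "reactor", "measure")
      hist <- invoke_logged(ctx, "reactor", "applied_history")
      lp <- light_program(as.numeric(hist$payload$duty),
                          period_min = config$period_min)
      est <- estimate_state(meas$payload$FP, lp, params,
                            t_sample = meas$payload$t, delay = 0)
      warm <- if (!is.null(ctx$data$plan))
        c(ctx$data$plan[-seq_len(cyc)], rep(utils::tail(ctx$data$plan, 1), cyc))
      plan <- plan_light(est, target, params, config, warm_start = warm)
      ctx$data$plan <- plan$duty
      ctx$data$traj[[length(ctx$data$traj) + 1L]] <-
        data.frame(t = meas$payload$t, FP = meas$payload$FP)
      invoke_logged(ctx, "reactor", "actuate",
                    list(duty = plan$duty[seq_len(cyc)]))
    },
    schedule = "periodic", interval_h = config$replan_interval_h)
  register_event(ex, mpc)
  run_experiment(ex, duration_h, tick_h = per_h)
  traj <- do.call(rbind, ex$data$traj)
  list(experiment = ex, trajectory = traj, final_FP = reactor$state$plant$FP)
}
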