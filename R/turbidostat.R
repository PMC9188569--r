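#' Growth model for the simulated turbidostat
#'
#' Per-strain growth kinetics with optional histidine dependence. A
#' prototroph grows at its intrinsic rate `mu_max`. A histidine auxotroph is
#' limited by uptake through its high-affinity transporter (Monod constant
#' `K_m`, literature value 17 uM) and grows at
#' \deqn{\mu(h) = \min(\mu_{max},\; \mu_T \, h / (K_m + h)),}
#' a transport-limited Monod law with an intrinsic-rate cap: `mu_T` is the
#' growth rate the transporter flux could sustain at saturation. With
#' `mu_T > mu_max` the auxotroph grows at full speed while residual
#' histidine is plentiful and collapses as it is depleted — the regime
#' change that makes the growth-rate difference steerable by OD. Every
#' strain consumes `q` uM of histidine per OD unit of biomass produced
#' (prototrophs import it preferentially rather than synthesizing it).
#'
#' Default calibration (stated in the methods vignette): `mu_max = 0.45 1/h`
#' for both strains of the competition pair, `mu_T = 1.25 1/h`, `q = 20
#' uM/OD`. At feed `h_in = 20 uM` the steady residual histidine is
#' `h = h_in - q * OD`, giving a near-zero growth-rate difference below OD
#' 0.6 that exceeds 0.2 1/h at OD 0.8; at `h_in = 4 uM` the auxotroph is
#' outcompeted at every setpoint.
#'
#' @param strains named list; each element a list with `mu_max` (1/h),
#'   `his_dependent` (logical), and optionally `mu_T` (1/h), `K_m` (uM),
#'   `q` (uM/OD) overriding the shared defaults.
#' @param h_in feed histidine concentration, uM (paper regimes: 4 or 20).
#' @param K_m shared Monod constant, uM (default 17).
#' @param mu_T shared transport-capacity rate, 1/h (default 1.25).
#' @param q shared histidine yield, uM consumed per OD produced (default 20).
#' @return A `growth_model` object.
#' @export
growth_model <- function(strains, h_in = 20, K_m = 17, mu_T = 1.25, q = 20) {
  if (K_m <= 0 || q < 0 || h_in < 0) stop("invalid growth parameters",
                                          call. = FALSE)
  strains <- lapply(strains, function(s) {
    if (is.null(s$mu_max) || s$mu_max <= 0)
      stop("each strain needs mu_max > 0", call. = FALSE)
    s$his_dependent <- isTRUE(s$his_dependent)
    if (is.null(s$K_m)) s$K_m <- K_m
    if (is.null(s$mu_T)) s$mu_T <- mu_T
    if (is.null(s$q)) s$q <- q
    s
  })
  structure(list(strains = strains, h_in = h_in),
            class = "growth_model")
}

# per-strain growth rates at histidine concentration h (uM)
strain_growth_rates <- function(model, h) {
  vapply(model$strains, function(s) {
    if (s$his_dependent) min(s$mu_max, s$mu_T * h / (s$K_m + h)) else s$mu_max
  }, numeric(1))
}

#' Turbidostat culture state
#'
#' A fixed-volume (default 30 mL) continuous culture whose dilution is
#' actuated to hold the optical density at a setpoint (default 0.5). OD is
#' the sum of per-strain biomass densities; in- and out-flows are balanced,
#' so volume is constant.
#'
#' @param densities named numeric vector of per-strain biomass densities, OD
#'   units (>= 0); names must match the growth model's strains.
#' @param h histidine concentration in the vessel, uM.
#' @param setpoint OD setpoint (default 0.5).
#' @param volume_ml culture volume, mL (default 30; constant).
#' @param light_duty current light duty fraction in `[0, 1]` (carried for
#'   optogenetic strains; does not affect growth).
#' @param t time, h.
#' @return A `turbidostat_state` object; `od(state)` gives total OD.
#' @export
turbidostat_state <- function(densities, h = 20, setpoint = 0.5,
                              volume_ml = 30, light_duty = 0, t = 0) {
  if (any(densities < 0)) stop("densities must be >= 0", call. = FALSE)
  if (h < 0) stop("histidine concentration must be >= 0", call. = FALSE)
  structure(list(densities = densities, h = h, setpoint = setpoint,
                 volume_ml = volume_ml, light_duty = light_duty, t = t),
            class = "turbidostat_state")
}

#' @rdname turbidostat_state
#' @param state a `turbidostat_state`.
#' @export
od <- function(state) sum(state$densities)

#' Advance the turbidostat by one time step
#'
#' Integrates the batch/turbidostat dynamics with internal sub-stepping:
#' \deqn{dX_i/dt = (\mu_i - D) X_i, \qquad
#'       dh/dt = D (h_{in} - h) - \sum_i q_i \mu_i X_i,}
#' with the ideal turbidostat law `D =` total specific growth rate while the
#' culture is at (or above) the setpoint, and `D = 0` below it. Histidine is
#' clamped at zero (consumption cannot exceed what is present: in the
#' depleted regime the Monod factor shuts growth down first). Sub-steps are
#' sized so that no rate moves the state by more than ~0.5% per sub-step.
#'
#' @param state a [turbidostat_state()].
#' @param model a [growth_model()] whose strain names match the state.
#' @param dt step duration, h.
#' @return The updated state, with attribute `D_mean` (time-averaged dilution
#'   rate over the step) and `growth_dilution_gap` (absolute OD imbalance
#'   between integrated growth and dilution while holding, a mass-balance
#'   diagnostic).
#' @export
turbidostat_step <- function(state, model, dt) {
  stopifnot(inherits(state, "turbidostat_state"),
            inherits(model, "growth_model"))
  if (!setequal(names(state$densities), names(model$strains)))
    stop("state and model strain names differ", call. = FALSE)
  X <- state$densities[names(model$strains)]
  h <- state$h
  if (sum(X) == 0) {                      # sterile vessel: only medium turnover
    state$t <- state$t + dt
    attr(state, "D_mean") <- 0
    attr(state, "growth_dilution_gap") <- 0
    return(state)
  }
  mu_max_all <- max(vapply(model$strains, function(s) s$mu_max, numeric(1)))
  n_sub <- max(1L, ceiling(dt * mu_max_all / 0.005))
  h_sub <- dt / n_sub
  q <- vapply(model$strains, function(s) s$q, numeric(1))
  D_int <- 0; gap <- 0
  for (i in seq_len(n_sub)) {
    mu <- strain_growth_rates(model, h)
    total <- sum(X)
    holding <- total >= state$setpoint - 1e-12
    D <- if (holding) sum(mu * X) / total else 0
    growth <- mu * X
    X_new <- X + h_sub * (growth - D * X)
    # exact hold: renormalize to the setpoint once reached (continuous ideal)
    if (holding) {
      gap <- gap + abs(sum(X_new) - state$setpoint)
      X_new <- X_new * (state$setpoint / sum(X_new))
    } else if (sum(X_new) > state$setpoint) {
      X_new <- X_new * (state$setpoint / sum(X_new))  # crossed within sub-step
    }
    h_new <- h + h_sub * (D * (model$h_in - h) - sum(q * growth))
    if (h_new < 0) h_new <- 0
    X <- pmax(X_new, 0)
    h <- h_new
    D_int <- D_int + D * h_sub
  }
  out <- turbidostat_state(X, h, state$setpoint, state$volume_ml,
                           state$light_duty, state$t + dt)
  attr(out, "D_mean") <- D_int / dt
  attr(out, "growth_dilution_gap") <- gap
  out
}

#' Run the turbidostat to (quasi-)steady state
#'
#' Convenience wrapper stepping the simulator until the histidine
#' concentration and strain growth rates stop changing, or `t_max` is
#' reached. Composition may still be drifting (a competition in progress);
#' steadiness refers to OD and residual nutrient.
#'
#' @param state,model as in [turbidostat_step()].
#' @param t_max maximum simulated time, h.
#' @param dt step size, h.
#' @param tol relative change in `h` per step below which to stop.
#' @return The evolved state.
#' @export
turbidostat_settle <- function(state, model, t_max = 50, dt = 0.1,
                               tol = 1e-9) {
  h_prev <- state$h
  t_end <- state$t + t_max
  while (state$t < t_end) {
    state <- turbidostat_step(state, model, dt)
    if (abs(state$h - h_prev) <= tol * max(1, h_prev) &&
        od(state) >= state$setpoint - 1e-9) break
    h_prev <- state$h
  }
  state
}

#' Sample a culture into a cytometry population specification
#'
#' Bridges the simulated culture to the synthetic cytometer: strain fractions
#' are proportional to biomass densities, and per-strain fluorophore optics
#' (log-mean/log-sd of expressed amounts, a.u.) come from a per-strain optics
#' table — constitutive barcode fluorophores as constants, optogenetic
#' reporters from the expression model's current FP via `fp_to_meanlog`.
#'
#' @param state a [turbidostat_state()] with `od(state) > 0`.
#' @param optics named list (per strain) of lists with `meanlog` and `sdlog`
#'   named numeric vectors over fluorophores, as in [population_spec()].
#' @param signature a [spectral_signature()].
#' @param n_events events to acquire (> 0).
#' @param seed integer seed.
#' @param noise_sd,doublet_fraction,debris_fraction passed to
#'   [population_spec()].
#' @return A [population_spec()] whose strain fractions equal the culture's
#'   biomass fractions.
#' @export
sample_culture <- function(state, optics, signature, n_events, seed = 1L,
                           noise_sd = 0.05, doublet_fraction = 0,
                           debris_fraction = 0) {
  if (n_events <= 0) stop("n_events must be > 0", call. = FALSE)
  pos <- state$densities[state$densities > 0]
  if (length(pos) == 0L) stop("cannot sample a sterile culture", call. = FALSE)
  miss <- setdiff(names(pos), names(optics))
  if (length(miss))
    stop("optics missing for strain(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  fr <- pos / sum(pos)
  strains <- lapply(names(fr), function(s) {
    c(list(fraction = unname(fr[[s]])), optics[[s]])
  })
  names(strains) <- names(fr)
  population_spec(strains, signature, n_events,
                  doublet_fraction = doublet_fraction,
                  debris_fraction = debris_fraction,
                  noise_sd = noise_sd, seed = seed)
}

#' Map an FP level in RPU to the generator's log-mean amount
#'
#' Utility for optogenetic reporter strains: converts a model FP level (RPU)
#' into the log-mean amount (a.u.) the synthetic generator should draw, given
#' the RPU reference median and the typical forward scatter.
#'
#' @param fp FP level, RPU (values below `floor` are clipped).
#' @param ref_median reference median (a.u./a.u.) of the fluorophore.
#' @param fsc_meanlog log-mean forward scatter of the strain.
#' @param floor minimum RPU representable (default 1e-3).
#' @export
fp_to_meanlog <- function(fp, ref_median, fsc_meanlog = log(1000),
                          floor = 1e-3) {
  log(max(fp, floor) * ref_median) + fsc_meanlog
}
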