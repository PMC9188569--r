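# Shared fixtures: everything is generated in code, seeded, and small.

# two-channel identity-free signature with 30% cross-talk of mCerulean into
# the green channel (the overlapping pair the deconvolution exists for)
make_signature <- function(crosstalk = 0.3, autofluor = c(5, 5)) {
  S <- matrix(c(1, 0, crosstalk, 1), 2, 2,
              dimnames = list(c("GRN-B", "BLU-V"),
                              c("mNeonGreen", "mCerulean")))
  spectral_signature(S, autofluor)
}

make_identity_signature <- function(channels = c("c1", "c2"),
                                    fluors = c("f1", "f2")) {
  S <- diag(length(channels))
  dimnames(S) <- list(channels, fluors)
  spectral_signature(S)
}

# one tight single-strain population (green-only)
make_single_strain_spec <- function(n, seed = 0, noise_sd = 0.05, ...) {
  population_spec(
    strains = list(wt = list(fraction = 1,
                             meanlog = c(mNeonGreen = 6),
                             sdlog = c(mNeonGreen = 0.25))),
    signature = make_signature(), n_events = n, noise_sd = noise_sd,
    seed = seed, ...)
}

# two well-separated barcoded strains (competition-assay style)
make_two_strain_spec <- function(n, frac_aux = 5 / 6, seed = 0,
                                 noise_sd = 0.05, ...) {
  population_spec(
    strains = list(
      aux = list(fraction = frac_aux,
                 meanlog = c(mNeonGreen = 6), sdlog = c(mNeonGreen = 0.3)),
      wt = list(fraction = 1 - frac_aux,
                meanlog = c(mCerulean = 6), sdlog = c(mCerulean = 0.3))),
    signature = make_signature(), n_events = n, noise_sd = noise_sd,
    seed = seed, ...)
}

# RPU reference putting both barcode fluorophores' typical level at ~e^2 RPU,
# computed so the generator's meanlog-6 strains land well above 1 RPU
make_reference <- function() {
  rpu_reference(c(mNeonGreen = exp(6) / 1000 / exp(2),
                  mCerulean = exp(6) / 1000 / exp(2)))
}

make_genotype_rules <- function(threshold = 1) {
  genotype_rules(data.frame(
    label = c("wt", "aux"),
    fluorophore = c("mCerulean", "mNeonGreen"),
    dir = c(">=", ">="),
    threshold = threshold))
}

# competition growth model: his3 auxotroph vs same-background prototroph
make_competition_model <- function(h_in = 20) {
  growth_model(list(aux = list(mu_max = 0.45, his_dependent = TRUE),
                    wt = list(mu_max = 0.45)),
               h_in = h_in)
}

# per-strain optics used by sample_culture in end-to-end assays
make_optics <- function() {
  list(aux = list(meanlog = c(mNeonGreen = 6), sdlog = c(mNeonGreen = 0.3)),
       wt = list(meanlog = c(mCerulean = 6), sdlog = c(mCerulean = 0.3)))
}

# brute-force RK4 integrator for the expression ODE (independent oracle)
rk4_expression <- function(par, lp, t_end, dt = 1e-3) {
  f <- function(L, y) {
    c(par$sigma * L - par$gamma_m * y[1],
      par$k_m * y[1] - par$gamma_FP * y[2])
  }
  y <- c(0, 0)
  t <- 0
  n <- round(t_end / dt)
  for (i in seq_len(n)) {
    # dt is chosen to divide the light-switch grid, so light is constant
    # across each step: evaluate it once at the step midpoint
    L <- light_state(lp, t + dt / 2)
    k1 <- f(L, y)
    k2 <- f(L, y + dt / 2 * k1)
    k3 <- f(L, y + dt / 2 * k2)
    k4 <- f(L, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  c(mRNA = y[1], FP = y[2])
}

# run one simulated competition assay and estimate the growth-rate difference
# (positive = wild-type advantage), sampling the culture by cytometry
run_competition_assay <- function(setpoint, h_in, n_events = 2000,
                                  settle_h = 12, t_end = 10, seed = 0,
                                  tolerance = 0.1) {
  gm <- make_competition_model(h_in)
  st <- turbidostat_state(c(aux = setpoint * 5 / 6, wt = setpoint / 6),
                          h = h_in, setpoint = setpoint)
  st <- turbidostat_settle(st, gm, t_max = settle_h)
  sig <- make_signature()
  ref <- make_reference()
  rules <- make_genotype_rules()
  times <- seq(0, t_end, by = 2)
  n_wt <- n_aux <- numeric(length(times))
  for (i in seq_along(times)) {
    if (i > 1) st <- turbidostat_step(st, gm, 2)
    sp <- sample_culture(st, make_optics(), sig, n_events, seed = seed + i)
    pr <- process_events(generate_events(sp)$events, sig, ref, rules = rules)
    n_wt[i] <- sum(pr$labels == "wt")
    n_aux[i] <- sum(pr$labels == "aux")
  }
  rs <- ratio_series(times, n_wt, n_aux)
  w <- detect_steady_window(rs, tolerance = tolerance)
  est <- estimate_fitness_difference(rs, w$index)
  mu <- reacloop:::strain_growth_rates(gm, st$h)
  list(estimate = est, true_dmu = mu[["wt"]] - mu[["aux"]], state = st)
}
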