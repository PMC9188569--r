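# Virtual lab: turbidostat with histidine-limited growth, culture sampling,
# plate-reader bookkeeping.

test_that("turbidostat dynamics honor mass balance and the dilution law", {
  gm <- make_competition_model(20)

  # sterile vessel: nothing but the clock moves
  st0 <- turbidostat_state(c(aux = 0, wt = 0), h = 20)
  st1 <- turbidostat_step(st0, gm, 1)
  expect_equal(st1$densities, st0$densities)
  expect_equal(st1$h, st0$h)
  expect_equal(st1$t, 1)

  # prototroph-only culture held at setpoint: D equals mu_max exactly
  proto <- growth_model(list(wt = list(mu_max = 0.4)), h_in = 20)
  st <- turbidostat_state(c(wt = 0.5), h = 20, setpoint = 0.5)
  st <- turbidostat_step(st, proto, 2)
  expect_equal(attr(st, "D_mean"), 0.4, tolerance = 1e-9)
  expect_equal(od(st), 0.5)
  expect_lt(attr(st, "growth_dilution_gap"), 1e-8)

  # below the setpoint no dilution happens: pure exponential growth
  stb <- turbidostat_state(c(wt = 0.1), h = 20, setpoint = 0.5)
  stb <- turbidostat_step(stb, proto, 1)
  expect_equal(od(stb), 0.1 * exp(0.4), tolerance = 1e-3)
  expect_equal(attr(stb, "D_mean"), 0)

  # histidine never goes negative even under heavy consumption
  gm4 <- make_competition_model(4)
  sth <- turbidostat_state(c(aux = 0.6, wt = 0.2), h = 4, setpoint = 0.8)
  for (i in 1:10) {
    sth <- turbidostat_step(sth, gm4, 1)
    expect_gte(sth$h, 0)
  }
})

test_that("steady-state residual histidine matches a bisection oracle", {
  # auxotroph-only culture at setpoint X: D = mu(h), so the steady state
  # solves D (h_in - h) = q mu(h) X
  gm <- make_competition_model(20)
  X <- 0.5
  st <- turbidostat_state(c(aux = X, wt = 0), h = 20, setpoint = X)
  st <- turbidostat_settle(st, gm, t_max = 60)

  q <- gm$strains$aux$q
  mu_of <- function(h) min(0.45, 1.25 * h / (17 + h))
  f <- function(h) mu_of(h) * (20 - h) - q * mu_of(h) * X
  root <- uniroot(f, c(1e-3, 19.99), tol = 1e-12)$root
  expect_equal(st$h, root, tolerance = 1e-6)
})

test_that("the growth-rate difference sweeps reproduce the nutrient-limitation structure", {
  # 20 uM feed: negligible wild-type advantage at and below OD 0.5, above
  # 0.2/h at OD 0.8; 4 uM feed: auxotroph outcompeted at every setpoint
  dmu_at <- function(setpoint, h_in) {
    gm <- make_competition_model(h_in)
    st <- turbidostat_state(c(aux = setpoint * 5 / 6, wt = setpoint / 6),
                            h = h_in, setpoint = setpoint)
    st <- turbidostat_settle(st, gm, t_max = 60)
    mu <- reacloop:::strain_growth_rates(gm, st$h)
    mu[["wt"]] - mu[["aux"]]
  }
  sweep20 <- vapply(seq(0.1, 0.8, 0.1), dmu_at, numeric(1), h_in = 20)
  expect_lt(max(abs(sweep20[1:5])), 0.01)      # OD 0.1-0.5: neutral
  expect_lte(abs(sweep20[6]), 0.06)            # OD 0.6: still close to zero
  expect_gt(sweep20[8], 0.2)                   # OD 0.8: strong advantage
  expect_true(all(diff(sweep20) >= -1e-9))     # monotone in OD

  sweep4 <- vapply(c(0.1, 0.4, 0.8), dmu_at, numeric(1), h_in = 4)
  expect_true(all(sweep4 >= 0.3))              # full growth arrest
})

test_that("culture sampling preserves strain fractions end to end", {
  gm <- make_competition_model(20)
  sig <- make_signature()

  single <- turbidostat_state(c(aux = 0.5, wt = 0), h = 20)
  sp1 <- sample_culture(single, make_optics(), sig, 100, seed = 1)
  expect_equal(unname(sp1$strains$aux$fraction), 1)

  even <- turbidostat_state(c(aux = 0.25, wt = 0.25), h = 20)
  sp2 <- sample_culture(even, make_optics(), sig, 100, seed = 1)
  expect_equal(unname(sp2$strains$aux$fraction), 0.5)

  # closed loop: classify(generate(sample)) recovers fractions within 2%
  mixed <- turbidostat_state(c(aux = 0.35, wt = 0.15), h = 20)
  sp3 <- sample_culture(mixed, make_optics(), sig, 10000, seed = 0)
  pr <- process_events(generate_events(sp3)$events, sig, make_reference(),
                       rules = make_genotype_rules())
  expect_lt(abs(pr$fractions[["aux"]] - 0.7), 0.02)

  expect_error(sample_culture(single, make_optics(), sig, 0), "> 0")
  sterile <- turbidostat_state(c(aux = 0, wt = 0), h = 20)
  expect_error(sample_culture(sterile, make_optics(), sig, 10), "sterile")
})

test_that("plate dilution arithmetic conserves volume and solutes", {
  # worked example: 1 h of evaporation at 10 uL/h from 200 uL, OD 0.12
  p <- plate_state("A1", volume_ul = 200, od = 0.12 * 190 / 200)
  p <- plate_evaporate(p, 1)                 # -> 190 uL, OD concentrates
  expect_equal(p$volume_ul, 190)
  expect_equal(p$od, 0.12)

  res <- plate_dilution_protocol(p, threshold = 0.1)
  expect_equal(res$action, "dilute")
  # +100 uL dilutes OD by 190/290; removing mixed culture leaves OD alone
  expect_equal(res$plate$od, 0.12 * 190 / 290)
  expect_equal(res$plate$volume_ul, 200)     # estimate matches truth: nominal

  # below threshold, recently diluted: nothing happens
  calm <- plate_state("A1", od = 0.01)
  expect_equal(plate_dilution_protocol(calm, 0.05)$action, "none")

  # 10 h without dilution forces a feed with no removal
  dry <- plate_evaporate(plate_state("A1", od = 0.01), 10)
  fed <- plate_dilution_protocol(dry, threshold = 0.5)
  expect_equal(fed$action, "force-feed")
  expect_equal(fed$plate$volume_ul, 100 + 100 * 1)

  # evaporation estimate >= added volume clamps removal and warns
  parched <- plate_evaporate(plate_state("A1", od = 0.2), 11)
  res2 <- plate_dilution_protocol(parched, threshold = 0.1)
  expect_match(res2$warnings, "clamped")
})

test_that("volume is periodic when the evaporation estimate is right, drifts when wrong", {
  sim_cycles <- function(est) {
    p <- plate_state("A1", od = 1)
    vols <- numeric(6)
    for (i in 1:6) {
      p <- plate_evaporate(p, 2)
      p <- plate_dilution_protocol(p, threshold = 0.1,
                                   evap_estimate_ul_h = est)$plate
      vols[i] <- p$volume_ul
    }
    vols
  }
  expect_equal(sim_cycles(10), rep(200, 6))          # exact return to nominal
  drift <- sim_cycles(7)                             # underestimate: -6 uL/cycle
  expect_equal(diff(drift), rep(-6, 5))
})

test_that("antibiotic treatment mixes by conservation and commutes", {
  p <- plate_state(c("A1", "B1"), od = 0.1)
  # media-only: drug stays zero, cells dilute by the volume ratio
  p1 <- treat_well(p, "A1", dose = 0)
  expect_equal(p1$antibiotic[1], 0)
  expect_equal(p1$od[1], 0.1 * 200 / 250)

  # dose for a 16 mg/L final concentration in 250 uL: 80 mg/L in the 50 uL
  p2 <- treat_well(p, "A1", dose = 80)
  expect_equal(p2$antibiotic[1], 16)

  # sequential additions commute
  pa <- treat_well(treat_well(p, "A1", 80), "A1", 20)
  pb <- treat_well(treat_well(p, "A1", 20), "A1", 80)
  expect_equal(pa$antibiotic[1], pb$antibiotic[1])

  expect_error(treat_well(p, "Z9", 10), "unknown well")
})

test_that("OD series cleaning removes only early aberrant points", {
  t <- seq(0, 5, 0.5)
  blank <- rep(1e-3, length(t))
  od <- blank
  expect_true(all(clean_od(t, od, blank)$od == 0))

  # three early spikes above 3e-3 are removed; a late one is retained
  od2 <- blank + 1e-4
  od2[c(1, 2, 4)] <- 5e-3       # t = 0, 0.5, 1.5 h
  od2[7] <- 5e-3                # t = 3 h: outside the artifact window
  cl <- clean_od(t, od2, blank)
  expect_equal(attr(cl, "removed"), 3L)
  expect_true(3 %in% cl$t)
  expect_equal(nrow(cl), length(t) - 3L)

  expect_error(clean_od(1:3, 1:3, 1:2), "aligned")
})
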