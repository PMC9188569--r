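# Cytometry module: generation, gating, deconvolution, RPU, classification.

test_that("event tables enforce their shape invariants and round-trip files", {
  ev <- event_table(c(900, 1100), c(400, 520),
                    list(`GRN-B` = c(10, 20), `ORG-G` = c(5, 8)))
  expect_equal(n_events(ev), 2L)
  expect_equal(channel_names(ev), c("GRN-B", "ORG-G"))
  expect_error(event_table(1:3, 1:2), "same length")
  expect_error(event_table(1, 1, list(a = 1, a = 2)), "unique")
  expect_error(event_table(1:2, 1:2, list(a = 1:3)), "length n_events")

  f <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, f)
  expect_equal(as.data.frame(read_events(f)), as.data.frame(ev))

  sig <- make_signature()
  fs <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, fs)
  sig2 <- read_signature(fs)
  expect_equal(sig2$S, sig$S)
  expect_equal(unname(sig2$a), unname(sig$a))
})

test_that("generator honors the empty, identity-mixing and mixture-ratio contracts", {
  # empty acquisition
  g0 <- generate_events(make_single_strain_spec(0))
  expect_equal(n_events(g0$events), 0L)
  expect_length(g0$labels, 0L)

  # identity signature, zero noise: channels equal the drawn amounts
  spec <- population_spec(
    strains = list(wt = list(fraction = 1, meanlog = c(f1 = 5),
                             sdlog = c(f1 = 0.2))),
    signature = make_identity_signature(), n_events = 50, noise_sd = 0,
    seed = 3)
  g <- generate_events(spec)
  expect_equal(unname(channel_matrix(g$events)[, "c1"]),
               unname(g$amounts[, "f1"]))
  expect_equal(unname(channel_matrix(g$events)[, "c2"]), rep(0, 50))

  # 5:1 competition-style inoculum: label counts inside the binomial 99% CI
  n <- 12000
  g2 <- generate_events(make_two_strain_spec(n, frac_aux = 5 / 6, seed = 0))
  ci <- qbinom(c(0.005, 0.995), n, 5 / 6)   # oracle: exact binomial quantiles
  expect_gte(sum(g2$labels == "aux"), ci[1])
  expect_lte(sum(g2$labels == "aux"), ci[2])

  expect_error(generate_events(make_single_strain_spec(-5)), "non-negative")
  expect_error(population_spec(
    strains = list(a = list(fraction = 0.7), b = list(fraction = 0.7)),
    signature = make_signature(), n_events = 10), "sum to 1")
})

test_that("gating keeps tight singlet populations and removes planted contamination", {
  expect_length(gate(generate_events(make_single_strain_spec(0))$events),
                0L)

  # fewer than 3 events: all-true mask plus warning record, not an error
  tiny <- generate_events(make_single_strain_spec(2, seed = 1))
  m_tiny <- gate(tiny$events)
  expect_true(all(m_tiny))
  expect_match(attr(m_tiny, "warning"), "fewer than 3")

  # clean population at the default 0.5 / 0.5 thresholds
  g <- generate_events(make_single_strain_spec(5000, seed = 0))
  m <- gate(g$events)
  expect_gte(mean(m), 0.99)

  # idempotence: re-gating removes < 1% more
  kept <- g$events[as.logical(m), , drop = FALSE]
  class(kept) <- c("event_table", "data.frame")
  expect_lt(1 - mean(gate(kept)), 0.01)

  # 5% debris at 0.05x FSC mode + 5% doublets: removal recall/precision >= 0.95
  gc <- generate_events(make_single_strain_spec(
    10000, seed = 0, doublet_fraction = 0.05, debris_fraction = 0.05))
  mc <- gate(gc$events)
  bad <- gc$labels %in% c("doublet", "debris")
  removed <- !mc
  expect_gte(sum(removed & bad) / sum(bad), 0.95)       # recall
  expect_gte(sum(removed & bad) / sum(removed), 0.95)   # precision
})

test_that("deconvolution solves the per-event least-squares problem exactly", {
  # identity signature, no background: output equals input channels
  idsig <- make_identity_signature()
  ev <- event_table(c(1000, 900), c(400, 300),
                    list(c1 = c(7, 2), c2 = c(1, 5)))
  d <- deconvolve(ev, idsig)
  expect_equal(unname(d$amounts), unname(channel_matrix(ev)))
  expect_equal(d$residual_norm, c(0, 0))

  # channels exactly at autofluorescence: zero amounts
  sig <- make_signature()
  ev0 <- event_table(1000, 400, list(`GRN-B` = 5, `BLU-V` = 5))
  expect_equal(unname(deconvolve(ev0, sig)$amounts[1, ]), c(0, 0))

  # 3 channels x 2 fluorophores with 30% cross-talk: exact recovery
  S <- matrix(c(1, 0.3, 0.05, 0.3, 1, 0.2), 3, 2,
              dimnames = list(c("ch1", "ch2", "ch3"), c("fA", "fB")))
  sig3 <- spectral_signature(S, c(2, 3, 1))
  x <- matrix(c(4, 9), 1)
  y <- as.numeric(S %*% t(x)) + sig3$a
  ev3 <- event_table(1, 1, as.list(setNames(y, rownames(S))))
  d3 <- deconvolve(ev3, sig3)
  expect_lt(max(abs(d3$amounts[1, ] - x) / x), 1e-9)

  # rank-deficient signature names the collinear pair
  Sbad <- matrix(c(1, 2, 2, 4), 2, 2,
                 dimnames = list(c("a", "b"), c("fX", "fY")))
  expect_error(spectral_signature(Sbad), "fX.*fY|collinear")
})

test_that("deconvolution matches the normal-equations oracle on random instances", {
  set.seed(42)
  for (rep in 1:20) {
    nf <- sample(2:4, 1)
    nc <- sample(nf:6, 1)
    repeat {
      S <- matrix(runif(nc * nf, 0, 2), nc, nf,
                  dimnames = list(paste0("ch", 1:nc), paste0("f", 1:nf)))
      if (qr(S)$rank == nf && kappa(S) < 1e4) break
    }
    a <- runif(nc, 0, 3)
    sig <- spectral_signature(S, a)
    n <- 25
    Y <- matrix(rnorm(n * nc, 10, 4), n, nc)
    ev <- event_table(rep(1000, n), rep(400, n),
                      as.data.frame(setNames(as.data.frame(Y), rownames(S))))
    d <- deconvolve(ev, sig)
    # oracle: explicit normal equations, one event at a time
    oracle <- t(apply(sweep(Y, 2, a), 1,
                      function(b) solve(crossprod(S), crossprod(S, b))))
    expect_lt(max(abs(d$amounts - oracle) / pmax(abs(oracle), 1e-6)), 1e-9)
  }
})

test_that("RPU normalization has unit reference median and scale equivariance", {
  set.seed(7)
  n <- 4001
  fsc <- rlnorm(n, log(1000), 0.25)
  amounts <- cbind(mNeonGreen = fsc * rlnorm(n, 0, 0.2))
  ref <- estimate_rpu_reference(amounts, fsc)
  r <- to_rpu(amounts, fsc, ref)
  expect_equal(median(r[, "mNeonGreen"]), 1)

  # an event at exactly twice the reference median is 2 RPU
  ev2 <- to_rpu(cbind(mNeonGreen = 2 * ref$medians[["mNeonGreen"]] * 500),
                500, ref)
  expect_equal(unname(ev2[1, 1]), 2)

  # scale equivariance
  ref10 <- rpu_reference(ref$medians * 10)
  r10 <- to_rpu(amounts * 10, fsc, ref10)
  expect_equal(unname(r10), unname(r))

  # non-positive FSC flagged and excluded
  rr <- to_rpu(amounts[1:5, , drop = FALSE], c(100, -1, 0, 50, 20), ref)
  expect_equal(attr(rr, "excluded"), 2L)
  expect_equal(nrow(rr), 3L)

  # autofluorescence-only strain: |median RPU| < 0.05 after deconvolution
  sp <- population_spec(
    strains = list(autofl = list(fraction = 1, meanlog = NULL, sdlog = NULL)),
    signature = make_signature(), n_events = 4000, seed = 0)
  g <- generate_events(sp)
  d <- deconvolve(g$events, make_signature())
  r0 <- to_rpu(d$amounts, g$events$fsc, make_reference())
  expect_lt(max(abs(apply(r0, 2, median))), 0.05)
})

test_that("classification assigns every event one label with fractions summing to 1", {
  rules <- make_genotype_rules()
  # all events at 1.5 mCerulean RPU with threshold 1: all wild-type
  rp <- cbind(mCerulean = rep(1.5, 10), mNeonGreen = rep(0.01, 10))
  cl <- classify(rp, rules)
  expect_true(all(cl$labels == "wt"))
  expect_equal(sum(cl$fractions), 1)

  # with an explicit below-threshold label, all-dim events are all mutant
  rules_mut <- genotype_rules(data.frame(
    label = c("wt", "mutant"), fluorophore = "mCerulean",
    dir = c(">=", "<"), threshold = 1))
  rp0 <- cbind(mCerulean = rep(0.1, 5), mNeonGreen = rep(0.1, 5))
  expect_equal(unname(classify(rp0, rules_mut)$fractions[["mutant"]]), 1)
  # without one, they fall in the explicit unassigned bucket
  expect_equal(unname(classify(rp0, rules)$fractions[["unassigned"]]), 1)

  # permutation invariance
  set.seed(1)
  rp2 <- cbind(mCerulean = runif(200, 0, 2), mNeonGreen = runif(200, 0, 2))
  f1 <- classify(rp2, rules)$fractions
  f2 <- classify(rp2[sample(200), ], rules)$fractions
  expect_equal(f1, f2)

  expect_error(classify(cbind(other = 1), rules), "missing")
})

test_that("the full pipeline recovers planted strain fractions", {
  sig <- make_signature()
  ref <- make_reference()
  rules <- make_genotype_rules()

  # 5:1 mixture, well-separated: fractions within 1% of truth
  g <- generate_events(make_two_strain_spec(10000, frac_aux = 5 / 6, seed = 0))
  pr <- process_events(g$events, sig, ref, rules = rules)
  truth <- mean(g$labels == "aux")
  expect_lt(abs(pr$fractions[["aux"]] - truth), 0.01)

  # end-to-end with contamination: within 2% of the generator fractions
  gc <- generate_events(make_two_strain_spec(
    10000, frac_aux = 0.7, seed = 0, doublet_fraction = 0.03,
    debris_fraction = 0.03))
  pc <- process_events(gc$events, sig, ref, rules = rules)
  expect_lt(abs(pc$fractions[["aux"]] - 0.7), 0.02)
  expect_lt(abs(pc$fractions[["wt"]] - 0.3), 0.02)
})
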