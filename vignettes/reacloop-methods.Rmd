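---
title: "reacloop: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{reacloop: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reacloop)
```

reacloop is a hardware-free re-implementation of the computational core of a
reactive bioreactor-automation platform: on-the-fly flow-cytometry
processing, a small ODE model of light-inducible gene expression driving a
receding-horizon controller, optical-density-mediated steering of a
two-strain yeast consortium, competition-assay fitness inference, and an
event-driven orchestrator closed over simulated instruments. This vignette
explains the models, the tunable parameters and their defaults, the design
decisions taken where the underlying procedures were open, and what the
simulators do and do not capture about real experiments.

## Cytometry processing

A sample is an *event table*: per-event forward scatter (FSC), side scatter
(SSC) and named fluorescence channels, all in instrument arbitrary units.
Processing runs gate → deconvolve → normalize → classify.

### Gating

Two parameters, both defaulting to 0.5, control the gate.

* **Size gate.** A kernel density estimate of log-FSC is computed with a
  deliberately wide bandwidth — 2.5 × the MAD of log-FSC — and events whose
  density value falls below `size_threshold` × the mode are discarded. The
  wide bandwidth is the load-bearing choice: with a data-driven bandwidth a
  *homogeneous* population would lose its own tails (a half-maximum cut on a
  Gaussian keeps only ~76%), whereas with the wide kernel a tight population
  is kept essentially entirely (≥ 99% in the test suite) while debris modes
  sitting far below the cell mode (the generator places them at 0.05 × the
  FSC mode) fall well under half-max and are removed.
* **Doublet gate.** A robust line (`MASS::rlm`) of log-SSC on log-FSC is
  fitted; orthogonal residuals are standardized by their MAD; events below
  `-qnorm(1 - doublet_threshold / 200)` (z ≈ −2.81 at the default) are
  removed. The cut is one-sided because coincident doublets — event-wise
  sums of two cells — fall *below* the singlet line whenever SSC grows
  super-linearly with FSC. Under this rule the gate is idempotent and
  removes well under 1% of a clean sample, while recovering planted
  doublets with ≥ 95% recall and precision.

Both rules are reconstructions of a gating procedure whose published
description names only the two thresholds; they were chosen to be monotone
in those thresholds and testable against the generator's ground truth.

### Spectral deconvolution

Each event's channel vector is modeled as `y = S x + a`, with `S` the
channels × fluorophores signature matrix measured once from single-color
control strains and `a` the autofluorescence background (a fixed per-channel
vector, the median of an autofluorescence-only control — not a per-event
estimate). `deconvolve()` solves the per-event ordinary least-squares
problem by QR; with full column rank the solution is unique and equals the
normal-equations solution to 1e-9 relative (property-tested against that
explicit oracle). Estimates are deliberately *unconstrained*: dim events
scatter to small negative amounts, and clipping them before median
summaries would bias population statistics upward. A non-negative
active-set variant is available behind `nonneg = TRUE` for applications
that need physical amounts per event.

### RPU normalization and classification

Amounts are divided by FSC (a cell-size proxy) and then by the median
FSC-normalized signal of a single-color control strain driven by the strong
constitutive pTDH3 promoter. The reference therefore sits at exactly
1 relative promoter unit (RPU) by construction, and the unit is stable
across sessions and instruments. Medians, not means, are used throughout:
cytometry distributions are heavy-tailed and the downstream controller
consumes median levels.

Genotype classification is rule-based: each label is a conjunction of RPU
thresholds (the competition assays call the constitutively
mCerulean-marked wild type at ≥ 1 mCerulean RPU), labels are tried in
order, and anything matching no rule is `"unassigned"`, which keeps label
fractions exhaustive and summing to one.

### The synthetic event generator

`population_spec()` / `generate_events()` stand in for the cytometer. They
emulate: per-strain log-normal expression mixed through the true signature,
log-normal FSC, an SSC power law, multiplicative measurement noise,
coincident doublets (event-wise sums) and low-FSC debris, with ground-truth
labels. The SSC exponent defaults to 1.8: with a proportional SSC–FSC
relation doublets would sit exactly on the singlet line and *no* scatter
gate could find them, so super-linearity is what makes the doublet gate
testable (real cell doublets are likewise off-line). The generator does
not emulate spillover spreading error, autofluorescence heterogeneity,
detector saturation, or acquisition-time drift — so passing tests show the
pipeline recovers what the model family can express, not that it is robust
to every instrument artifact.

## The light-driven expression model

Two variables, three free parameters:

$$\frac{dm}{dt} = \sigma L(t) - \gamma_m m, \qquad
  \frac{dFP}{dt} = k_m m - \gamma_{FP} FP,$$

with `L(t) ∈ {0,1}` the blue-light state. mRNA units are arbitrary — only
`k_m · m` is observable from protein medians — so `k_m` is tied to
`γ_m`, exactly the identifiability convention of the reference
characterization, whose fitted values are the package defaults:
`γ_m = 2.09 h⁻¹` (mRNA half-life ≈ 20 min), `σ = 0.64 RPU h⁻¹`,
`γ_FP = 0.475 h⁻¹` (protein half-life 1.46 h, mostly dilution).

Light programs are duty-cycled: 30-min cycles, ON for `u_k × 30 min` at the
start of each cycle (the within-cycle placement is not specified by the
procedure being modeled; ON-first was chosen and matters little because the
cycle period is comparable to `1/γ_m`, so the cycle-integrated response
dominates). Simulation is *exact*: the linear ODE is integrated in closed
form on every constant-light segment, with the degenerate `γ_m = γ_FP`
branch handled analytically; a fine-step RK4 integrator serves as the
independent oracle in the tests.

### Fitting

`fit_expression()` minimizes the summed squared FP residual over
`(γ_m, σ, γ_FP)` with L-BFGS-B inside bounds (`γ ∈ [10⁻³, 20] h⁻¹`,
`σ ∈ [10⁻⁴, 20] RPU h⁻¹`) from 20 seeded log-uniform starts plus the bound
vectors. Two subtleties surfaced during development and are part of the
contract:

* **Pole exchange.** With `k_m = γ_m` and a zero initial state the FP
  response determines only the pole pair and the gain: `(g₁, s, g₂)` and
  `(g₂, s·g₁/g₂, g₁)` fit identically. The fit is reported in the
  canonical orientation `γ_m ≥ γ_FP` — the regime the circuit operates in
  (mRNA turns over faster than the protein dilutes).
* **Flat directions.** When the data cannot constrain a parameter (all-dark
  data say nothing about `σ`), ties are broken toward the smallest `σ`,
  the flat direction settles on its bound, and `identifiable = FALSE` is
  reported.

Under 5% multiplicative noise, parameter recovery to better than 10%
median relative error requires frequency-diverse characterization inputs
(step, slow square wave, half-duty chopping, sparse pulses); a single step
response leaves the two decay rates sliding along a correlated ridge. The
test suite uses exactly such a four-program design.

### State estimation

Measurements arrive 10–15 min after sampling. `estimate_state()` sets FP to
the measured median, takes mRNA from an open-loop simulation of the entire
light history (initial state: dark steady state), and advances both through
the arrival delay under the light actually applied meanwhile.

## Model-predictive control

### Light → FP

`plan_light()` minimizes the mean squared deviation of the model-predicted
FP from the target, sampled every 6 min over a 5-h horizon of 10 duty
cycles, by bounded gradient-based search from a deterministic start set:
the one-cycle-shifted previous plan (standard receding-horizon warm start),
all-OFF, all-ON, and seeded random starts. Monotonicity of FP in the duty
fractions makes unreachable targets saturate cleanly at the all-ON bound
(flagged, not an error), and on 3-cycle horizons the planner's objective
matches an exhaustive 0.05-step duty-grid search. Re-planning runs hourly;
in closed loop on the noise-free plant all reachable targets are held to
well under 2% relative error within 10 h. If every optimizer start fails,
the previous plan is kept and the failure recorded — the fail-safe contract
of an unattended overnight experiment.

### OD → consortium ratio

The steering map is the steady-state growth-rate difference between the two
strains as a function of the OD setpoint, fitted as a four-parameter
sigmoid `Δµ(OD) = c₀ − c₁/(1 + e^{−(OD−c₂)/c₃})` (auxotroph minus
prototroph, non-increasing in OD). Constant characterization data are a
degenerate sigmoid and short-circuit to `c₁ = 0`. The two-strain ratio
then obeys exact odds dynamics — `d/dt log(r/(1−r)) = Δµ(OD(t))` —
integrated in closed form per constant-OD block; odds space was chosen over
raw count ratios because it is identical for two strains and stable near
the absorbing boundaries 0 and 1. `plan_od()` optimizes five 2-h setpoint
blocks over a 10-h horizon against squared ratio deviation at block ends,
within bounds [0.1, 0.8] (the characterized range). A deliberate model
mismatch (+0.05 h⁻¹ unmodeled recovery of the slow strain) leaves the
documented signature: a persistent measured ratio below target.

## Fitness inference

At culture steady state a two-strain ratio evolves exponentially at the
growth-rate difference, so the log-odds of classified event counts is
linear in time. `detect_steady_window()` operationalizes "linear for at
least three time points" as: the longest suffix window whose least-squares
line has maximum absolute residual below a tolerance (default 0.05
log-odds units; assays that sample thousands of events per time point sit
well inside it). `estimate_fitness_difference()` is the OLS slope over the
window with its standard error; it is exact on noise-free input, unbiased
under multinomial event sampling, and its 1-σ interval covers the true
slope at the nominal ~68% in the package's Monte-Carlo checks.

## The virtual laboratory

### Turbidostat

State: per-strain biomass densities (OD units), vessel histidine (µM),
constant 30 mL volume. The ideal turbidostat law is used — dilution equals
total specific growth while OD is at the setpoint, zero below it — because
the platform being modeled holds OD tightly; pump hysteresis is deliberately
not modeled. Dynamics per strain `i`:

$$\frac{dX_i}{dt} = (\mu_i - D)X_i, \qquad
  \frac{dh}{dt} = D(h_{in} - h) - \textstyle\sum_i q_i \mu_i X_i,$$

sub-stepped so no rate moves the state more than ~0.5% per sub-step, with
histidine clamped at zero.

**Growth law.** Prototrophs grow at a constant `µ_max`. The histidine
auxotroph is limited by uptake through its single high-affinity transporter
(literature Monod constant `K_m = 17 µM`), modeled as

$$\mu_{aux}(h) = \min\!\big(\mu_{max},\ \mu_T\, h/(K_m + h)\big),$$

a transport-limited Monod law with an intrinsic-rate cap. The cap is
essential: a plain growth-Monod `µ_max · h/(K_m+h)` is analytically too
shallow to reproduce the observed regime structure. At the setpoint the
steady residual histidine is exactly `h* = h_in − q·OD` (the dilution rate
cancels when all strains share the yield `q`), so over the explored range
the Monod factor must swing from saturating to near-arrest within
`h* ∈ [4, 20] µM` — a ratio a single hyperbola with `K_m = 17 µM` cannot
deliver once the curve is pinned near saturation at low OD. Separating the
transporter capacity (`µ_T`) from the intrinsic ceiling (`µ_max`) resolves
this with one extra, biologically meaningful parameter.

**Calibration** (fixed once, used by all tests): `µ_max = 0.45 h⁻¹` for
both strains of the competition pair (same genetic background),
`µ_T = 1.25 h⁻¹`, `q = 20 µM` histidine per OD unit of biomass. At a
20 µM feed this yields a wild-type advantage of ~0 up to OD 0.5, 0.05 h⁻¹
at OD 0.6, and 0.21 h⁻¹ at OD 0.8; at a 4 µM feed the auxotroph is
effectively growth-arrested at every setpoint (Δµ ≥ 0.3 h⁻¹) — the
qualitative structure of the characterization the consortium controller
relies on. For consortium-control scenarios the prototroph is the slower
strain (`µ = 0.30 h⁻¹`), placing the Δµ = 0 crossing near OD 0.72, interior
to the setpoint bounds.

What the simulator does not capture: physiological hysteresis of starvation
(stress responses make real arrest slow to reverse), nutrient storage
pools, growth-rate dependence of cell size and fluorescence, and any
antibiotic pharmacodynamics — the plate simulator tracks drug
concentrations by conservation only and leaves growth response pluggable,
because the platform's published account of antibiotic action is
qualitative.

### Plate reader and liquid handling

Wells track volume, blank-subtracted OD, and drug concentration.
Evaporation (default 10 µL/h) removes water only, concentrating solutes;
every pipetting action updates concentrations by conservation of amount.
The maintenance protocol mirrors the robot's: when the median OD exceeds a
threshold, add 100 µL of feed medium, mix, and remove 100 µL minus the
estimated evaporation since the last dilution — so the volume returns
exactly to nominal when the estimate matches the true rate, and drifts
linearly when it does not (a sensitivity the tests document). Ten hours
without dilution triggers a forced 100 µL feed with no removal. OD series
cleaning subtracts the time-aligned blank and removes raw readings above
3×10⁻³ only within the first 2 h of a run — later excursions are data, not
artifacts.

## Orchestration

Instruments are in-process endpoints: named operations over a mutable
state, every invocation answered with a status (`ok`/`error`/
`unavailable`) — the request/response shape of the original networked
architecture without sockets, which keeps the control surface fully
testable; an HTTP adapter would be a thin extension. Events are
condition/action pairs on three schedules: `on-data` (checked every tick),
`periodic` (fire at interval completions, never at t = 0, ties broken by
registration order), and `one-shot`. Every instrument invocation and event
firing appends exactly one record to an append-only log (JSON lines,
doubles serialized with 17 significant digits so they round-trip exactly);
re-executing the logged invocation sequence against freshly initialized
instruments reproduces the final state bit-for-bit. An action error aborts
only its own chain, is logged, and the loop continues — an unattended run
must degrade, not die. The full closed-loop light-control experiment is
expressed purely as one periodic MPC event over a reactor endpoint
(`run_light_control()`), and the acceptance suite replays it from its log.

## Numerical choices and problem sizes

* All bounded searches use L-BFGS-B with seeded multi-starts; planners run
  with a relaxed convergence factor (1e7) since their objectives are flat
  near the optimum, fits with a tight one (1e4).
* Seeded internals save and restore the caller's RNG stream, so package
  calls never perturb user-level reproducibility.
* The test suite's simulation sizes — 10⁴-event acquisitions, 10-h closed
  loops, 200-replicate Monte-Carlo batches, 0.05-step exhaustive duty
  grids on 3-cycle horizons — were chosen as the smallest designs in which
  the tested properties are statistically unambiguous.
* Degenerate inputs have defined behavior rather than errors where an
  unattended loop could plausibly produce them: < 3 events (gate returns
  all-true with a warning record), negative measurements (clipped, warned),
  unreachable targets (saturate, flagged), optimizer failure (previous plan
  kept), ratios at 0/1 (absorbing).

## Limitations

The package validates methods against its own generative models; agreement
there bounds software correctness, not biological fidelity. Real cytometry
violates the generator's noise model in instrument-specific ways; real
gene-expression dynamics show cell-to-cell variability the median-level
model ignores; the nutrient simulator's sharp regime transition stands in
for physiology (transport saturation plus stress) that it does not
mechanistically resolve. Quantities that depend on those unmodeled layers —
e.g. the exact fitted growth-rate differences of a particular wet
experiment — are outside what a desk reproduction can promise.
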