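---
title: "Modeling progressive retinal ganglion cell dysfunction and death"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling progressive retinal ganglion cell dysfunction and death}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgcprog)
```

## The model

In glaucoma and other optic neuropathies, retinal ganglion cells (RGCs) do
not jump from healthy to dead: they pass through a dysfunctional but viable
stage during which electrophysiological function (measured by the pattern
electroretinogram, PERG) is reduced while retinal structure (OCT
inner-retina thickness, optic-nerve axon counts) still looks normal. That
sick stage is the window in which neuroprotective treatment can still
rescue cells. `rgcprog` turns this narrative into a quantitative,
fittable model.

A cohort of `H0` healthy cells decays with per-time-unit fraction `b` into a
sick state; a sick cell functions at a fraction `d` of normal capacity and
survives exactly `tau` time units before dying:

- healthy: `H(t) = H0 (1-b)^t`
- sick: `S(t) = H0 [1 - (1-b)^t]` for `t <= tau`, then
  `H0 [1 - (1-b)^tau] (1-b)^(t-tau)`
- dead: `D(t) = 0` for `t <= tau`, then `D(t) = H0 [1 - (1-b)^(t-tau)]`

The dead-compartment expression is the unique form consistent with
conservation `H + S + D = H0` given the other two; the package enforces that
identity to numerical precision, and supports real-valued `t` and `tau` by
evaluating `(1-b)^x` as `exp(x log(1-b))` (`b = 1` is excluded as a
degenerate instant collapse). What measurements see are two derived indices:
function `F(t) = H(t) + d S(t)` and surviving population
`P(t) = H(t) + S(t)`. Since `d < 1` delays nothing but discounts sick cells,
`F` decays ahead of `P`: the structure–function dissociation.

```{r}
p <- example_params()   # H0 = 100, b = 0.3, tau = 2, d = 0.5
trajectory(p, 0:4)
```

Two biomarkers summarize the dissociation. The **horizontal window**
`horizontal_window()` is the time by which function reaches a fractional
loss before structure does; in deep loss it converges to
`log(d + (1-d)(1-b)^tau) / log(1-b)`, an estimate of the sick-cell lifespan
and hence of the treatment window. The **vertical gap** `vertical_gap()`,
`[P(t) - F(t)]/H0 = (1-d) S(t)/H0`, is the function deficit not explained by
death — the recoverable part; it peaks exactly at `t = tau`.

## The stochastic simulator

`three_state_scheme()` re-expresses the closed forms as a discrete-time
state-transition structure: healthy cells become sick with per-step
probability `1 - (1-b)^step`, and the fixed lag is a chain of
`tau/step` unit-residence substates, so a cell entering the sick chain dies
exactly `tau` later. Expected-value propagation (`simulate_expected()`)
reproduces the closed forms exactly at step times — the package tests
exploit this as a two-route consistency check. `simulate_stochastic()`
replaces expectations by multinomial draws (one seeded generator per call),
and `simulate_cells()` logs per-cell stage-entry times, which is how the
residence-time property is verified rather than assumed.

Two generalizations are deliberate:

- a **geometric residence** option (`residence = "geometric"`, mean `tau`)
  for sensitivity analysis — the default is the deterministic lag because
  that is what the closed-form model implies;
- a **seven-stage chain** (`seven_stage_scheme()`: Healthy, At Risk, Sick,
  Very sick, Dying, Dead, Effaced) with per-stage function coefficients and
  structure-visibility flags. The staged scheme's default probabilities and
  coefficients are illustrative configuration values only — no published
  estimates exist for them — and the constructor enforces only the
  qualitative shape: coefficients non-increasing, healthy at 1, dead and
  effaced at 0 (function at floor), structure loss visible from the dying
  stage onward. How a partially abnormal early stage maps to a coefficient
  is left to configuration.

## The observation model

`observe_function()` maps `F(t)` to a PERG-like series as
`max(floor, scale * F(t)) + noise`, clipped at the floor;
`observe_structure()` maps `P(t)` to `offset + scale * P(t) + noise`,
clipped at the offset. Defaults state the emulated world:

- **floor = 10% of the baseline signal** (`noise_floor_fraction = 0.1`).
  PERG has a signal-to-noise ratio of about one log unit, so a fully
  abolished response still measures ~10% of baseline (the noise level).
- **additive Gaussian noise**, chosen for fittability; no noise distribution
  is established for these measurements, and a multiplicative log-normal
  option is available by flag.
- **structure offset 0** — appropriate for axon counts; a positive offset
  models non-RGC contributions to OCT thickness.
- `generate_dataset()` defaults to monthly samples over months 2–12 with the
  DBA/2J natural-history parameters (`b = 0.3`, `tau = 6.5` months,
  `d = 0.5`), emulating the age range over which mouse PERG and axon-count
  series are measured, and records the generating truth in metadata so
  recovery can be tested.

What the generator does **not** emulate: between-animal parameter
heterogeneity, local (sectoral) loss, latency changes (no generative
equations exist for PERG latency), and age-dependent factors unrelated to
the disease process. A green recovery test therefore establishes that the
estimator inverts the stated observation model — not that real mouse data
satisfy it.

## Fitting

`fit_decay()` averages replicates, normalizes each measure to its earliest
retained value (fixing `H0 = 100` and removing the measurement scale, which
is otherwise confounded with `d`), and minimizes the unweighted summed
squared residuals of both normalized series jointly over `(b, tau, d)`.
Numerical choices:

- **Multistart**: `tau` enters the loss piecewise, so the surface can be
  multimodal; a coarse grid over the bounded box is scanned, the best cells
  are refined with L-BFGS-B, ties break by lower loss then lower `b`, and a
  derivative-free polish settles the winner (L-BFGS-B line searches can
  fail spuriously once the loss reaches machine precision).
- **Floor censoring** (default): clipping at the floor biases group means
  upward well before the mean itself reaches the floor, so function points
  are censored once their mean is within two observation SDs of the floor
  (SD estimated from replicate scatter; with a single replicate, points at
  or below the floor are dropped). Floored measurements no longer track
  progression, so discarding them loses little information. The
  alternative `floor_handling = "fit"` keeps them and floors the model
  prediction instead.
- **Raw-scale fitting** (`normalize = FALSE`) profiles per-measure scale
  factors out analytically instead of normalizing.
- Flat series fit cleanly to `b = 0` with a diagnostic that `tau` and `d`
  are then unidentifiable, rather than erroring.

`bootstrap_ci()` returns expanded percentile intervals (quantile levels
widened by the usual small-sample `t`-correction, since plain percentile
intervals are systematically narrow at modest resampling-unit counts) from
a seeded bootstrap. When
the dataset carries replicate structure (at least 8 replicate animals), a
**case bootstrap at the replicate level** is used: whole paired
function/structure replicate series are resampled with replacement. This
choice was forced by a calibration study: after baseline normalization,
baseline measurement noise lies along directions the parameters absorb, so
it perturbs the estimates (especially `b`) while leaving almost no trace in
the residuals — classical residual resampling is then structurally blind to
that variance and its `b` intervals undercover. Resampling animals captures
every noise pathway, including baseline error, heteroscedasticity and floor
clipping. For datasets without replicates, residual resampling is retained,
with leverage rescaling (`r_i / sqrt(1 - h_ii)` from the model Jacobian),
exclusion of the structurally-zero baseline residual, and renormalization
of each bootstrap series at its own baseline.

## The dynamics layer

PERG response dynamics — how the response changes with stimulus contrast,
sustained stimulation, stressors and treatment — distinguish phenotypes and
probe surviving cells. These constructs are defined verbally in the
literature; the formulas here are this package's operationalization:

- `contrast_gain()`: least-squares slope of amplitude (or latency) against
  log10 contrast over a chosen range;
- `detect_dip()`: strictly interior local minima of the contrast transfer
  function (descriptive only — generator interactions are not modeled);
- `adaptation_index()`: `(initial - steady)/initial`, clipped to [0, 1];
- `susceptibility_index()`: fractional drop under a stressor plus a
  reversibility flag (recovery within a fractional tolerance of baseline);
- `classify_intervention()`: a pattern call (enhancement / restoration /
  susceptibility / resilience / no_effect) requiring both a material
  relative change (default 10%) and a Welch-test-significant one (default
  alpha 0.05) — improvement should be both real and big enough to matter.
  In the stressor context the `control` pair is read as the reference
  (e.g. pre-treatment) stressor response and the `disease` pair as the test
  condition, so "resilience" means the test condition's drop is materially
  reduced relative to the reference.

Constructs with no operational definition in the source literature
(protection, rescue, plasticity) are intentionally not implemented.

## Design choices that were genuinely open

- **Dead-compartment form**: the conservation-consistent
  `D(t) = H0 [1-(1-b)^(t-tau)]` is adopted; any other reading breaks
  `H + S + D = H0`.
- **Lag generalization**: the sick-compartment exponent is `tau`, not the
  worked example's hard-coded 2, so non-integer lags (6.5 months) are
  expressible.
- **"Decay rate" reading**: `b` is the per-time-unit *fraction* of healthy
  cells converting (30% in the worked example), not an instantaneous
  exponential rate; the worked example's printed values force this reading.
- **Window read-out level**: at which loss fraction the horizontal distance
  is read is not standardized; both a user-chosen level and the deep-loss
  asymptote are exposed, the asymptote being the default because it is
  level-free.
- **Config dialect**: the CLI accepts JSON configuration (flags override
  file values); every CSV output carries a JSON sidecar sufficient to
  regenerate it, and all stochastic paths are reproducible from the logged
  seed.

## Known limitations

- PERG is a global metric; the model has no spatial/sectoral structure.
- The seven-stage scheme's quantitative defaults are illustrative; only its
  qualitative ordering constraints are scientifically grounded.
- Latency is handled descriptively (slopes), never generatively.
- Between-eye and between-animal correlation structures are not modeled;
  replicates are treated as independent.
- Bootstrap intervals are percentile intervals; with few replicates or very
  short series they can undercover somewhat, as percentile intervals
  generally do at small n, and the replicate-free residual scheme does not
  capture baseline-normalization error.
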