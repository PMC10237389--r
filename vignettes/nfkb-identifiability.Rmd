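---
title: "Methods: a reduced NF-κB pathway model and its identifiability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a reduced NF-κB pathway model and its identifiability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfkbid)
```

## The model and its assumptions

The package implements a six-variable, non-dimensional ODE model of the
canonical NF-κB pathway driven by a binary TNF input. The variables are
the neutral and active IKK fractions (`IKKn`, `IKKa`), free nuclear NF-κB
(`NFkBn`), the A20 protein, free cytoplasmic IκBα protein and the IκBα
transcript. Two assumptions shape the equations:

* **Conservation of NF-κB.** Total NF-κB is constant and scaled to 1, so
  the cytoplasmic (NF-κB|IκBα) complex pool is `1 − NFkBn` and needs no
  equation of its own. Total IκBα protein, the experimentally accessible
  quantity, is `IkBa + 1 − NFkBn`.
* **Fast binding relative to trafficking.** IκBα binds NF-κB much faster
  than either protein shuttles between compartments. The IKKa-driven
  degradation of IκBα inside complexes releases NF-κB, and the released
  NF-κB is partitioned by the Michaelis-type factor `δ/(IkBa + δ)` between
  successful nuclear entry and recapture by free IκBα; the complementary
  factor `IkBa/(IkBa + δ)` consumes free IκBα. The second constant, ε,
  plays the analogous role for the removal of nuclear NF-κB by imported
  IκBα. Both δ and ε are dimensionless and well below 1.

Two negative feedbacks arise: IκBα (via its transcript, which supplies the
delay needed for oscillations) and A20, which inactivates IKKa and thereby
protects IκBα. Two parameter presets are provided: `"prefitted"` (the
values produced directly by reducing a detailed mass-action model) and
`"fitted"` (the values after refitting the reduced model to the detailed
one); `nfkb_params()` documents all 13 rate constants. Rate constants are
in s⁻¹, while protocols and schedules are stated in minutes and response
horizons in hours; conversions (×60, ×3600) happen at the interfaces, so
integration is always in seconds.

The A20 knockout genotype is realized by zeroing the A20 *synthesis* term,
so `A20 ≡ 0` from the resting state. For every variable except A20 itself
this is equivalent to removing the A20 feedback (`k2 = 0`), and it mirrors
the biology of a knocked-out protein; A20 is excluded from knockout
measurement schedules.

## Stimulation protocols and bookkeeping

A protocol is a piecewise-constant TNF profile (contiguous on/off segments
in minutes) plus per-genotype measurement schedules for the five
observables. The built-in `make_on_off()` protocol applies 2 h of TNF
followed by a 10 h washout with sparse schedules: 50 measurements in 9
series. The rationale for this design is that the stimulation phase drives
every variable except IKKn up, and the washout lets them relax, so both
forward and backward rates leave a signature in the data. Tonic and
pulsatile stimulus shapes are provided by `make_tonic()` and
`make_pulsatile()`; multi-protocol experiments are assembled from YAML or
JSON files (`read_protocol()`, a transcription template ships in
`inst/extdata/`).

A series of *n* measurements normalized by its geometric mean carries only
*n − 1* independent numbers, so an experiment's effective dimension is
`dim = N − n_series`. Every scaled quantity in the identifiability module
divides by `sqrt(dim)`, which makes repeating an experiment a no-op for
the scaled spectrum — the property that lets protocols of very different
sizes be compared fairly.

## Measurement model: normalization and noise

Measured time series are assumed to be in arbitrary units with
multiplicative errors. Each simulated series is therefore normalized in
two steps: a shift `x + ρ·max(x)` with `ρ = 0.03`, because values below a
few percent of a series' maximum are dominated by background in real
assays (and because series that start at the resting state contain exact
zeros); then division by the geometric mean. Normalization is
scale-invariant, so the arbitrary unit cancels.

Measurement noise is multiplicative lognormal: each raw value is replaced
by a draw with median equal to the clean value and geometric SD
`sigma_data ≥ 1` (`sigma_data = 1` is a no-op). Noise is applied to raw
values *before* the ρ-shift and normalization, exactly as an experimenter
would normalize whatever values the instrument produced; consequently the
ρ-shift uses the noisy series' maximum. Every noisy draw is seeded, and
Monte Carlo replicate *r* at noise level *l* uses the recorded seed
`base_seed + 1000(l−1) + r`. Measurement-set row order is fixed by a
locale-independent radix sort so that seeded draws map to measurements
identically on every system.

What the generator emulates is a *population-average* (bulk) measurement
of five observables with multiplicative error. It does not emulate
single-cell stochasticity, cell-to-cell parameter variability, background
subtraction artifacts, or correlated errors within a blot or time course —
so tests passing on these synthetic data certify the machinery and the
average-dynamics model, not robustness to those real-data complications.

## Fitting

Fitting minimizes the log-least-squares objective
`J = Σ (ln y_model − ln y_ref)²` over all matched measurements of
normalized sets; the companion summary `AMD = exp(sqrt(J/N))` reads as the
average fold-discrepancy (1 = identical, 2 = average two-fold error).
Because all parameters are positive rates with multiplicative uncertainty,
the search space is log-transformed.

The optimizer has two stages. The global stage is a differential-evolution
search (rand/1/bin, F = 0.8, CR = 0.9, population 15 per parameter by
default, log-uniform initialization inside multiplicative bounds that
default to 100-fold below/above the start). The local stage polishes with
Levenberg–Marquardt on the vector of log-residuals. Both stages respect
box bounds and a shared evaluation budget (2×10⁵ by default); stopping is
by relative objective stall (10⁻⁶ over 50 generations). A fit that
exhausts its budget is returned with `converged = FALSE` rather than an
error. All stochastic stages are reproducible under a fixed seed.

## Linear identifiability analysis

The sensitivity matrix `S` has one row per normalized measurement and one
column per parameter, with log-log entries computed by central finite
differences: each parameter is perturbed to 1.01·θ and 0.99·θ and
`s_ij = [ln y_i(1.01θ_j) − ln y_i(0.99θ_j)] / ln(1.01/0.99)`. Design
choices worth recording:

* Rows are all `N` normalized measurements, not a reduced independent
  basis; the within-series linear dependence introduced by normalization
  is retained, and all scaling uses `dim`, not the row count. This makes
  the scaled singular values exactly invariant under protocol repetition
  (a tested property). Reducing rows to an explicit `dim`-dimensional
  basis instead could shift third significant figures of the reported
  norms; the convention here is fixed and stated.
* Scaled quantities: singular values, column norms `‖S_j‖` and
  perpendicular-component norms `‖S_j⊥‖` are all divided by `sqrt(dim)`.
  The error ratios `R_j` (row norms of the pseudo-inverse, computed via
  the numerically stable QR route and verified against the direct
  `(SᵀS)⁻¹Sᵀ` computation in tests) are reported both raw — which is what
  converts a measurement geometric SD into a parameter geometric SD,
  `σ_linear,j = σ_data^{R_j}` — and ×`sqrt(dim)` for cross-protocol
  comparison, since either scaling convention is defensible.
* Structural identifiability is read off the scaled spectrum: for the
  on–off protocol at the fitted parameters all 13 scaled singular values
  exceed 10⁻³ (the smallest is ≈ 0.025), with no spectral gap, so no
  parameter combination is invisible to the data.

Confidence ellipses for parameter pairs are 2-D marginals of the
log-parameter covariance `ln(σ_data)²·(SᵀS)⁻¹` scaled by the two-degree
χ² quantile.

## Monte Carlo practical identifiability

`run_monte_carlo()` draws `k` noisy measurement sets per noise level,
refits all 13 parameters to each, and summarizes the scatter as geometric
SDs `σ_carlo,j = exp(SD(ln θ_j))`. The default refit is the
Levenberg–Marquardt stage alone, started from the generating parameters:
with tens to hundreds of replicates this keeps a full four-level, k = 50
analysis within minutes on one CPU, and because the refit is deterministic
the unperturbed level cleanly reports `σ_carlo = 1`. The trade-off is
deliberate: a local refit measures the noise-induced displacement of the
optimum, which is the quantity the linear analysis predicts, while a
cheap global stage would mostly add optimizer scatter of its own.

Two findings from this analysis are worth flagging. First, `σ_carlo,j`
grows with `σ_data` for every parameter and broadly tracks
`σ_linear,j`. Second, the two least identifiable parameters, δ and ε, are
*bound-sensitive*: for some noise realizations at `σ_data = 1.3` the
noisy likelihood decreases monotonically in δ all the way to the 100-fold
lower search bound (verified by profiling the objective and by global
DE+polish refits reaching the same optimum), so their σ_carlo (≈ 5 and
≈ 4.5 at `σ_data = 1.3` with k = 50) exceeds the linear prediction and
depends on the chosen bounds. Reported ceilings of parameter-estimation
error should therefore always be read together with the search bounds
that produced them.

## Dynamical regimes

`classify_response()` simulates tonic TNF switched on at t = 1 h (so peak
times are absolute simulation times), samples at ≤ 0.5 min, detects
NFκBn maxima with prominence filtering and quadratic sub-grid refinement,
and labels the response:

* **sustained** if the late-window (last 25 % of the horizon) peak-to-peak
  amplitude exceeds 1 % of the first-peak amplitude — **spiky** if,
  in addition, the late-window trough falls below 10 % of the late-window
  peak, i.e. the cycles are relaxation-like and return near baseline
  between spikes. A duty-cycle criterion (fraction of time above 10 % of
  the late maximum) was considered and is still recorded in the metrics,
  but it fails to separate relaxation oscillations whose spikes decay
  along a slow shoulder from genuinely smooth small-amplitude cycles; the
  trough criterion separates them cleanly.
* **near-perfect adaptation** if the response decays and the final NFκBn
  is below 10 % of the first peak (the pre-stimulus level being 0);
  checked before the damped label because an adapting system may also
  show several small decaying oscillations on its way down.
* **damped** for two or more decaying peaks converging to an elevated
  state; **no oscillation** for at most one peak with an elevated final
  level. Metrics near a threshold set a low-confidence flag.

The TNF-on fixed point is found by damped Newton iteration seeded from
the time-average of a long simulation tail (which also locates the
unstable focus inside a limit cycle), with residual ∞-norm tolerance
10⁻¹² and stability judged from the numerical Jacobian's eigenvalues with
a 10⁻⁹ s⁻¹ margin.

## Numerical choices

* Integration: `lsoda` with rtol 10⁻⁸, atol 10⁻¹⁰ and a compiled C
  right-hand side; the integrator restarts at every TNF switch so the
  discontinuous input never sits inside an adaptive step. Halving the
  tolerances changes trajectories by far less than 10⁻⁶ (tested).
* Extracted observable values are clamped at 0: the integrator can
  undershoot an exact zero by up to the absolute tolerance, and the
  normalization's logarithms require non-negative values.
* Degenerate inputs fail loudly: all-zero series cannot be normalized,
  rank-deficient sensitivity matrices raise a structural-identifiability
  error in `error_ratios()` (and report zero perpendicular norms with a
  warning), and schedule mismatches between measurement sets list the
  offending (genotype, observable, time) triples.

## Problem sizes used in the shipped analyses

The test suite and the acceptance script run the on–off protocol
(50 measurements, 41 independent points), sensitivity analyses at 1 %
perturbation, 24–48 h regime simulations at 0.25–0.5 min sampling, and a
four-level Monte Carlo with k = 50 replicates per level under the
reduced (local) refit. These sizes were chosen as the smallest that
exercise every claim of the analysis while keeping a complete run on one
CPU in the minutes range.

## Known limitations

* Both identifiability analyses are local: they start from the fitted
  parameters, and a differently parameterized regime (e.g. deep in the
  limit-cycle region) may be less identifiable.
* The sensitivity-matrix row construction and the `R_j` scaling follow
  one stated convention among defensible alternatives; third-significant-
  figure differences against other conventions are expected, and the
  c5a sensitivity norm in particular is sensitive to how the ρ-shift
  damps near-zero measurements.
* No single-cell (stochastic) simulation, no SBML import/export, and no
  bifurcation continuation; regime labels come from simulation-based
  metrics, not from tracking Hopf points.
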