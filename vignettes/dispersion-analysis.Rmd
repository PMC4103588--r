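---
title: "Two-site relaxation dispersion analysis with rexfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-site relaxation dispersion analysis with rexfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rexfit)
```

## The physical problem

Atoms in a biomolecule that exchange between two conformations A and B on
the microsecond-to-millisecond time scale broaden their NMR resonances. In a
CPMG experiment the effective transverse relaxation rate R2eff of such a
site depends on the repetition frequency of the refocusing pulses,
nu_cpmg = 1/(2 tau_cp); under a spin lock, the rotating-frame rate R1rho
depends on the lock amplitude omega1 and its offset Omega. Fitting these
dispersion curves yields the populations of the two states (pA, pB = 1 -
pA), the exchange rate kex = kAB + kBA, and the chemical-shift difference
between the states (dw), i.e. thermodynamics, kinetics and structural
information on a sparsely populated excited state.

rexfit implements both the classical closed-form models for this problem
and numeric propagation of the underlying Bloch-McConnell equations, plus
an automated protocol (sequential optimisation with warm starts, fixed
elimination rules, Monte-Carlo error propagation, AIC model selection over
clusters of spins that share kinetics).

## Model catalogue

Thirteen 2-site models are exposed through one catalogue
(`list_models()`), in the order the protocol optimises them:

* CPMG, closed form: `NoRex` (flat baseline), `LM63` (fast exchange,
  parameters phi_ex = pA pB dw^2 and kex), `IT99` (skewed populations),
  `TSMFK01` (very slow exchange, forward rate kAB), `CR72`
  (Carver-Richards, most time scales), `MMQ_CR72` (CR72 with
  coherence-dependent effective shifts for SQ/ZQ/DQ/MQ data).
* CPMG, numeric: `NS_CPMG_2site`, `NS_MMQ_2site` — explicit
  (tau - 180 - tau)^n propagation of the 2x2 complex Bloch-McConnell
  coherence evolution, with the 180-degree pulse applied as complex
  conjugation and one exact matrix exponential per free-evolution segment.
* R1rho, closed form: `NoRex`, `M61` (on-resonance fast exchange), `DPL94`
  (off-resonance fast exchange), `TP02`, `MP05` (skewed populations /
  all time scales).
* R1rho, numeric: `NS_R1rho_2site` — one matrix exponential of the 6x6
  real (x, y, z per state) evolution matrix over the spin-lock period.

The numeric solutions are the convention-free reference: every analytic
model is cross-validated against them in its validity regime (tests and the
acceptance script recompute these agreements). The measured agreement
domains are: CR72 within 2% of the numeric curve for kex >= 4 dw
(about 3.7% at kex = 2 dw and about 6% over a broad sweep that includes
slow-intermediate exchange); LM63 within 2% for kex >= 20 dw; IT99 within
10% for pA >= 0.95 on the fast side; TSMFK01 within 10% for kAB of order
1/s (kex <= 200/s at pA = 0.99); DPL94 within 5% for kex >= 10 dw; TP02 and
MP05 within 10% for pA >= 0.95, with MP05 strictly closer to the numeric
reference than TP02 over a mixed-regime sweep.

## Conventions and units

All frequencies are rad/s internally; the user-facing boundary is ppm for
shift differences, Hz for nu_cpmg and omega1/(2 pi), and 1/s for rates.
Conversions use |gamma_X/gamma_1H| = 1 (1H), 0.10136767 (15N), 0.25144953
(13C).

* `dw` is stored as a magnitude: 2-site dispersion data determine it only
  through even powers (analytic models) or a global sign symmetry (numeric
  models), so its sign is not identifiable and is not reported.
* `phi_ex` is parameterised in ppm^2 and converted to rad^2/s^2 at each
  point's field, so a single per-spin value describes multi-field data.
* CPMG: tau_cp is the time between consecutive 180-degree pulses,
  nu_cpmg = 1/(2 tau_cp), and the numeric models round 2 T nu_cpmg to the
  nearest even pulse count (warning above 1% mismatch). This convention is
  pinned by the analytic-numeric agreement itself: a factor-of-two error in
  it would produce order-100% disagreement with LM63 in fast exchange,
  where the observed deviation is 0.04%.
* R1rho geometry: Omega_A is the state-A offset from the spin-lock carrier,
  Omega_B = Omega_A + dw, the averaged offset defines theta for the
  fast-exchange models, and state-specific effective fields enter TP02 and
  MP05, following each model's derivation. R1 is a measured per-point
  input, never fitted.
* Numeric initial conditions: thermal equilibrium (pA, pB) for CPMG
  (a `state_a` flag switches to pure state A), and equilibrium
  magnetization hard-aligned onto the state-A effective field for R1rho.

## Fitting machinery

The target is the standard weighted least squares chi2 = sum((R_calc -
R_obs)^2 / sigma^2) over all points of a spin (or of a cluster, in which
case pA and kex — or kAB — are shared and dw, dwH, phi_ex and the per-field
baselines remain per-spin). Optimisation is Nelder-Mead on bound-normalised
coordinates (log scale for kex, kAB, phi_ex) with a logarithmic barrier, so
the models are never evaluated outside their bounds:

* bounds: r20 (and R1rho') in [0.1, 200] 1/s; pA in [0.5, 1 - 1e-6]
  (pA >= 0.5 breaks the 2-site label-swap symmetry); kex in [1, 1e6] 1/s;
  kAB in [0.01, 1e4] 1/s; dw, dwH in [0, 30] ppm; phi_ex in [1e-4, 225]
  ppm^2;
* the barrier weight is annealed through 1e-3, 1e-6, 1e-9 with warm starts;
* after the last stage the simplex is restarted from its own optimum until
  the restart cannot improve chi2 by more than 1e-9 relative (at most 25
  restarts). A single restart proved insufficient: in eight-dimensional
  cluster fits it left chi2 up to 1e-4 above the minimum, enough to break
  the warm-start-equals-exhaustive contract, so stagnation of the restart
  sequence is the convergence criterion;
* the initial grid search uses 11 points per gridded dimension (log-spaced
  for kex, kAB, phi_ex), with baseline rates seeded from the observed rate
  at the largest nu_cpmg (or omega1) of each (spin, field) rather than
  gridded.

The automated protocol (`run_protocol()`) skips the grid wherever a warm
start exists: model nesting (DPL94 starts from M61; TP02 from DPL94 with dw
seeded from phi_ex at pA = 0.95; MP05 copies TP02), model equivalence (the
numeric CPMG models copy the CR72 / MMQ-CR72 optima), and cluster averaging
(clustered fits start from the mean of the members' non-clustered global
parameters). The prescribed optimisation order lists IT99 before CR72
although IT99's natural warm-start source is CR72; in that position the
protocol simply falls back to the grid search, which also covers the case
of an eliminated source fit.

Elimination rules (applied to every fit and to every Monte-Carlo
simulation): a kinetic rate within 1% of its upper bound; pA within 1e-4 of
1 while dw sits at its upper bound; non-convergence; any non-finite
parameter. NoRex is never removed from the candidate set. Model selection
minimises AIC = chi2 + 2k (AICc available behind a flag); ties resolve to
fewer parameters, then catalogue order. The final selection run re-ranks
the stored fits without refitting.

Monte-Carlo errors back-calculate the fitted curve, add Gaussian noise with
each point's measured sigma, refit from the point estimate (one barrier
stage, simplex tolerance 1e-8 — error estimates need far less polish than
point estimates), eliminate failed simulations, and report per-parameter
standard deviations over the survivors (default 500 simulations; the test
suite uses 50 with wider tolerances). Per-unit seeds are derived from the
master seed by unit index, which makes serial and parallel execution
bit-identical for any worker count.

## The synthetic-data generator

`simulate_dataset()` back-calculates any catalogue model and adds Gaussian
noise directly on the rates; `simulate_intensities()` instead emulates the
constant-time intensity observable I = I_ref exp(-R T) with Gaussian
intensity noise, exercising the peak-intensity entry point
(`calc_r2eff_two_point()` + `propagate_r2eff_error()`). The frozen study
conditions used by the tests and the acceptance script are a classic
well-conditioned intermediate-exchange design: pA = 0.95, kex = 1000/s,
dw = 3 ppm, baselines 10 and 12 1/s at 600 and 800 MHz, 15 CPMG frequencies
(67-1000 Hz, T = 30 ms) per field, sigma(R2eff) = 0.5 1/s. At these
settings all of pA, kex and dw are separately identifiable; a fast-exchange
design (kex well above dw) would determine only phi_ex and kex, and no
simulated-data check can demonstrate that real data escape that degeneracy.
The generator draws i.i.d. Gaussian noise and emulates neither peak overlap
nor baseline distortions nor field-dependent baseline differences beyond
those specified, so passing tests validate the estimator and protocol
logic, not spectral processing.

Problem sizes in the acceptance checks (chosen to make the Monte-Carlo
statements statistically meaningful at interactive run times): 100
replicate datasets for parameter recovery with 50 MC simulations each, 100
replicates per model-selection scenario, 500 MC simulations for the
error-calibration check.

## Numerical choices

* 2x2 complex matrix exponentials use the exact closed form
  e^mu (cosh(d) I + sinh(d)/d B) with a series for small d; the 6x6 real
  exponentials use `Matrix::expm` (scaling-and-squaring), which matches an
  eigen-decomposition reference to 5e-14 on stiff exchange matrices.
* The echo train is applied as the linear pair propagator
  A conj(A) conj(A) A raised to n/2 by repeated squaring; splitting each
  segment in half changes the result only at rounding level (tested at
  1e-8).
* CR72 clamps its acosh argument to >= 1 against rounding near dw -> 0 and
  evaluates the large-eta branch in log space to avoid cosh overflow;
  TSMFK01 evaluates its sinc by series below 1e-8; every model returns the
  baseline *exactly* (early return, not to rounding) when pA = 1, dw = 0,
  phi_ex = 0, kAB = 0 or kex = 0.
* Parameter regions where a numeric propagation loses positive
  magnetization score chi2 = Inf, so grids and the simplex avoid them
  instead of aborting a fit.

## Known limitations

* Two-site exchange only; no 3-site or multi-site variants.
* CPMG pulses are ideal and instantaneous; off-resonance pulse effects are
  not modelled.
* The MQ branch of the MMQ models averages the two multiple-quantum
  components' decays; differential proton relaxation within the MQ manifold
  is not modelled.
* AIC model selection carries its known per-model false-positive rate; the
  no-exchange selection check therefore asserts >= 90%, not 100%.
* The sign of dw (and dwH) is not determined by these data and is reported
  as a magnitude.
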