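---
title: "Modeling THC-induced changes in feeling high and alertness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling THC-induced changes in feeling high and alertness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thcpd)
```

## The problem

Subjective psychoactive effects of Δ9-tetrahydrocannabinol (THC) are
routinely quantified on 0–100 mm visual analogue scales: "feeling high"
rises from a zero baseline after dosing, while "alertness" falls from its
pre-dose level and recovers. Both effects lag plasma — and even brain —
concentrations, and both are driven jointly by THC and its active
first-pass metabolite 11-OH-THC, which binds CB1 with comparable affinity.
`thcpd` couples a perfusion-limited PBPK model of the two compounds to two
pharmacodynamic models of these scales, and wraps them in virtual-trial
simulation, verification statistics, and parameter estimation.

## Pharmacokinetic layer

The PK engine is a whole-body perfusion-limited model: venous blood →
lung → arterial blood → tissues (brain, liver, rest-of-body in the
default topology; the tissue set is configurable). Every tissue is
flow-limited,

$$V_i \frac{dC_i}{dt} = Q_i\left(C_\text{art} - \frac{C_i}{Kp_i / BP}\right),$$

with $Kp_i$ the tissue:plasma partition coefficient and $BP$ the
blood:plasma ratio. Clearance of both compounds is hepatic, referenced to
the liver's emergent venous blood concentration, and a fraction `fm` of
parent clearance forms 11-OH-THC in situ. Absorption is first-order from
depots: oral doses (scaled by `f_a = 0.45`, rate `k_a = 0.7` h⁻¹) enter
the liver, so first-pass extraction and first-pass metabolite formation
emerge mechanistically; inhaled doses (scaled by `lung_f_a`, rate
`lung_k_a`) enter the lung; IV bolus and infusion enter venous blood.
Setting `oral_entry = "venous"` bypasses first-pass, which is the
configuration under which fast oral absorption converges to an IV bolus —
a useful structural check, since a lung- or gut-entry bolus differs from a
venous one by one circulation pass of hepatic extraction.

The published clinical parameterization of this PBPK structure (tissue
partition coefficients, clearances) is not reproduced here: the engine is
fully configuration-driven and ships with `default_pk_spec()`, a
**synthetic, non-authoritative fixture** built from standard adult
physiology (cardiac output 390 L/h; brain 46 L/h, 1.45 L; liver 90 L/h,
1.8 L) with partition and clearance constants chosen so that three
qualitative THC properties hold: the brain:plasma total-concentration
ratio sits in the 2–5 range after distribution (brain Kp 3.5), oral
availability is low (f_a 0.45 × hepatic availability ≈ 0.14), and inhaled
brain exposure peaks within minutes. Quantitative predictions for a real
trial require a study-specific `pk_model_spec()`.

The ODE system is integrated with `deSolve::lsoda` (stiff-capable) at
`rtol = 1e-8`, `atol = 1e-10`. Dosing discontinuities are handled as
solver events so integration restarts exactly at bolus times and infusion
window edges. Mass balance — absorbed amount equals amount in circulation
plus cumulative elimination — is audited at every output time and exposed
in the `balance` attribute; states more negative than 100 × `atol` raise
an error rather than being clipped.

## The "feeling high" model

A direct-effect model with one effect compartment per compound:

$$\frac{dC_\text{eff}}{dt} = k_{e0}\,(C_\text{brain} - C_\text{eff}),
\qquad k_{e0} = 2\ \text{h}^{-1}\ \text{(both compounds)},$$

followed by a shared sigmoid Emax transform of the *summed* effect-site
concentrations $S = C_\text{THC,eff} + C_\text{11OH,eff}$:

$$\text{VAS}_\text{high} = \frac{E_\text{max}\,S^{h}}{EC_{50}^{h} + S^{h}},
\qquad E_\text{max} = 80\ \text{mm},\ EC_{50} = 0.21\ \mu M,\ h = 1.8.$$

The two compounds are assumed equipotent (shared $E_\text{max}$ and
$EC_{50}$), so the score is symmetric in them and depends on the
concentrations only through their sum; the sum is formed *before*
exponentiation. Total (not unbound) brain tissue concentration is the
driver. The pre-dose baseline is 0 mm — a turnover model cannot be
anchored at a zero baseline, which is why this endpoint uses a direct
model. The score is naturally bounded by $E_\text{max} = 80$ mm; clipping
to the physical [0, 100] mm range happens only at the reporting layer.

## The alertness model

An indirect-response (turnover) model with **no** effect compartment —
the module exposes no effect-site state, the turnover itself supplying
the observed lag:

$$\frac{d\,\text{VAS}}{dt} = k_\text{in}\,(1 - E(t)) - k_\text{out}\,\text{VAS},
\qquad k_\text{in} = \text{baseline} \times k_\text{out},$$

with baseline 60 mm, $k_\text{out} = 1$ h⁻¹, and inhibition of production
by the summed brain concentrations:

$$E(t) = \frac{E_\text{max}\,S^{h}}{EC_{50}^{h} + S^{h}},
\qquad E_\text{max} = 90\%,\ EC_{50} = 0.23\ \mu M,\ h = 1.9.$$

$E_\text{max}$ is stored as a percent, matching how it is reported, and
converted to a fraction in exactly one place (`inhibition_fraction()`).
The initial condition is the drug-free steady state, so a zero-dose
simulation holds 60 mm indefinitely; under exposure the score is confined
to $(\text{baseline}(1 - E_\text{max}/100),\ \text{baseline}]$ — a floor
of 6 mm for the defaults, approached only asymptotically — and it relaxes
back to baseline at rate $k_\text{out}$ as concentrations decay. Trial
configurations may override the baseline (e.g. to a placebo-arm mean)
via `alertness_params(baseline = )` or the design document.

## Numerical choices

The effect-compartment and turnover equations are linear in their state
with time-varying forcing, so when driven by gridded concentrations the
package propagates them with the *exact* exponential-update formula for
piecewise-linear forcing: on each interval the update
$y_{i+1} = (y_i - a + b/k)e^{-kh} + a + bh - b/k$ is exact for forcing
$a + bt$. The only approximation is linear interpolation of the driver
between grid points (default grid 0.05 h), which also makes per-subject
simulation cheap enough for 500-subject virtual trials and smooth enough
for least-squares fitting. When the driver is supplied as a continuous
function, the same equations are integrated with `lsoda` at
`rtol = 1e-10` instead; the analytic-oracle tests use this path against
closed-form solutions for constant and mono-exponential forcing.

Peaks and troughs are taken over the simulated sampling grid, not the
continuous solution. Ties in the trough break to the earliest time.

## Virtual trials and variability

`run_virtual_study()` simulates the PK once (no PK variability by
default), then draws per-subject $E_\text{max}$ and $EC_{50}$ for the
requested endpoint from **median-anchored log-normal** distributions:
$\sigma^2 = \ln(1 + CV^2)$ with the median at the population value. The
published CVs are 34% ($E_\text{max}$) and 70% ($EC_{50}$, capped from a
126% literature value precisely to avoid non-positive draws) for feeling
high, and 30%/30% for alertness. The log-normal family is the package's
choice — the source context does not name a distribution — because it
respects the printed CVs while guaranteeing positivity, and it is the
standard pharmacometric convention. One consequence: draws around the 90%
alertness maximum-inhibition value can exceed 100%; they are used as
drawn (production can transiently invert) and the reported score is
clipped to [0, 100] mm, keeping the realized CV at its configured value.
Parameters without published CVs ($k_{e0}$, Hill coefficients,
$k_\text{out}$, baselines) are fixed across subjects. Age range and sex
ratio are recorded as design metadata but drive nothing: no covariate
model is applied.

Reproducibility: a single integer seed initializes one RNG stream and
subjects are sampled from it in order (trial-major), so identical seeds
give bit-identical outputs; the seed is written into every manifest.
The default design is 20 trials × 25 subjects, ages 18–65, 1:1 sex
ratio, baselines 0 mm (feeling high) and 60 mm (alertness). Percentile
envelopes (5th–95th) are pooled across all subjects rather than across
trial means.

## Verification statistics

`verify_trial()` computes the field's acceptance statistics against an
observed mean VAS series: the ratio of predicted to observed extreme
score ($R_\text{max}$; peak for feeling high, trough for alertness),
checked against a fold-range with *inclusive* bounds
($1/f \le r \le f$; $f = 2$ for feeling high, 1.3 for alertness — the
tighter band reflecting the nonzero alertness baseline), and the fraction
of observed points inside the interpolated 5th–95th percentile envelope.
Observed extremes are taken on the observed grid as given, with no
smoothing.

## Synthetic data and what passing tests show

`generate_observed_study()` fabricates clinical-style "observed" series:
a forward-simulated population mean under known true parameters (with the
configured interindividual CVs across subjects), additive Gaussian
observation noise (default sd 3 mm — the simplest defensible stand-in, as
no noise model is published), clipped to [0, 100] mm, on a
clinical-style grid (every 10 min to 2 h, then hourly to 8 h), emitted
together with its ground truth. `make_two_peak_oral_series()` adds a
delayed oral depot at a meal time to fabricate the double-peak pattern
seen in some long oral trials — a stress fixture the single-peak model is
not expected to cover.

The generator shares the forward model with the simulator, so recovery
tests demonstrate *self-consistency* — that estimation inverts the
package's own data-generating process — and the verification suite
demonstrates the statistics behave correctly. They do not validate the
model against real clinical behavior: digitized trial data, real
PK parameterizations, placebo response, meal effects on absorption, and
tolerance are all outside what these tests can show.

## Parameter estimation

`fit_pd()` mirrors the original manual-plus-module optimization with a
reproducible procedure: bounded nonlinear least squares
(`minpack.lm::nls.lm`) on the mean VAS trajectory, with parameters
log-transformed by default (they are all positive; Hill coefficients are
bounded to [0.5, 5], a plausible pharmacodynamic slope range) and a
seeded Latin-hypercube multistart (default 10 starts) replacing manual
tuning. The loss is the sum of squared residuals, optionally weighted by
the reported subject count. Non-convergence of all starts is flagged in
the result rather than raised. `profile_loss()` re-optimizes the
remaining free parameters along a grid of one parameter — the standard
diagnostic for the $E_\text{max}$–$EC_{50}$ ridge that appears when only
low-dose data are available.

On noise-free self-generated data the fits recover the generating
parameters to well under 1%; with 3 mm observation noise on 13-point
clinical grids, median absolute relative errors for
$(E_\text{max}, EC_{50}, k_{e0})$ stay under 15% across replicates (the
test suite runs 100).

## Problem sizes

The shipped tests and the acceptance script run at desk scale by design:
virtual studies of 20 × 25 subjects on a 0.05 h grid over 12 h, Monte
Carlo sampling checks at $10^5$ draws, recovery studies of 100 noisy
replicates on 13-point grids, and dose–response sweeps over 5–7 doses per
route. These sizes were chosen as the smallest that make the statistical
assertions stable; all complete in minutes on one CPU.

## Known limitations

- The default PK fixture is qualitative; no claim of clinical accuracy.
- Linear PK only; no enterohepatic recirculation, no food effects, no
  permeability-limited brain uptake.
- No placebo-response model and no covariate model on PD parameters.
- Mean-trajectory (naive-pooled) estimation only — no mixed-effects or
  Bayesian machinery.
- VAS clipping at [0, 100] mm is a reporting convention; the underlying
  states are unbounded above by construction only for sampled
  maximum-inhibition values above 100%.
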