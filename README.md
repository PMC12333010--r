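# thcpd

PBPK–PD simulation of the psychoactive effects of Δ9-tetrahydrocannabinol
(THC) and its active metabolite 11-OH-THC, measured on 0–100 mm visual
analogue scales (VAS): the euphoric "feeling high" score and the sedative
drop in "alertness".

## Who this is for

Pharmacometricians and cannabinoid researchers who need to simulate how
subjective THC effects evolve over time for IV, oral, or inhaled dosing;
run virtual clinical trials with interindividual variability; check model
predictions against observed VAS–time curves with the field's fold-range
and percentile-coverage statistics; or estimate pharmacodynamic parameters
from mean VAS trajectories.

## The model

**Pharmacokinetics.** A perfusion-limited, whole-body compartmental model
(venous and arterial blood, lung, brain, liver, rest-of-body; extensible)
for THC and 11-OH-THC. Each tissue obeys

    V dC/dt = Q (C_art − C / (Kp / B:P))

with first-order absorption depots for oral (gut → liver, so hepatic
first-pass extraction and first-pass 11-OH-THC formation emerge) and
inhaled (lung) dosing. THC absorption constants: f_a = 0.45, k_a = 0.7 h⁻¹
oral; lung f_a up to 0.9 and lung k_a up to 200 h⁻¹ inhaled. The shipped
PK fixture (`default_pk_spec()`) is a synthetic, non-authoritative
parameterization tuned only to qualitative THC disposition (brain:plasma
ratio 2–5, low oral availability, fast inhaled uptake); quantitative work
should supply a study-specific `pk_model_spec()`.

**VAS "feeling high"** — a direct-effect model. Each compound's total
brain concentration drives a first-order effect compartment,

    dC_eff/dt = k_e0 (C_brain − C_eff),      k_e0 = 2 h⁻¹,

and the summed effect-site concentrations pass through a shared sigmoid
Emax function (E_max = 80 mm, EC50 = 0.21 µM, Hill = 1.8):

    VAS_high = E_max S^h / (EC50^h + S^h),   S = C_THC,eff + C_11OH,eff.

**VAS "alertness"** — an indirect-response (turnover) model with no effect
compartment. Alertness is produced at zero-order rate k_in =
baseline × k_out (baseline 60 mm, k_out = 1 h⁻¹) and lost first-order;
the summed brain concentrations inhibit production through a second Hill
function (maximum inhibition 90%, EC50 = 0.23 µM, Hill = 1.9):

    dVAS/dt = k_in (1 − E(t)) − k_out VAS.

**Virtual trials.** Per-subject E_max and EC50 are drawn from
median-anchored log-normal distributions with the published
interindividual CVs (34% / 70% for feeling high, 30% / 30% for
alertness); 20 trials × 25 subjects by default, summarized as the mean and
5th–95th percentile envelope.

## Worked example

Five legal cannabis cigarettes' worth of inhaled THC (12.75 mg):

```r
library(thcpd)

cs <- simulate_pk(default_pk_spec(), default_compounds(),
                  dose_event("inhaled", cigarette_dose(5)),
                  times = seq(0, 12, by = 0.05))
vh <- simulate_feeling_high(cs, feeling_high_params())
va <- simulate_alertness(cs, alertness_params())

max(vh$vas_mm)                      # 66.3 mm peak "feeling high"
vh$time_h[which.max(vh$vas_mm)]     # at 0.40 h (brain peak is at 0.05 h)
alertness_trough(va)                # 39.7 mm trough at 0.75 h

des <- trial_design(dose_event("inhaled", cigarette_dose(5)),
                    seed = 20260924L)            # 20 trials x 25 subjects
st <- run_virtual_study(des, endpoint = "feeling_high")
peaks <- apply(st$subject_matrix, 2, max)
mean(peaks)                         # 62.2 mm mean subject peak
quantile(peaks, c(0.05, 0.95))      # [27.7, 100.0] mm across subjects
```

The effect peaks well after the brain concentration does — the
effect-compartment lag for "feeling high", the turnover lag for
alertness — and the wide subject-level band reflects the large
published CVs on E_max and EC50.

Configuration-file pipelines (`cmd_simulate()`, `cmd_dose_response()`,
`cmd_verify()`) run the same stages from YAML documents and write tidy,
unit-suffixed CSVs plus a manifest (seed, config hash, version) that makes
every run reproducible.

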