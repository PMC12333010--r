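Package: thcpd
Title: PBPK-PD Simulation of THC Psychoactive Effects on Visual Analogue Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A perfusion-limited physiologically based pharmacokinetic (PBPK)
    engine for delta-9-tetrahydrocannabinol (THC) and its active metabolite
    11-OH-THC after intravenous, oral, or inhaled dosing, coupled to two
    pharmacodynamic models of subjective effect: a dual effect-compartment
    sigmoid Emax model for the visual analogue scale (VAS) "feeling high"
    score and an indirect-response (turnover) model for VAS "alertness".
    Includes virtual-trial simulation with log-normal interindividual
    variability, dose-response sweeps, model-verification statistics
    (fold-range ratios and percentile coverage), nonlinear least-squares
    parameter estimation with multistart, and a synthetic-data generator
    for parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
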