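# shared fixtures: default model objects and small time grids
fx_compounds <- default_compounds()
fx_pk <- default_pk_spec()
fx_high <- feeling_high_params()
fx_alert <- alertness_params()

grid_fast <- seq(0, 12, by = 0.05)
grid_coarse <- seq(0, 12, by = 0.2)

sim_inhaled <- function(dose_mg, times = grid_fast, spec = fx_pk, ...) {
  simulate_pk(spec, fx_compounds, dose_event("inhaled", dose_mg), times, ...)
}

sim_oral <- function(dose_mg, times = grid_fast, spec = fx_pk, ...) {
  simulate_pk(spec, fx_compounds, dose_event("oral", dose_mg), times, ...)
}

# a zero-concentration series on a grid
zero_conc <- function(times = grid_coarse) {
  structure(
    data.frame(time_h = times, thc_plasma_uM = 0, thc_brain_uM = 0,
               ohthc_plasma_uM = 0, ohthc_brain_uM = 0),
    class = c("conc_series", "data.frame")
  )
}

# small design for quick population runs
small_design <- function(regimen, n_trials = 2, n_subj = 10,
                         times = grid_coarse, seed = 42L, ...) {
  trial_design(regimen, n_trials = n_trials, n_subjects_per_trial = n_subj,
               sampling_times = times, seed = seed, ...)
}
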