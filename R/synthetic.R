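#' Synthetic observed-study specification
#'
#' Describes how to fabricate a clinical-style "observed" mean VAS series
#' from known true parameters: forward-simulate a virtual population under
#' the true PD parameters (with interindividual variability), take the mean
#' trajectory at a clinical sampling grid, and add observation noise. Used
#' to exercise verification and estimation with no external data.
#'
#' @param regimen list of [dose_event()]s (or one event).
#' @param endpoint `"feeling_high"` or `"alertness"`.
#' @param true_high,true_alert the generating PD parameter sets (these are
#'   the ground truth for recovery studies).
#' @param pk_spec the PK fixture used for forward simulation.
#' @param compounds compound parameters.
#' @param sampling_times observation grid, h. Default is clinical-style:
#'   every 10 min to 2 h, then hourly to 8 h.
#' @param noise_sd_mm additive Gaussian observation noise on the mean
#'   curve, mm (>= 0).
#' @param n_subjects number of virtual subjects contributing to the mean.
#' @param seed RNG seed.
#' @return An object of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(regimen, endpoint = "feeling_high",
                                 true_high = feeling_high_params(),
                                 true_alert = alertness_params(),
                                 pk_spec = default_pk_spec(),
                                 compounds = default_compounds(),
                                 sampling_times = c(seq(0, 2, by = 1 / 6),
                                                    seq(3, 8, by = 1)),
                                 noise_sd_mm = 3, n_subjects = 25,
                                 seed = 1L) {
  if (inherits(regimen, "dose_event")) regimen <- list(regimen)
  if (noise_sd_mm < 0) stop("`noise_sd_mm` must be >= 0", call. = FALSE)
  if (any(diff(sampling_times) <= 0))
    stop("`sampling_times` must be increasing", call. = FALSE)
  structure(
    list(regimen = regimen, endpoint = endpoint, true_high = true_high,
         true_alert = true_alert, pk_spec = pk_spec, compounds = compounds,
         sampling_times = sampling_times, noise_sd_mm = noise_sd_mm,
         n_subjects = as.integer(n_subjects), seed = as.integer(seed)),
    class = "synthetic_study_spec"
  )
}

#' Generate a synthetic observed study
#'
#' Forward-simulates the population mean VAS under the spec's true
#' parameters (one trial of `n_subjects` with the configured CVs), adds
#' additive Gaussian noise to the mean curve, clips to `[0, 100]` mm, and
#' returns the series together with a ground-truth record for recovery
#' testing.
#'
#' @param spec a [synthetic_study_spec()].
#' @return list with `observed` (an [observed_series()]), `conc` (the
#'   driving `conc_series`) and `truth` (list of the generating parameters
#'   and the noiseless mean curve).
#' @export
generate_observed_study <- function(spec) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  des <- trial_design(
    spec$regimen, n_trials = 1L, n_subjects_per_trial = spec$n_subjects,
    sampling_times = spec$sampling_times,
    baseline_alertness = spec$true_alert$baseline, seed = spec$seed
  )
  st <- run_virtual_study(des, pk_spec = spec$pk_spec,
                          compounds = spec$compounds,
                          endpoint = spec$endpoint,
                          pop_high = spec$true_high,
                          pop_alert = spec$true_alert)
  mean_vas <- st$summary$mean_mm

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed + 1000003L)  # distinct stream from the subject draws
  noisy <- mean_vas + stats::rnorm(length(mean_vas), 0, spec$noise_sd_mm)
  noisy <- pmin(pmax(noisy, 0), 100)

  obs <- observed_series(spec$sampling_times, noisy,
                         n = spec$n_subjects, endpoint = spec$endpoint,
                         trial = sprintf("synthetic-seed%d", spec$seed))
  list(observed = obs, conc = st$conc,
       truth = list(high = spec$true_high, alert = spec$true_alert,
                    noiseless_mean_mm = mean_vas, seed = spec$seed))
}

#' Synthesize a two-peak oral series (post-meal absorption boost)
#'
#' Oral THC trials with long sampling windows can show a second
#' "feeling high" peak a few hours post-dose, consistent with a meal
#' increasing oral availability and re-starting absorption. This helper
#' fabricates such a series by adding a delayed oral dose (a second depot)
#' of `meal_boost` times the original dose at `meal_time`. It is a stress
#' fixture for the verification metrics; the single-peak model itself does
#' not reproduce two peaks.
#'
#' @param spec a [synthetic_study_spec()] whose regimen is a single oral
#'   dose.
#' @param meal_time time of meal, h, within the sampling span.
#' @param meal_boost fraction of the original dose re-presented for
#'   absorption at the meal (0 reproduces the standard series).
#' @return as [generate_observed_study()].
#' @export
make_two_peak_oral_series <- function(spec, meal_time, meal_boost) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  span <- range(spec$sampling_times)
  if (meal_time <= span[1] || meal_time >= span[2])
    stop("`meal_time` must lie inside the sampling span", call. = FALSE)
  if (meal_boost < 0) stop("`meal_boost` must be >= 0", call. = FALSE)
  base_ev <- spec$regimen[[1]]
  if (base_ev$route != "oral")
    stop("two-peak fixture requires an oral regimen", call. = FALSE)
  if (meal_boost > 0) {
    spec$regimen <- c(spec$regimen, list(
      dose_event("oral", base_ev$amount_mg * meal_boost,
                 start_time = meal_time)
    ))
  }
  generate_observed_study(spec)
}
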