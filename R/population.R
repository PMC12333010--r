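#' Virtual trial design
#'
#' @param regimen list of [dose_event()]s (or one event).
#' @param n_trials number of replicate trials, >= 1.
#' @param n_subjects_per_trial subjects per trial, >= 1.
#' @param sampling_times output grid, h, increasing. Default: 0 to 12 h in
#'   0.05 h steps.
#' @param age_range,sex_ratio demographic metadata recorded with outputs;
#'   no covariate model is applied to the PD parameters.
#' @param baseline_high pre-dose "feeling high" score, mm (0 by design).
#' @param baseline_alertness pre-dose alertness score, mm.
#' @param seed integer RNG seed; recorded in all outputs.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(regimen, n_trials = 20, n_subjects_per_trial = 25,
                         sampling_times = seq(0, 12, by = 0.05),
                         age_range = c(18, 65), sex_ratio = 0.5,
                         baseline_high = 0, baseline_alertness = 60,
                         seed = 1L) {
  if (inherits(regimen, "dose_event")) regimen <- list(regimen)
  stopifnot(n_trials >= 1, n_subjects_per_trial >= 1,
            all(diff(sampling_times) > 0))
  structure(
    list(regimen = regimen, n_trials = as.integer(n_trials),
         n_subjects_per_trial = as.integer(n_subjects_per_trial),
         sampling_times = sampling_times, age_range = age_range,
         sex_ratio = sex_ratio, baseline_high = baseline_high,
         baseline_alertness = baseline_alertness, seed = as.integer(seed)),
    class = "trial_design"
  )
}

# median-anchored log-normal draw: median = m, CV (%) -> sdlog
rlnorm_cv <- function(n, median, cv_pct) {
  if (cv_pct == 0) return(rep(median, n))
  sdlog <- sqrt(log(1 + (cv_pct / 100)^2))
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

#' Sample one virtual subject's PD parameters
#'
#' Draws per-subject `E_max` and `EC50` for both endpoints from
#' median-anchored log-normal distributions with the population
#' coefficients of variation (`sdlog^2 = ln(1 + CV^2)`); parameters without
#' a CV (`k_e0`, Hill coefficients, `k_out`, baseline) are carried over
#' fixed. Log-normal sampling guarantees every draw is strictly positive,
#' which is the reason the published EC50 variability was capped. Draws
#' consume the current R RNG stream; seed it (or use [run_virtual_study()],
#' which seeds one stream and samples subjects in order).
#'
#' @param pop_high population [feeling_high_params()].
#' @param pop_alert population [alertness_params()].
#' @param subject_id identifier stored in the realization.
#' @return An object of class `subject_realization` with elements `high`
#'   and `alert` (per-subject parameter sets) and `subject_id`.
#' @export
sample_subject <- function(pop_high, pop_alert, subject_id = 1L) {
  high <- feeling_high_params(
    k_e0_thc = pop_high$k_e0_thc, k_e0_ohthc = pop_high$k_e0_ohthc,
    e_max = rlnorm_cv(1, pop_high$e_max, pop_high$cv_emax),
    ec50 = rlnorm_cv(1, pop_high$ec50, pop_high$cv_ec50),
    hill = pop_high$hill, cv_emax = 0, cv_ec50 = 0
  )
  # built without the population-level (0, 100] check on e_max: a
  # log-normal draw around 90% can exceed 100%; it is used as drawn (the
  # reported score is clipped at 0 mm), preserving the configured CV.
  alert <- structure(
    list(k_out = pop_alert$k_out, baseline = pop_alert$baseline,
         e_max = rlnorm_cv(1, pop_alert$e_max, pop_alert$cv_emax),
         ec50 = rlnorm_cv(1, pop_alert$ec50, pop_alert$cv_ec50),
         hill = pop_alert$hill, cv_emax = 0, cv_ec50 = 0),
    class = "alertness_params"
  )
  structure(list(subject_id = subject_id, high = high, alert = alert),
            class = "subject_realization")
}

#' Summarize subject trajectories
#'
#' Pointwise mean and empirical 5th / 95th percentiles across subjects
#' (pooled over trials).
#'
#' @param mat matrix of VAS scores, time in rows, subjects in columns.
#' @param times time grid, h.
#' @return data frame `time_h`, `mean_mm`, `p5_mm`, `p95_mm`, `n`.
#' @export
summarize_subjects <- function(mat, times) {
  data.frame(
    time_h = times,
    mean_mm = rowMeans(mat),
    p5_mm = apply(mat, 1, stats::quantile, probs = 0.05, names = FALSE),
    p95_mm = apply(mat, 1, stats::quantile, probs = 0.95, names = FALSE),
    n = ncol(mat)
  )
}

#' Run a replicated virtual trial
#'
#' Simulates the PK once (pharmacokinetics carry no interindividual
#' variability by default), then draws `n_trials * n_subjects_per_trial`
#' subject realizations from one RNG stream seeded with `design$seed` and
#' simulates each subject's VAS trajectory for the requested endpoint.
#' Identical seeds give bit-identical output.
#'
#' @param design a [trial_design()].
#' @param pk_spec a [pk_model_spec()].
#' @param compounds list with `thc`, `ohthc` [compound_params()].
#' @param endpoint `"feeling_high"` or `"alertness"`.
#' @param pop_high,pop_alert population PD parameter sets.
#' @return list with `subjects` (long data frame: `trial_id`, `subject_id`,
#'   `time_h`, `vas_mm`), `summary` (see [summarize_subjects()]), `conc`
#'   (the shared `conc_series`), `endpoint`, `seed`.
#' @export
run_virtual_study <- function(design, pk_spec = default_pk_spec(),
                              compounds = default_compounds(),
                              endpoint = c("feeling_high", "alertness"),
                              pop_high = feeling_high_params(),
                              pop_alert = alertness_params()) {
  endpoint <- match.arg(endpoint)
  stopifnot(inherits(design, "trial_design"))
  pop_alert <- alertness_params(
    k_out = pop_alert$k_out, baseline = design$baseline_alertness,
    e_max = pop_alert$e_max, ec50 = pop_alert$ec50, hill = pop_alert$hill,
    cv_emax = pop_alert$cv_emax, cv_ec50 = pop_alert$cv_ec50
  )
  conc <- simulate_pk(pk_spec, compounds, design$regimen,
                      design$sampling_times)
  n_tot <- design$n_trials * design$n_subjects_per_trial

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(design$seed)

  nt <- length(design$sampling_times)
  mat <- matrix(NA_real_, nrow = nt, ncol = n_tot)
  meta <- data.frame(
    trial_id = rep(seq_len(design$n_trials), each = design$n_subjects_per_trial),
    subject_id = seq_len(n_tot)
  )
  for (i in seq_len(n_tot)) {
    subj <- sample_subject(pop_high, pop_alert, subject_id = i)
    vas <- tryCatch(
      if (endpoint == "feeling_high") simulate_feeling_high(conc, subj$high)
      else simulate_alertness(conc, subj$alert),
      error = function(e) stop(sprintf(
        "subject %d (seed %d) failed: %s", i, design$seed,
        conditionMessage(e)), call. = FALSE)
    )
    mat[, i] <- vas$vas_mm
  }

  subjects <- data.frame(
    trial_id = rep(meta$trial_id, each = nt),
    subject_id = rep(meta$subject_id, each = nt),
    time_h = rep(design$sampling_times, times = n_tot),
    vas_mm = as.vector(mat)
  )
  list(subjects = subjects, summary = summarize_subjects(mat, design$sampling_times),
       conc = conc, endpoint = endpoint, seed = design$seed,
       subject_matrix = mat)
}

#' THC content of legal cannabis cigarettes
#'
#' One cigarette (850 mg at 0.3% THC) carries 2.55 mg THC.
#'
#' @param n_cigarettes number of cigarettes.
#' @return THC dose in mg: `n_cigarettes * 2.55`.
#' @export
cigarette_dose <- function(n_cigarettes) {
  if (any(n_cigarettes < 0)) stop("`n_cigarettes` must be >= 0", call. = FALSE)
  n_cigarettes * 0.85 * 0.003 * 1000
}

#' Dose-response sweep of peak "feeling high" or trough alertness
#'
#' For each dose, runs a virtual study and summarizes the per-subject
#' extreme score: the maximum over the sampling grid for "feeling high",
#' the minimum for alertness.
#'
#' @param doses_mg vector of THC doses, mg (non-empty).
#' @param route `"oral"` or `"inhaled"` (or any [dose_event()] route).
#' @param design_template a [trial_design()] whose regimen is replaced by a
#'   single dose event per swept dose; its seed is offset by the dose index
#'   so doses are independent but reproducible.
#' @param endpoint `"feeling_high"` or `"alertness"`.
#' @param ... passed to [run_virtual_study()].
#' @return data frame `dose_mg`, `route`, `endpoint`, `mean_mm`, `p5_mm`,
#'   `p95_mm`.
#' @export
dose_response_curve <- function(doses_mg, route = "inhaled",
                                design_template = trial_design(
                                  dose_event("inhaled", 10)),
                                endpoint = c("feeling_high", "alertness"),
                                ...) {
  endpoint <- match.arg(endpoint)
  if (length(doses_mg) == 0L) stop("empty dose list", call. = FALSE)
  rows <- lapply(seq_along(doses_mg), function(i) {
    d <- doses_mg[i]
    des <- design_template
    des$regimen <- list(dose_event(route, d))
    des$seed <- design_template$seed + i - 1L
    st <- run_virtual_study(des, endpoint = endpoint, ...)
    ext <- if (endpoint == "feeling_high") {
      apply(st$subject_matrix, 2, max)
    } else {
      apply(st$subject_matrix, 2, min)
    }
    data.frame(dose_mg = d, route = route, endpoint = endpoint,
               mean_mm = mean(ext),
               p5_mm = stats::quantile(ext, 0.05, names = FALSE),
               p95_mm = stats::quantile(ext, 0.95, names = FALSE))
  })
  do.call(rbind, rows)
}
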