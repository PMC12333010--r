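#' Observed VAS series
#'
#' Container for a clinical (or synthetic) mean VAS-time series used for
#' model verification or parameter estimation.
#'
#' @param time_h observation times, h, strictly increasing.
#' @param vas_mm mean VAS scores, mm, in `[0, 100]`.
#' @param sd_mm optional standard deviations, mm.
#' @param n optional number of subjects contributing to the mean.
#' @param endpoint `"feeling_high"` or `"alertness"`.
#' @param trial optional trial label; `dose_mg`, `route` optional metadata.
#' @return An object of class `observed_series`.
#' @export
observed_series <- function(time_h, vas_mm, sd_mm = NULL, n = NA_integer_,
                            endpoint = "feeling_high", trial = NA_character_,
                            dose_mg = NA_real_, route = NA_character_) {
  if (any(diff(time_h) <= 0)) stop("`time_h` must be increasing", call. = FALSE)
  if (any(vas_mm < 0 | vas_mm > 100))
    stop("`vas_mm` must lie in [0, 100]", call. = FALSE)
  df <- data.frame(time_h = time_h, vas_mm = vas_mm)
  if (!is.null(sd_mm)) df$sd_mm <- sd_mm
  structure(df, class = c("observed_series", "data.frame"),
            n = n, endpoint = endpoint, trial = trial,
            dose_mg = dose_mg, route = route)
}

#' @rdname observed_series
#' @param path CSV with columns `time_h`, `vas_mm` and optionally `sd_mm`,
#'   `n`.
#' @param ... passed on to `observed_series()`.
#' @export
read_observed_series <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  observed_series(df$time_h, df$vas_mm, sd_mm = df$sd_mm,
                  n = if (!is.null(df$n)) df$n[1] else NA_integer_, ...)
}

#' Predicted-to-observed extreme-score ratio
#'
#' `R_max`: the ratio of the predicted to the observed extreme VAS score
#' (peak for "feeling high", trough for alertness).
#'
#' @param predicted_extreme,observed_extreme extreme scores, mm;
#'   `observed_extreme` must be positive.
#' @return the ratio `predicted / observed`.
#' @export
rmax_ratio <- function(predicted_extreme, observed_extreme) {
  if (any(observed_extreme <= 0))
    stop("observed extreme must be positive for a ratio", call. = FALSE)
  predicted_extreme / observed_extreme
}

#' Fold-range acceptance check
#'
#' Passes when `1/fold <= ratio <= fold` (bounds inclusive). The
#' verification convention is a 2-fold range for peak "feeling high" and a
#' 1.3-fold range for trough alertness, the tighter band reflecting the
#' nonzero alertness baseline.
#'
#' @param ratio an [rmax_ratio()] value (vectorized).
#' @param fold fold threshold, > 1.
#' @return logical pass flag(s).
#' @export
fold_check <- function(ratio, fold) {
  if (fold <= 1) stop("`fold` must exceed 1", call. = FALSE)
  ratio >= 1 / fold & ratio <= fold
}

#' Fraction of observed points inside the predicted percentile band
#'
#' Linearly interpolates the predicted 5th and 95th percentile envelopes to
#' the observed times and returns the fraction of observed scores falling
#' inside the closed band.
#'
#' @param observed an [observed_series()].
#' @param summary a summary data frame (`time_h`, `p5_mm`, `p95_mm`) from
#'   [run_virtual_study()] / [summarize_subjects()].
#' @return coverage fraction in `[0, 1]`.
#' @export
percentile_coverage <- function(observed, summary) {
  rng <- range(summary$time_h)
  if (any(observed$time_h < rng[1] - 1e-9 | observed$time_h > rng[2] + 1e-9))
    stop("observed times outside the predicted time span (no extrapolation)",
         call. = FALSE)
  p5 <- stats::approx(summary$time_h, summary$p5_mm, xout = observed$time_h,
                      rule = 2)$y
  p95 <- stats::approx(summary$time_h, summary$p95_mm, xout = observed$time_h,
                       rule = 2)$y
  mean(observed$vas_mm >= p5 & observed$vas_mm <= p95)
}

#' Verify one trial against a virtual-study prediction
#'
#' Computes the extreme-score ratio (peak for "feeling high", trough for
#' alertness), the fold-range pass flag at the endpoint's conventional
#' threshold, and the percentile coverage.
#'
#' @param observed an [observed_series()].
#' @param study a [run_virtual_study()] result for the matching design.
#' @param fold fold threshold; defaults to 2 for "feeling high" and 1.3 for
#'   alertness.
#' @return one-row data frame of class `verification_report`: `trial`,
#'   `endpoint`, `predicted_extreme_mm`, `observed_extreme_mm`, `rmax`,
#'   `fold`, `pass`, `coverage`.
#' @export
verify_trial <- function(observed, study, fold = NULL) {
  endpoint <- attr(observed, "endpoint")
  if (is.null(fold)) fold <- if (endpoint == "alertness") 1.3 else 2
  if (endpoint == "alertness") {
    pred <- min(study$summary$mean_mm)
    obs <- min(observed$vas_mm)
  } else {
    pred <- max(study$summary$mean_mm)
    obs <- max(observed$vas_mm)
  }
  r <- rmax_ratio(pred, obs)
  structure(
    data.frame(trial = attr(observed, "trial"), endpoint = endpoint,
               predicted_extreme_mm = pred, observed_extreme_mm = obs,
               rmax = r, fold = fold, pass = fold_check(r, fold),
               coverage = percentile_coverage(observed, study$summary)),
    class = c("verification_report", "data.frame")
  )
}

#' Aggregate a batch of verification reports
#'
#' @param reports list of [verify_trial()] rows (or a combined data frame).
#' @return list with `per_trial` (data frame), `pass_rate` (fraction of
#'   trials passing the fold check) and `mean_coverage`.
#' @export
aggregate_verification <- function(reports) {
  df <- if (is.data.frame(reports)) reports else do.call(rbind, reports)
  list(per_trial = df,
       pass_rate = mean(df$pass),
       mean_coverage = mean(df$coverage))
}
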