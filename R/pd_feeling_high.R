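#' Effect-compartment (biophase) trajectory
#'
#' Solves the first-order effect-site equilibration equation
#' `dC_eff/dt = k_e0 (C_brain(t) - C_eff)` with `C_eff(0) = 0`. The
#' effect-site concentration lags the brain concentration, producing the
#' hysteresis between exposure and subjective effect.
#'
#' Two drivers are supported. When `brain_conc` is a numeric vector on
#' `times`, the trajectory is propagated with the exact exponential-update
#' formula for piecewise-linear forcing (no solver error beyond the linear
#' interpolation of the input between grid points). When `brain_conc` is a
#' function of time, the ODE is integrated with [deSolve::lsoda()] at tight
#' tolerance.
#'
#' @param k_e0 equilibration rate constant, 1/h, positive.
#' @param brain_conc driving brain concentration: numeric vector matching
#'   `times` (uM) or a vectorized function of time.
#' @param times strictly increasing time grid, h.
#' @return numeric vector of effect-site concentrations (uM) on `times`.
#' @export
simulate_effect_site <- function(k_e0, brain_conc, times) {
  if (!is.numeric(k_e0) || length(k_e0) != 1L || k_e0 <= 0 || !is.finite(k_e0))
    stop("`k_e0` must be a positive finite scalar (1/h)", call. = FALSE)
  if (length(times) < 1L || any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)

  if (is.function(brain_conc)) {
    f <- brain_conc
    sol <- deSolve::lsoda(
      y = c(ce = 0), times = times,
      func = function(t, y, p) list(k_e0 * (f(t) - y[[1]])),
      parms = NULL, rtol = 1e-10, atol = 1e-12
    )
    ce <- sol[, "ce"]
  } else {
    u <- as.numeric(brain_conc)
    if (length(u) != length(times))
      stop("`brain_conc` vector must match `times`", call. = FALSE)
    ce <- pwl_first_order(times, u, k_e0)
  }
  pmax(ce, 0)
}

# Exact update of y' = k (u - y) for piecewise-linear u on the grid.
pwl_first_order <- function(times, u, k, y0 = 0) {
  n <- length(times)
  y <- numeric(n)
  y[1] <- y0
  if (n == 1L) return(y)
  h <- diff(times)
  b <- diff(u) / h
  e <- exp(-k * h)
  for (i in seq_len(n - 1L)) {
    a <- u[i]
    # particular solution for linear forcing a + b (t - t_i)
    y[i + 1L] <- (y[i] - a + b[i] / k) * e[i] + a + b[i] * h[i] - b[i] / k
  }
  y
}

#' Sigmoid Emax response for VAS "feeling high"
#'
#' Maps the THC and 11-OH-THC effect-site concentrations to a VAS score
#' through a shared Hill function of their sum:
#' `E_max * S^h / (EC50^h + S^h)` with `S = c_thc_eff + c_11oh_eff`.
#' The two compounds are assumed equipotent (shared `E_max` and `EC50`),
#' so the score depends on the concentrations only through their sum and
#' is bounded above by `E_max`.
#'
#' @param c_thc_eff,c_11oh_eff effect-site concentrations, uM, >= 0
#'   (vectorized).
#' @param p a [feeling_high_params()].
#' @return VAS "feeling high" score(s), mm, in `[0, e_max)`.
#' @examples
#' p <- feeling_high_params()
#' feeling_high_score(p$ec50, 0, p)  # half-maximum: 40 mm
#' @export
feeling_high_score <- function(c_thc_eff, c_11oh_eff, p) {
  stopifnot(inherits(p, "feeling_high_params"))
  if (any(c_thc_eff < 0) || any(c_11oh_eff < 0))
    stop("effect-site concentrations must be non-negative", call. = FALSE)
  s <- c_thc_eff + c_11oh_eff
  sh <- s^p$hill
  p$e_max * sh / (p$ec50^p$hill + sh)
}

#' Simulate the VAS "feeling high" trajectory
#'
#' Runs both effect compartments (THC and 11-OH-THC, each with its own
#' `k_e0`) from the brain concentrations of a [simulate_pk()] output, then
#' applies [feeling_high_score()] pointwise to the summed effect-site
#' concentrations. The pre-dose baseline is 0 mm.
#'
#' @param conc a `conc_series`.
#' @param p a [feeling_high_params()].
#' @param clip clip the reported score to `[0, 100]` mm. The model itself
#'   is bounded by `e_max`; clipping is a reporting convention.
#' @return A `vas_series`: data frame with `time_h`, `vas_mm`; the
#'   effect-site trajectories are kept in the `effect_site` attribute.
#' @export
simulate_feeling_high <- function(conc, p, clip = TRUE) {
  stopifnot(inherits(p, "feeling_high_params"))
  ce_thc <- simulate_effect_site(p$k_e0_thc, conc$thc_brain_uM, conc$time_h)
  ce_oh <- simulate_effect_site(p$k_e0_ohthc, conc$ohthc_brain_uM, conc$time_h)
  vas <- feeling_high_score(ce_thc, ce_oh, p)
  if (clip) vas <- pmin(pmax(vas, 0), 100)
  structure(
    data.frame(time_h = conc$time_h, vas_mm = vas),
    class = c("vas_series", "data.frame"),
    endpoint = "feeling_high", baseline = 0,
    effect_site = data.frame(time_h = conc$time_h,
                             c_thc_eff_uM = ce_thc, c_11oh_eff_uM = ce_oh)
  )
}
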