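#' Fractional inhibition of alertness production
#'
#' Sigmoid Emax inhibition of the zero-order alertness input by the summed
#' THC + 11-OH-THC total brain concentration:
#' `(e_max/100) * S^h / (EC50^h + S^h)` with `S` the summed brain
#' concentration. The stored `e_max` is a percent; this function is the
#' single place where it is converted to a fraction.
#'
#' @param c_thc_brain,c_11oh_brain total brain concentrations, uM, >= 0
#'   (vectorized).
#' @param p an [alertness_params()].
#' @return inhibition fraction(s) in `[0, e_max/100)`.
#' @examples
#' p <- alertness_params()
#' inhibition_fraction(p$ec50, 0, p)  # half-maximum: 0.45
#' @export
inhibition_fraction <- function(c_thc_brain, c_11oh_brain, p) {
  stopifnot(inherits(p, "alertness_params"))
  if (any(c_thc_brain < 0) || any(c_11oh_brain < 0))
    stop("brain concentrations must be non-negative", call. = FALSE)
  s <- c_thc_brain + c_11oh_brain
  sh <- s^p$hill
  (p$e_max / 100) * sh / (p$ec50^p$hill + sh)
}

#' Simulate the VAS "alertness" trajectory (indirect-response model)
#'
#' Turnover model `dV/dt = k_in (1 - E(t)) - k_out V` with
#' `k_in = baseline * k_out` and `E(t)` the [inhibition_fraction()] of the
#' summed brain concentrations. The initial condition is the drug-free
#' steady state `V(0) = baseline`, so a zero-dose simulation holds the
#' baseline exactly; drug exposure depresses the score towards, but never
#' to, `baseline * (1 - e_max/100)`, and the score relaxes back to
#' baseline at rate `k_out` as the brain concentrations decay. There is no
#' effect compartment: the response is driven directly by brain
#' concentrations, the turnover itself supplying the lag.
#'
#' The trajectory is propagated with the exact exponential-update formula
#' for piecewise-linear forcing (the inhibition is evaluated at the grid
#' points and interpolated linearly between them).
#'
#' @param conc a `conc_series`.
#' @param p an [alertness_params()].
#' @param clip clip the reported score to `[0, 100]` mm (reporting
#'   convention; the model is bounded in
#'   `(baseline (1 - e_max/100), baseline]` for these initial conditions).
#' @return A `vas_series` with `time_h`, `vas_mm`;
#'   `attr(, "endpoint") == "alertness"`.
#' @export
simulate_alertness <- function(conc, p, clip = TRUE) {
  stopifnot(inherits(p, "alertness_params"))
  if (any(diff(conc$time_h) <= 0))
    stop("`conc` time grid must be strictly increasing", call. = FALSE)
  e <- inhibition_fraction(conc$thc_brain_uM, conc$ohthc_brain_uM, p)
  k_in <- p$baseline * p$k_out
  # dV/dt = k_out * (u(t) - V) with u = k_in (1 - E) / k_out = baseline (1 - E)
  u <- p$baseline * (1 - e)
  vas <- pwl_first_order(conc$time_h, u, p$k_out, y0 = p$baseline)
  if (clip) vas <- pmin(pmax(vas, 0), 100)
  structure(
    data.frame(time_h = conc$time_h, vas_mm = vas),
    class = c("vas_series", "data.frame"),
    endpoint = "alertness", baseline = p$baseline, k_in = k_in
  )
}

#' Trough of a VAS "alertness" series
#'
#' The minimum score over the observation window and the time at which it
#' occurs; ties are broken to the earliest time. The trough is the extreme
#' excursion used by the verification fold-range statistic for alertness.
#'
#' @param series a `vas_series` (or any data frame with `time_h`,
#'   `vas_mm`).
#' @return named list `t_trough` (h) and `vas_min` (mm).
#' @export
alertness_trough <- function(series) {
  if (is.null(series$time_h) || nrow(series) == 0L)
    stop("empty VAS series", call. = FALSE)
  i <- which.min(series$vas_mm)  # which.min takes the earliest of ties
  list(t_trough = series$time_h[i], vas_min = series$vas_mm[i])
}
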