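#' Compound parameter set
#'
#' Physicochemical and absorption constants for one compound. Fractions
#' absorbed (`f_a`, `lung_f_a`) and first-order absorption rate constants
#' (`k_a`, `lung_k_a`) parameterize the oral and inhaled depot models;
#' `molar_mass` bridges mg doses to micromolar concentrations.
#'
#' @param name compound label.
#' @param molar_mass molar mass, g/mol. Must be positive.
#' @param f_a fraction absorbed from the oral dosage form, in `[0, 1]`.
#' @param k_a oral first-order absorption rate constant, 1/h.
#' @param lung_f_a fraction of an inhaled dose absorbed from the lung,
#'   in `[0, 1]`.
#' @param lung_k_a inhaled (lung) first-order absorption rate constant, 1/h.
#' @return An object of class `compound_params`.
#' @examples
#' thc <- compound_params("THC", 314.46, f_a = 0.45, k_a = 0.7,
#'                        lung_f_a = 0.6, lung_k_a = 200)
#' @export
compound_params <- function(name, molar_mass, f_a = 1, k_a = 1,
                            lung_f_a = 1, lung_k_a = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(molar_mass) || length(molar_mass) != 1L || !is.finite(molar_mass) ||
      molar_mass <= 0) {
    stop("`molar_mass` must be a positive finite number (g/mol)", call. = FALSE)
  }
  for (f in list(f_a = f_a, lung_f_a = lung_f_a)) {
    if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1)
      stop("absorbed fractions must lie in [0, 1]", call. = FALSE)
  }
  if (k_a <= 0 || lung_k_a <= 0)
    stop("absorption rate constants must be positive", call. = FALSE)
  structure(
    list(name = name, molar_mass = molar_mass, f_a = f_a, k_a = k_a,
         lung_f_a = lung_f_a, lung_k_a = lung_k_a),
    class = "compound_params"
  )
}

#' Default THC and 11-OH-THC compound parameters
#'
#' THC absorption constants: `f_a = 0.45`, `k_a = 0.7` 1/h for oral dosing;
#' inhaled dosing defaults to `lung_f_a = 0.6`, `lung_k_a = 200` 1/h (a
#' rapid, high-availability smoking scenario; study-specific lung
#' availabilities span roughly 0.025-0.9 and can be overridden).
#' 11-OH-THC is formed in the liver and never dosed directly, so its
#' absorption fields are placeholders. Molar masses are standard chemistry
#' constants (THC 314.46, 11-OH-THC 330.46 g/mol).
#'
#' @param lung_f_a,lung_k_a inhaled absorption constants for THC.
#' @return A list with elements `thc` and `ohthc`, each `compound_params`.
#' @export
default_compounds <- function(lung_f_a = 0.6, lung_k_a = 200) {
  list(
    thc   = compound_params("THC", 314.46, f_a = 0.45, k_a = 0.7,
                            lung_f_a = lung_f_a, lung_k_a = lung_k_a),
    ohthc = compound_params("11-OH-THC", 330.46, f_a = 1, k_a = 1,
                            lung_f_a = 1, lung_k_a = 1)
  )
}

#' Convert a mass dose to an amount of substance
#'
#' @param amount_mg dose in mg, non-negative.
#' @param molar_mass molar mass in g/mol, positive.
#' @return amount in micromoles: `amount_mg / molar_mass * 1000`.
#' @examples
#' dose_to_amount(2.55, 314.46)  # one cannabis cigarette's THC, in umol
#' @export
dose_to_amount <- function(amount_mg, molar_mass) {
  if (!is.numeric(molar_mass) || any(!is.finite(molar_mass)) || any(molar_mass <= 0))
    stop("`molar_mass` must be positive and finite", call. = FALSE)
  if (any(amount_mg < 0)) stop("`amount_mg` must be non-negative", call. = FALSE)
  amount_mg / molar_mass * 1000
}

#' Pharmacodynamic parameters for the VAS "feeling high" model
#'
#' The direct-effect model drives two first-order effect compartments from
#' the THC and 11-OH-THC brain concentrations and maps their summed
#' effect-site concentration through a shared sigmoid Emax (Hill) function.
#' Defaults are the optimized population values: `k_e0 = 2` 1/h for both
#' compounds, `e_max = 80` mm, `ec50 = 0.21` uM, Hill coefficient 1.8,
#' interindividual CVs of 34% (Emax) and 70% (EC50).
#'
#' @param k_e0_thc,k_e0_ohthc effect-compartment equilibration rate
#'   constants, 1/h. One value is used per compound; the population default
#'   is the same for both.
#' @param e_max maximum VAS increase, mm.
#' @param ec50 summed effect-site concentration giving half-maximal
#'   response, uM.
#' @param hill Hill (slope) coefficient, unitless.
#' @param cv_emax,cv_ec50 interindividual coefficients of variation, percent.
#' @return An object of class `feeling_high_params`.
#' @export
feeling_high_params <- function(k_e0_thc = 2, k_e0_ohthc = 2, e_max = 80,
                                ec50 = 0.21, hill = 1.8,
                                cv_emax = 34, cv_ec50 = 70) {
  vals <- c(k_e0_thc = k_e0_thc, k_e0_ohthc = k_e0_ohthc, e_max = e_max,
            ec50 = ec50, hill = hill)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("feeling-high parameters must be positive and finite", call. = FALSE)
  if (cv_emax < 0 || cv_ec50 < 0) stop("CVs must be >= 0", call. = FALSE)
  structure(
    list(k_e0_thc = k_e0_thc, k_e0_ohthc = k_e0_ohthc, e_max = e_max,
         ec50 = ec50, hill = hill, cv_emax = cv_emax, cv_ec50 = cv_ec50),
    class = "feeling_high_params"
  )
}

#' Pharmacodynamic parameters for the VAS "alertness" model
#'
#' The indirect-response (turnover) model produces alertness at a zero-order
#' rate `k_in = baseline * k_out` and removes it with first-order rate
#' `k_out`; the summed THC + 11-OH-THC brain concentration inhibits
#' production through a sigmoid Emax function. Defaults: `k_out = 1` 1/h,
#' baseline 60 mm, maximum inhibition 90%, `ec50 = 0.23` uM, Hill 1.9,
#' CVs 30%. `e_max` is stored as a percent (matching how it is reported)
#' and converted to a fraction in exactly one place,
#' [inhibition_fraction()].
#'
#' @param k_out first-order loss rate constant, 1/h.
#' @param baseline pre-dose alertness, mm, in `(0, 100]`. Trial
#'   configurations may override it (e.g. to a placebo-arm mean).
#' @param e_max maximum inhibition of the production rate, percent, in
#'   `(0, 100]`.
#' @param ec50 summed brain concentration giving half-maximal inhibition, uM.
#' @param hill Hill coefficient, unitless.
#' @param cv_emax,cv_ec50 interindividual coefficients of variation, percent.
#' @return An object of class `alertness_params`.
#' @export
alertness_params <- function(k_out = 1, baseline = 60, e_max = 90,
                             ec50 = 0.23, hill = 1.9,
                             cv_emax = 30, cv_ec50 = 30) {
  if (k_out <= 0 || !is.finite(k_out)) stop("`k_out` must be positive", call. = FALSE)
  if (baseline <= 0 || baseline > 100)
    stop("`baseline` must lie in (0, 100] mm", call. = FALSE)
  if (e_max <= 0 || e_max > 100)
    stop("`e_max` (percent) must lie in (0, 100]", call. = FALSE)
  if (ec50 <= 0 || hill <= 0) stop("`ec50` and `hill` must be positive", call. = FALSE)
  if (cv_emax < 0 || cv_ec50 < 0) stop("CVs must be >= 0", call. = FALSE)
  structure(
    list(k_out = k_out, baseline = baseline, e_max = e_max, ec50 = ec50,
         hill = hill, cv_emax = cv_emax, cv_ec50 = cv_ec50),
    class = "alertness_params"
  )
}
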