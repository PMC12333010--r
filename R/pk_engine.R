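#' Perfusion-limited PBPK model specification
#'
#' Defines the compartment structure of the whole-body pharmacokinetic model
#' for THC (parent) and 11-OH-THC (metabolite). The fixed topology is:
#' venous blood -> lung -> arterial blood -> tissues -> venous blood, with
#' any number of perfusion-limited tissues. The tissue set must contain
#' `brain` (drives the pharmacodynamic models, as total tissue concentration)
#' and `liver` (site of oral absorption input, parent clearance, metabolite
#' formation and metabolite clearance). Each tissue obeys
#' `V dC/dt = Q (C_art - C / (Kp / BP))`, i.e. tissue uptake is limited by
#' blood flow and the emergent venous blood is in equilibrium with the
#' tissue through the tissue:plasma partition coefficient Kp and the
#' blood:plasma ratio BP.
#'
#' @param volumes named numeric vector of compartment volumes (L); names
#'   must include `venous`, `arterial`, `lung`, and the tissues (at least
#'   `brain` and `liver`).
#' @param flows named numeric vector of tissue blood flows (L/h), one per
#'   tissue (everything in `volumes` except `venous`, `arterial`, `lung`).
#'   Must sum to `cardiac_output` within 1e-6 relative.
#' @param cardiac_output total blood flow through the lung, L/h.
#' @param kp list with elements `thc` and `ohthc`: named numeric vectors of
#'   tissue:plasma partition coefficients for `lung` and each tissue.
#' @param bp named numeric vector `c(thc = , ohthc = )` of blood:plasma
#'   concentration ratios.
#' @param cl_parent parent (THC) hepatic clearance, L/h, referenced to the
#'   liver emergent venous blood concentration.
#' @param fm fraction of parent clearance forming 11-OH-THC, in `[0, 1]`.
#' @param cl_metabolite 11-OH-THC hepatic clearance, L/h, same reference.
#' @param oral_entry compartment receiving oral absorption: `"liver"`
#'   (portal entry; hepatic first-pass extraction and first-pass
#'   11-OH-THC formation emerge from the model) or `"venous"` (systemic
#'   entry, no first-pass; in the limit of fast absorption this reproduces
#'   an IV bolus).
#' @return An object of class `pk_model_spec`.
#' @seealso [default_pk_spec()] for a ready-to-use fixture.
#' @export
pk_model_spec <- function(volumes, flows, cardiac_output, kp, bp,
                          cl_parent, fm, cl_metabolite,
                          oral_entry = c("liver", "venous")) {
  oral_entry <- match.arg(oral_entry)
  blood <- c("venous", "arterial", "lung")
  if (!all(blood %in% names(volumes)))
    stop("`volumes` must name venous, arterial and lung compartments", call. = FALSE)
  tissues <- setdiff(names(volumes), blood)
  if (!all(c("brain", "liver") %in% tissues))
    stop("tissue set must include `brain` and `liver`", call. = FALSE)
  if (!setequal(names(flows), tissues))
    stop("`flows` must name exactly the tissues in `volumes`", call. = FALSE)
  if (any(volumes <= 0) || any(flows <= 0) || cardiac_output <= 0)
    stop("volumes, flows and cardiac output must be positive", call. = FALSE)
  if (abs(sum(flows) - cardiac_output) > 1e-6 * cardiac_output)
    stop("sum of tissue flows must equal cardiac output (1e-6 relative)",
         call. = FALSE)
  for (cmp in c("thc", "ohthc")) {
    need <- c("lung", tissues)
    if (!all(need %in% names(kp[[cmp]])))
      stop(sprintf("kp$%s must name lung and every tissue", cmp), call. = FALSE)
    if (any(kp[[cmp]][need] <= 0)) stop("Kp values must be positive", call. = FALSE)
  }
  if (any(bp[c("thc", "ohthc")] <= 0))
    stop("blood:plasma ratios must be positive", call. = FALSE)
  if (cl_parent <= 0 || cl_metabolite <= 0)
    stop("clearances must be positive", call. = FALSE)
  if (fm < 0 || fm > 1) stop("`fm` must lie in [0, 1]", call. = FALSE)
  structure(
    list(volumes = volumes, flows = flows, cardiac_output = cardiac_output,
         kp = kp, bp = bp, cl_parent = cl_parent, fm = fm,
         cl_metabolite = cl_metabolite, tissues = tissues,
         oral_entry = oral_entry),
    class = "pk_model_spec"
  )
}

#' Default THC / 11-OH-THC PBPK fixture
#'
#' A six-compartment adult parameterization (venous blood, arterial blood,
#' lung, brain, liver, rest-of-body) assembled from standard human
#' physiology (cardiac output 390 L/h; brain 46 L/h / 1.45 L; liver
#' 90 L/h / 1.8 L) and partition/clearance constants chosen to reproduce
#' the qualitative disposition of THC: a brain:plasma total concentration
#' ratio in the 2-5 range after distribution, low oral availability from
#' extensive hepatic first-pass extraction, a large whole-body volume of
#' distribution, and rapid attainment of peak brain concentration after
#' inhalation. These constants are a synthetic, non-authoritative fixture:
#' they are NOT a fitted clinical parameterization, and any quantitative
#' use should supply a study-specific [pk_model_spec()].
#'
#' @return A `pk_model_spec`.
#' @export
default_pk_spec <- function() {
  pk_model_spec(
    volumes = c(venous = 3.7, arterial = 1.7, lung = 0.5,
                brain = 1.45, liver = 1.8, rest = 62),
    flows = c(brain = 46, liver = 90, rest = 254),
    cardiac_output = 390,
    kp = list(
      thc   = c(lung = 1, brain = 3.5, liver = 5, rest = 10),
      ohthc = c(lung = 1, brain = 3.5, liver = 5, rest = 8)
    ),
    bp = c(thc = 0.55, ohthc = 0.55),
    cl_parent = 200, fm = 0.35, cl_metabolite = 150
  )
}

#' Dosing event
#'
#' @param route one of `"iv_bolus"`, `"iv_infusion"`, `"oral"`, `"inhaled"`.
#' @param amount_mg dose, mg of THC, non-negative.
#' @param start_time start of administration, h.
#' @param duration infusion duration, h (must be positive for
#'   `iv_infusion`, 0 otherwise).
#' @return An object of class `dose_event`.
#' @export
dose_event <- function(route, amount_mg, start_time = 0, duration = 0) {
  route <- match.arg(route, c("iv_bolus", "iv_infusion", "oral", "inhaled"))
  if (amount_mg < 0) stop("`amount_mg` must be non-negative", call. = FALSE)
  if (duration < 0) stop("`duration` must be non-negative", call. = FALSE)
  if (route == "iv_infusion" && duration <= 0)
    stop("`iv_infusion` requires a positive `duration`", call. = FALSE)
  if (route != "iv_infusion" && duration != 0)
    stop("`duration` must be 0 for non-infusion routes", call. = FALSE)
  structure(list(route = route, amount_mg = amount_mg,
                 start_time = start_time, duration = duration),
            class = "dose_event")
}

#' First-order absorption rate from a depot
#'
#' Transfer rate from the absorption depot into the systemic circulation
#' for one dosing event at time `t`. Oral and inhaled dosing are
#' first-order in the remaining depot amount; an IV infusion delivers at a
#' constant rate during its window; an IV bolus is an impulse (the returned
#' continuous rate is 0 and the transfer is applied instantaneously by the
#' simulator).
#'
#' @param event a [dose_event()].
#' @param compound a [compound_params()].
#' @param depot_amount current depot amount, umol.
#' @param t time, h.
#' @return absorption rate, umol/h.
#' @export
absorption_rate <- function(event, compound, depot_amount, t) {
  if (t < event$start_time) return(0)
  switch(event$route,
    oral = compound$k_a * depot_amount,
    inhaled = compound$lung_k_a * depot_amount,
    iv_infusion = {
      if (t < event$start_time + event$duration)
        dose_to_amount(event$amount_mg, compound$molar_mass) / event$duration
      else 0
    },
    iv_bolus = 0,
    stop("unknown route", call. = FALSE)
  )
}

pk_state_names <- function(spec) {
  tis <- spec$tissues
  c("p_dep_oral", "p_dep_lung",
    paste0("p_", c("venous", "lung", "arterial", tis)), "p_elim", "p_in",
    paste0("m_", c("venous", "lung", "arterial", tis)), "m_elim", "m_formed")
}

# RHS of the PBPK system; state holds amounts in umol.
pk_derivs <- function(t, state, pars) {
  spec <- pars$spec
  tis <- spec$tissues
  V <- spec$volumes
  Q <- spec$flows
  Qco <- spec$cardiac_output

  out <- numeric(length(state))
  names(out) <- names(state)

  inf_rate <- 0
  for (ev in pars$infusions) {
    if (t >= ev$start_time && t < ev$start_time + ev$duration)
      inf_rate <- inf_rate + ev$rate_umol_h
  }

  for (cmp in c("p", "m")) {
    key <- if (cmp == "p") "thc" else "ohthc"
    bp <- spec$bp[[key]]
    kpv <- spec$kp[[key]]
    cven <- state[[paste0(cmp, "_venous")]] / V[["venous"]]
    cart <- state[[paste0(cmp, "_arterial")]] / V[["arterial"]]
    cvlu <- state[[paste0(cmp, "_lung")]] / (V[["lung"]] * kpv[["lung"]] / bp)
    cvtis <- vapply(tis, function(tn)
      state[[paste0(cmp, "_", tn)]] / (V[[tn]] * kpv[[tn]] / bp), numeric(1))

    out[paste0(cmp, "_venous")] <- sum(Q[tis] * cvtis[tis]) - Qco * cven
    out[paste0(cmp, "_lung")] <- Qco * (cven - cvlu)
    out[paste0(cmp, "_arterial")] <- Qco * (cvlu - cart)
    for (tn in tis)
      out[paste0(cmp, "_", tn)] <- Q[[tn]] * (cart - cvtis[[tn]])

    if (cmp == "p") {
      ka <- pars$compounds$thc$k_a
      lka <- pars$compounds$thc$lung_k_a
      abs_oral <- ka * state[["p_dep_oral"]]
      abs_lung <- lka * state[["p_dep_lung"]]
      cvli <- cvtis[["liver"]]
      elim <- spec$cl_parent * cvli
      out["p_dep_oral"] <- -abs_oral
      out["p_dep_lung"] <- -abs_lung
      oral_target <- if (identical(spec$oral_entry, "venous")) "p_venous" else "p_liver"
      out[oral_target] <- out[oral_target] + abs_oral
      out["p_liver"] <- out["p_liver"] - elim
      out["p_lung"] <- out["p_lung"] + abs_lung
      out["p_venous"] <- out["p_venous"] + inf_rate
      out["p_elim"] <- elim
      out["p_in"] <- abs_oral + abs_lung + inf_rate
      formed <- spec$fm * elim
    } else {
      cvli <- cvtis[["liver"]]
      elim <- spec$cl_metabolite * cvli
      out["m_liver"] <- out["m_liver"] + formed - elim
      out["m_elim"] <- elim
      out["m_formed"] <- formed
    }
  }
  list(out)
}

#' Simulate THC and 11-OH-THC concentration-time profiles
#'
#' Solves the coupled perfusion-limited mass-balance system for parent and
#' metabolite under a dosing regimen and returns venous plasma and total
#' brain tissue concentrations on the requested time grid. Oral doses enter
#' a gut depot (scaled by `f_a`) absorbed first-order into the liver, so
#' first-pass extraction and first-pass 11-OH-THC formation emerge from the
#' model; inhaled doses enter a lung depot (scaled by `lung_f_a`) absorbed
#' first-order into lung blood; IV doses enter venous blood. Integration
#' uses a stiff-capable solver ([deSolve::lsoda()]).
#'
#' @param spec a [pk_model_spec()].
#' @param compounds list with `thc` and `ohthc` [compound_params()].
#' @param regimen list of [dose_event()]s (a single event is accepted).
#' @param times output time grid, h, strictly increasing, starting at or
#'   after 0.
#' @param rtol,atol solver tolerances.
#' @return A `conc_series`: data frame with columns `time_h`,
#'   `thc_plasma_uM`, `thc_brain_uM`, `ohthc_plasma_uM`, `ohthc_brain_uM`,
#'   with the solver state and mass-balance audit in attributes
#'   (`balance`: relative mass-balance error per output time).
#' @export
simulate_pk <- function(spec, compounds, regimen, times,
                        rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(spec, "pk_model_spec"))
  if (inherits(regimen, "dose_event")) regimen <- list(regimen)
  if (length(times) < 2L || any(diff(times) <= 0) || times[1] < 0)
    stop("`times` must be increasing, length >= 2, starting at >= 0",
         call. = FALSE)

  snames <- pk_state_names(spec)
  y0 <- stats::setNames(numeric(length(snames)), snames)

  ev_rows <- list()
  infusions <- list()
  breakpoints <- numeric(0)
  for (ev in regimen) {
    amt <- dose_to_amount(ev$amount_mg, compounds$thc$molar_mass)
    if (ev$route == "iv_bolus") {
      ev_rows[[length(ev_rows) + 1L]] <-
        data.frame(var = c("p_venous", "p_in"), time = ev$start_time,
                   value = amt, method = "add")
    } else if (ev$route == "oral") {
      ev_rows[[length(ev_rows) + 1L]] <-
        data.frame(var = "p_dep_oral", time = ev$start_time,
                   value = amt * compounds$thc$f_a, method = "add")
    } else if (ev$route == "inhaled") {
      ev_rows[[length(ev_rows) + 1L]] <-
        data.frame(var = "p_dep_lung", time = ev$start_time,
                   value = amt * compounds$thc$lung_f_a, method = "add")
    } else if (ev$route == "iv_infusion") {
      infusions[[length(infusions) + 1L]] <-
        list(start_time = ev$start_time, duration = ev$duration,
             rate_umol_h = amt / ev$duration)
      # zero-value events force the solver to land on the window edges
      ev_rows[[length(ev_rows) + 1L]] <-
        data.frame(var = "p_in", time = c(ev$start_time,
                                          ev$start_time + ev$duration),
                   value = 0, method = "add")
    }
  }
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else NULL
  if (!is.null(events)) breakpoints <- unique(events$time)

  t_solver <- sort(unique(c(times, breakpoints)))
  if (t_solver[1] > 0) t_solver <- c(0, t_solver)

  pars <- list(spec = spec, compounds = compounds, infusions = infusions)
  sol <- deSolve::lsoda(
    y = y0, times = t_solver, func = pk_derivs, parms = pars,
    rtol = rtol, atol = atol, maxsteps = 50000,
    events = if (!is.null(events)) list(data = events) else NULL
  )
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop(sprintf("PK solver failed (istate = %d) at t ~ %.4g h",
                 diagn[1], max(sol[, "time"])), call. = FALSE)
  sol <- as.data.frame(sol)

  state_cols <- setdiff(names(sol), "time")
  neg_tol <- 100 * atol
  too_neg <- vapply(sol[state_cols], function(x) min(x), numeric(1))
  if (any(too_neg < -neg_tol)) {
    bad <- names(which.min(too_neg))
    stop(sprintf("negative state beyond tolerance: %s reached %.3g",
                 bad, min(too_neg)), call. = FALSE)
  }
  sol[state_cols] <- lapply(sol[state_cols], function(x) pmax(x, 0))

  keep <- match(times, sol$time)
  if (anyNA(keep)) {
    # match to solver grid within floating tolerance
    keep <- vapply(times, function(tt) which.min(abs(sol$time - tt)), integer(1))
  }
  sol <- sol[keep, , drop = FALSE]

  V <- spec$volumes
  # absorbed into circulation = amount in system (depots excluded) + eliminated
  p_sys <- rowSums(sol[paste0("p_", c("venous", "lung", "arterial",
                                      spec$tissues))])
  m_sys <- rowSums(sol[paste0("m_", c("venous", "lung", "arterial",
                                      spec$tissues))])
  denom_p <- pmax(sol$p_in, atol)
  denom_m <- pmax(sol$m_formed, atol)
  balance <- data.frame(
    time_h = sol$time,
    parent_rel_err = (p_sys + sol$p_elim - sol$p_in) / denom_p,
    metabolite_rel_err = (m_sys + sol$m_elim - sol$m_formed) / denom_m
  )

  out <- data.frame(
    time_h = sol$time,
    thc_plasma_uM = sol$p_venous / V[["venous"]] / spec$bp[["thc"]],
    thc_brain_uM = sol$p_brain / V[["brain"]],
    ohthc_plasma_uM = sol$m_venous / V[["venous"]] / spec$bp[["ohthc"]],
    ohthc_brain_uM = sol$m_brain / V[["brain"]]
  )
  structure(out, class = c("conc_series", "data.frame"),
            balance = balance, spec = spec)
}

#' Write / read concentration series as tidy CSV
#'
#' Long format with unit-suffixed columns: `time_h`, `compound`
#' (`THC` / `11-OH-THC`), `compartment` (`plasma` / `brain`), `conc_uM`.
#'
#' @param x a `conc_series` from [simulate_pk()].
#' @param path output CSV path.
#' @return `write_conc_series()` returns `path` invisibly;
#'   `read_conc_series()` returns a `conc_series` data frame.
#' @export
write_conc_series <- function(x, path) {
  long <- rbind(
    data.frame(time_h = x$time_h, compound = "THC", compartment = "plasma",
               conc_uM = x$thc_plasma_uM),
    data.frame(time_h = x$time_h, compound = "THC", compartment = "brain",
               conc_uM = x$thc_brain_uM),
    data.frame(time_h = x$time_h, compound = "11-OH-THC", compartment = "plasma",
               conc_uM = x$ohthc_plasma_uM),
    data.frame(time_h = x$time_h, compound = "11-OH-THC", compartment = "brain",
               conc_uM = x$ohthc_brain_uM)
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_conc_series
#' @export
read_conc_series <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  tt <- sort(unique(long$time_h))
  pick <- function(cmp, cpt) {
    sub <- long[long$compound == cmp & long$compartment == cpt, ]
    sub$conc_uM[match(tt, sub$time_h)]
  }
  structure(
    data.frame(time_h = tt,
               thc_plasma_uM = pick("THC", "plasma"),
               thc_brain_uM = pick("THC", "brain"),
               ohthc_plasma_uM = pick("11-OH-THC", "plasma"),
               ohthc_brain_uM = pick("11-OH-THC", "brain")),
    class = c("conc_series", "data.frame")
  )
}
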