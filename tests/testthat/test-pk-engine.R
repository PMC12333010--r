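test_that("absorption_rate follows the first-order depot model per route", {
  thc <- fx_compounds$thc
  oral <- dose_event("oral", 10)
  expect_equal(absorption_rate(oral, thc, depot_amount = 10, t = 0.1), 7)
  expect_equal(absorption_rate(oral, thc, depot_amount = 0, t = 0.1), 0)
  expect_equal(absorption_rate(oral, thc, depot_amount = 10, t = -1), 0)

  inh <- dose_event("inhaled", 10)
  expect_equal(absorption_rate(inh, thc, depot_amount = 2, t = 0.1), 400)

  inf <- dose_event("iv_infusion", 3.1446, duration = 0.5)
  expect_equal(absorption_rate(inf, thc, 0, t = 0.25), 10 / 0.5)
  expect_equal(absorption_rate(inf, thc, 0, t = 0.75), 0)
})

test_that("inhaled depot decays as a closed-form first-order exponential", {
  # dose 2.55 mg = 8.109 umol, lung_f_a 0.6 -> initial depot 4.866 umol
  # depot(t) = 4.866 e^(-200 t); >99% absorbed by 0.025 h
  d0 <- dose_to_amount(2.55, 314.46) * 0.6
  expect_equal(d0, 4.866, tolerance = 1e-3)
  expect_lt(d0 * exp(-200 * 0.025), 0.01 * d0)
})

test_that("zero dose yields an identically zero concentration series", {
  cs <- sim_inhaled(0, times = grid_coarse)
  expect_true(all(cs$thc_plasma_uM == 0))
  expect_true(all(cs$thc_brain_uM == 0))
  expect_true(all(cs$ohthc_brain_uM == 0))
})

test_that("mass balance holds within 0.1% on every route at all output times", {
  regimens <- list(
    dose_event("iv_bolus", 5),
    dose_event("iv_infusion", 5, duration = 0.25),
    dose_event("oral", 15),
    dose_event("inhaled", 25.5)
  )
  for (ev in regimens) {
    cs <- simulate_pk(fx_pk, fx_compounds, ev, grid_fast)
    bal <- attr(cs, "balance")
    post <- bal$time_h > ev$start_time  # before dosing the balance is 0/0
    expect_lt(max(abs(bal$parent_rel_err[post])), 1e-3)
    expect_lt(max(abs(bal$metabolite_rel_err[post])), 1e-3)
  }
})

test_that("the PK layer is dose-linear", {
  # tight solver tolerances: the 1e-9 bound measures model linearity, not
  # integration noise (which is ~1e-8 at the default rtol)
  c1 <- sim_inhaled(5, times = grid_coarse, rtol = 1e-11, atol = 1e-13)
  c2 <- sim_inhaled(10, times = grid_coarse, rtol = 1e-11, atol = 1e-13)
  for (col in c("thc_plasma_uM", "thc_brain_uM", "ohthc_brain_uM")) {
    nz <- c1[[col]] > 1e-12
    expect_lt(max(abs(c2[[col]][nz] / c1[[col]][nz] - 2)), 1e-9)
  }
})

test_that("a degenerate one-compartment configuration matches the analytic solution", {
  # all volume in the liver, negligible blood/tissue volumes, fast loop:
  # C(t) = (D/V) exp(-CL/V t)
  V <- 40; CL <- 5; eps_v <- 1e-6; q <- 1e4
  spec1 <- pk_model_spec(
    volumes = c(venous = eps_v, arterial = eps_v, lung = eps_v,
                brain = eps_v, liver = V, rest = eps_v),
    flows = c(brain = 1e-3, liver = q, rest = 1e-3),
    cardiac_output = q + 2e-3,
    kp = list(thc = c(lung = 1, brain = 1, liver = 1, rest = 1),
              ohthc = c(lung = 1, brain = 1, liver = 1, rest = 1)),
    bp = c(thc = 1, ohthc = 1),
    cl_parent = CL, fm = 0.5, cl_metabolite = CL
  )
  D_mg <- 31.446  # 100 umol
  tt <- seq(0, 24, by = 0.5)
  cs <- simulate_pk(spec1, fx_compounds, dose_event("iv_bolus", D_mg), tt,
                    rtol = 1e-10, atol = 1e-12)
  liver_conc <- cs$thc_plasma_uM  # bp = 1; venous == liver conc in this limit
  analytic <- (100 / V) * exp(-CL / V * tt)
  expect_equal(liver_conc[-1], analytic[-1], tolerance = 1e-6)
})

test_that("oral and inhaled dosing converge to the IV bolus as absorption becomes fast", {
  fast <- compound_params("THC", 314.46, f_a = 1, k_a = 1e4,
                          lung_f_a = 1, lung_k_a = 1e4)
  cmp <- list(thc = fast, ohthc = fx_compounds$ohthc)
  spec_ven <- default_pk_spec()
  spec_ven$oral_entry <- "venous"
  tt <- seq(0, 12, by = 0.02)
  auc <- function(cs) sum(diff(tt) * (head(cs$thc_plasma_uM, -1) +
                                      tail(cs$thc_plasma_uM, -1)) / 2)
  iv <- simulate_pk(spec_ven, cmp, dose_event("iv_bolus", 10), tt)
  or <- simulate_pk(spec_ven, cmp, dose_event("oral", 10), tt)
  expect_equal(auc(or), auc(iv), tolerance = 0.02)

  # a lung-entry bolus differs from a venous-entry bolus by a fixed
  # entry-site offset of one circulation pass (~dose / cardiac output),
  # which is small relative to AUC only when clearance is slow compared to
  # cardiac output and the AUC is integrated to elimination completion
  spec_lo <- spec_ven
  spec_lo$cl_parent <- 5
  tt_long <- seq(0, 600, by = 0.5)
  auc_long <- function(cs) sum(diff(tt_long) * (head(cs$thc_plasma_uM, -1) +
                                                tail(cs$thc_plasma_uM, -1)) / 2)
  iv_lo <- simulate_pk(spec_lo, cmp, dose_event("iv_bolus", 10), tt_long)
  inh_lo <- simulate_pk(spec_lo, cmp, dose_event("inhaled", 10), tt_long)
  expect_equal(auc_long(inh_lo), auc_long(iv_lo), tolerance = 0.02)
})

test_that("hepatic first-pass lowers oral availability with portal entry", {
  tt <- seq(0, 48, by = 0.05)
  auc <- function(cs) sum(diff(tt) * (head(cs$thc_plasma_uM, -1) +
                                      tail(cs$thc_plasma_uM, -1)) / 2)
  iv <- simulate_pk(fx_pk, fx_compounds, dose_event("iv_bolus", 10), tt)
  or <- simulate_pk(fx_pk, fx_compounds, dose_event("oral", 10), tt)
  f_oral <- auc(or) / auc(iv)
  expect_lt(f_oral, 0.2)   # f_a 0.45 x hepatic availability
  expect_gt(f_oral, 0.05)
})

test_that("default fixture keeps the brain:plasma ratio between 2 and 5 after distribution", {
  cs <- sim_inhaled(10)
  post <- cs$time_h >= 2  # past the distribution phase
  ratio <- cs$thc_brain_uM[post] / cs$thc_plasma_uM[post]
  expect_true(all(ratio >= 2 & ratio <= 5))
})

test_that("halving solver tolerances leaves the peak brain concentration unchanged to 0.1%", {
  cs1 <- sim_inhaled(10, rtol = 1e-8, atol = 1e-10)
  cs2 <- sim_inhaled(10, rtol = 5e-9, atol = 5e-11)
  expect_equal(max(cs2$thc_brain_uM), max(cs1$thc_brain_uM),
               tolerance = 1e-3)
})

test_that("spec and event validation reject inconsistent inputs", {
  expect_error(dose_event("nasal", 5), "arg")
  expect_error(dose_event("oral", -5), "non-negative")
  expect_error(dose_event("iv_infusion", 5), "duration")
  expect_error(
    pk_model_spec(
      volumes = c(venous = 1, arterial = 1, lung = 1, brain = 1, liver = 1),
      flows = c(brain = 10, liver = 20),
      cardiac_output = 50,  # flows sum to 30
      kp = list(thc = c(lung = 1, brain = 1, liver = 1),
                ohthc = c(lung = 1, brain = 1, liver = 1)),
      bp = c(thc = 1, ohthc = 1), cl_parent = 1, fm = 0.5,
      cl_metabolite = 1),
    "cardiac output")
  expect_error(simulate_pk(fx_pk, fx_compounds, dose_event("oral", 5),
                           c(0, 0, 1)), "increasing")
})

test_that("concentration series round-trip through the tidy CSV schema", {
  cs <- sim_inhaled(10, times = grid_coarse)
  path <- withr::local_tempfile(fileext = ".csv")
  write_conc_series(cs, path)
  back <- read_conc_series(path)
  expect_equal(back$thc_brain_uM, cs$thc_brain_uM)
  expect_equal(back$ohthc_plasma_uM, cs$ohthc_plasma_uM)
  header <- names(utils::read.csv(path, nrows = 1))
  expect_true(all(c("time_h", "compound", "compartment", "conc_uM") %in% header))
})
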