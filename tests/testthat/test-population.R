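test_that("with zero CVs sampled subjects carry the population values exactly", {
  pop_h <- feeling_high_params(cv_emax = 0, cv_ec50 = 0)
  pop_a <- alertness_params(cv_emax = 0, cv_ec50 = 0)
  set.seed(1)
  s <- sample_subject(pop_h, pop_a)
  expect_equal(s$high$e_max, pop_h$e_max)
  expect_equal(s$high$ec50, pop_h$ec50)
  expect_equal(s$alert$e_max, pop_a$e_max)
  expect_equal(s$alert$ec50, pop_a$ec50)
})

test_that("log-normal sampling reproduces the configured CVs and stays positive", {
  n <- 1e5
  set.seed(123)
  ec50_h <- e_max_h <- ec50_a <- e_max_a <- numeric(n)
  for (i in seq_len(n)) {
    s <- sample_subject(fx_high, fx_alert)
    ec50_h[i] <- s$high$ec50; e_max_h[i] <- s$high$e_max
    ec50_a[i] <- s$alert$ec50; e_max_a[i] <- s$alert$e_max
  }
  cv <- function(x) sd(x) / mean(x)
  expect_true(all(c(ec50_h, e_max_h, ec50_a, e_max_a) > 0))
  expect_lt(abs(cv(ec50_h) - 0.70), 0.02)
  expect_lt(abs(cv(e_max_h) - 0.34), 0.02)
  expect_lt(abs(cv(ec50_a) - 0.30), 0.02)
  expect_lt(abs(cv(e_max_a) - 0.30), 0.02)
  # median-anchored: about half of the E_max draws exceed the population value
  expect_lt(abs(mean(e_max_h > fx_high$e_max) - 0.5), 0.01)
})

test_that("a single deterministic subject equals the plain simulation", {
  des <- small_design(dose_event("inhaled", 10), n_trials = 1, n_subj = 1)
  st <- run_virtual_study(
    des, endpoint = "feeling_high",
    pop_high = feeling_high_params(cv_emax = 0, cv_ec50 = 0)
  )
  direct <- simulate_feeling_high(st$conc, fx_high)
  expect_equal(st$summary$mean_mm, direct$vas_mm)
  expect_equal(st$summary$p5_mm, direct$vas_mm)
})

test_that("virtual studies are bit-identical under the same seed", {
  des <- small_design(dose_event("inhaled", 10), seed = 77L)
  a <- run_virtual_study(des, endpoint = "feeling_high")
  b <- run_virtual_study(des, endpoint = "feeling_high")
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$summary, b$summary)
  des2 <- small_design(dose_event("inhaled", 10), seed = 78L)
  c2 <- run_virtual_study(des2, endpoint = "feeling_high")
  expect_false(identical(a$subjects$vas_mm, c2$subjects$vas_mm))
})

test_that("variability propagates through the PD response only", {
  des <- small_design(dose_event("inhaled", 10), n_trials = 4, n_subj = 25)
  st <- run_virtual_study(des, endpoint = "feeling_high")
  band <- st$summary$p95_mm - st$summary$p5_mm
  expect_lt(band[1], 1)                 # common 0 mm baseline at t = 0
  expect_gt(max(band), 5)               # wide band at peak from the CVs
  sa <- run_virtual_study(des, endpoint = "alertness")
  band_a <- sa$summary$p95_mm - sa$summary$p5_mm
  expect_lt(band_a[1], 1)               # common 60 mm baseline
})

test_that("summaries recomputed from the stored per-subject table match exactly", {
  des <- small_design(dose_event("oral", 15), n_trials = 2, n_subj = 8)
  st <- run_virtual_study(des, endpoint = "alertness")
  wide <- matrix(st$subjects$vas_mm, nrow = length(des$sampling_times))
  expect_identical(summarize_subjects(wide, des$sampling_times), st$summary)
  expect_true(all(st$summary$p5_mm <= st$summary$p95_mm))
  expect_true(all(st$summary$mean_mm >= apply(wide, 1, min) &
                  st$summary$mean_mm <= apply(wide, 1, max)))
})

test_that("cigarette arithmetic maps counts to mg of THC", {
  expect_equal(cigarette_dose(1), 2.55)
  expect_equal(cigarette_dose(5), 12.75)
  expect_equal(cigarette_dose(10), 25.5)
  expect_error(cigarette_dose(-1), ">= 0")
})

test_that("dose-response is monotone and ordered between routes", {
  des <- small_design(dose_event("inhaled", 10), n_trials = 1, n_subj = 20,
                      times = seq(0, 12, by = 0.1))
  dr_high <- dose_response_curve(c(5, 15, 50), route = "oral",
                                 design_template = des,
                                 endpoint = "feeling_high")
  expect_true(all(diff(dr_high$mean_mm) > 0))
  expect_gt(dr_high$mean_mm[dr_high$dose_mg == 50],
            dr_high$mean_mm[dr_high$dose_mg == 5])

  dr_alert <- dose_response_curve(c(5, 15, 50), route = "oral",
                                  design_template = des,
                                  endpoint = "alertness")
  expect_true(all(diff(dr_alert$mean_mm) < 0))
  expect_error(dose_response_curve(numeric(0)), "empty")

  # inhaled peaks earlier than oral at the same dose
  cs_in <- sim_inhaled(10)
  cs_or <- sim_oral(10)
  t_in <- cs_in$time_h[which.max(simulate_feeling_high(cs_in, fx_high)$vas_mm)]
  t_or <- cs_or$time_h[which.max(simulate_feeling_high(cs_or, fx_high)$vas_mm)]
  expect_lt(t_in, t_or)
})

test_that("zero dose gives baseline extremes in the dose-response table", {
  des <- small_design(dose_event("inhaled", 10), n_trials = 1, n_subj = 5)
  dr0 <- dose_response_curve(0, route = "inhaled", design_template = des,
                             endpoint = "feeling_high")
  expect_equal(dr0$mean_mm, 0)
  dr0a <- dose_response_curve(0, route = "inhaled", design_template = des,
                              endpoint = "alertness")
  expect_equal(dr0a$mean_mm, 60, tolerance = 1e-6)
})
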