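test_that("power-law antibody waning evaluates the reference clock", {
  am <- antibody_model()
  expect_equal(antibody_at(1, 1, am), 1)          # (42/42)^-1
  expect_equal(antibody_at(1, 43, am), 0.5)       # (84/42)^-1
  expect_equal(antibody_at(2, 0, am), 2 * 42 / 41)
  expect_error(antibody_at(1, -1, am), ">= 0")
  # strictly decreasing for a negative exponent
  tt <- seq(0, 400, by = 0.5)
  expect_true(all(diff(antibody_at(3, tt, am)) < 0))
})

test_that("risk-correlate map clips at zero protection and halves at titre 4", {
  expect_equal(ve_risk_correlate(1), 0)
  expect_equal(ve_risk_correlate(4), 0.5)
  expect_equal(ve_risk_correlate(0.25), 0) # 0.25^-0.5 = 2, clipped by min(.,1)
  expect_error(ve_risk_correlate(0), "positive")
})

test_that("within-host extinction map matches hand-computed values and limits", {
  map <- protection_map("within_host", k = 10)
  expect_equal(ve_within_host(0, map), 0)
  # a = 10, R0 = 10, m = 0.5, k*Ab = 10: (1-e^-0.2)/(1-e^-0.45), hand value
  expect_equal(ve_within_host(1, map), 0.4997703, tolerance = 1e-6)
  expect_equal(ve_within_host(1e12, map), 1, tolerance = 1e-9)
  expect_error(protection_map("within_host", r0 = 1), "exceed 1")
})

test_that("both maps are monotone in antibody on a fine grid", {
  ab <- exp(seq(log(1e-3), log(1e3), length.out = 1000))
  expect_true(all(diff(ve_risk_correlate(ab)) >= 0))
  expect_true(all(diff(ve_within_host(ab, protection_map("within_host"))) >= 0))
})

test_that("susceptibility 1 - VE grows as sqrt of the antibody clock until clipping", {
  am <- antibody_model() # exponent -1
  C <- 25
  tt <- 0:365
  one_minus_ve <- 1 - ve_risk_correlate(antibody_at(C, tt, am))
  expected <- pmin(C^-0.5 * ((tt + 41) / 42)^0.5, 1)
  expect_equal(one_minus_ve, expected, tolerance = 1e-12)
})

test_that("calibration reaches the target mean initial protection for both maps", {
  for (kind in c("risk_correlate", "within_host")) {
    cal <- calibrate_protection_scale(antibody_model(log_c_sd = 1),
                                      protection_map(kind))
    expect_lt(abs(cal$mean_ve - 0.9), 1e-3)
    # idempotent: recalibrating from the calibrated objects moves the scale
    # by less than 1e-6 (relative)
    cal2 <- calibrate_protection_scale(cal$model, cal$map)
    expect_lt(abs(cal2$scale - cal$scale) / abs(cal$scale), 1e-6)
    # the fixed scale no longer hits the target when the SD changes
    m15 <- cal$model; m15$log_c_sd <- 1.5
    expect_gt(abs(mean_ve_lognormal(m15, cal$map, 0) - 0.9), 1e-3)
  }
  expect_error(calibrate_protection_scale(antibody_model(),
                                          protection_map("risk_correlate"),
                                          target_mean_ve = 1),
               "strictly inside")
})

test_that("quadrature population mean VE agrees with Monte Carlo", {
  cal <- calibrate_protection_scale(antibody_model(log_c_sd = 1),
                                    protection_map("risk_correlate"))
  set.seed(42)
  C <- stats::rlnorm(2e5, cal$model$log_c_median, 1)
  for (t in c(0, 180)) {
    mc <- mean(ve_risk_correlate(antibody_at(C, t, cal$model)))
    expect_lt(abs(mean_ve_lognormal(cal$model, cal$map, t) - mc), 3 * 0.3 / sqrt(2e5))
  }
})

test_that("degenerate SD = 0 calibration solves the scalar equation", {
  cal <- calibrate_protection_scale(antibody_model(log_c_sd = 0),
                                    protection_map("risk_correlate"))
  ab0 <- antibody_at(exp(cal$model$log_c_median), 0, cal$model)
  expect_equal(ve_risk_correlate(ab0), 0.9, tolerance = 1e-6)
})

test_that("population mean VE over a cohort handles every protection kind", {
  leaky <- make_cohort(100, 0.5, 0.0025, protection_spec("leaky", 0.5), seed = 1)
  expect_equal(population_mean_ve(leaky, c(0, 100, 365)), rep(0.5, 3))
  beta <- make_cohort(2e5, 0.4, 0.0025,
                      protection_spec("beta", shape1 = 2, shape2 = 2), seed = 2)
  expect_lt(abs(population_mean_ve(beta) - 0.5), 0.005)
  full <- make_cohort(100, 0.5, 0.0025, protection_spec("leaky", 1), seed = 3)
  expect_equal(population_mean_ve(full), 1)
  none <- make_cohort(100, 0, 0.0025, protection_spec("leaky", 0.5), seed = 4)
  expect_error(population_mean_ve(none), "no vaccinated")
  # antibody-derived protection wanes
  cal <- calibrate_protection_scale(antibody_model(log_c_sd = 1),
                                    protection_map("risk_correlate"))
  coh <- make_cohort(5e4, 0.4, 0.0025,
                     protection_spec("antibody", antibody = cal$model),
                     seed = 5)
  ve0 <- population_mean_ve(coh, 0, map = cal$map)
  ve365 <- population_mean_ve(coh, 365, map = cal$map)
  expect_lt(abs(ve0 - 0.9), 0.01)
  expect_lt(ve365, ve0)
})
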