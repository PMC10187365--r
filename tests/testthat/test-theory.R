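test_that("survivor mean hazard: closed forms, delta laws and finite sums", {
  g <- hazard_law("gamma", shape = 0.2, rate = 80)
  # conjugacy closed form at the end of the season
  expect_equal(mean_hazard_surviving(g, 365), 0.2 / 445, tolerance = 1e-12)
  # against direct quadrature of the selection integral
  for (t in c(0, 50, 365)) {
    expect_equal(mean_hazard_surviving(g, t),
                 gamma_mean_hazard_quadrature(0.2, 80, t), tolerance = 1e-8)
  }
  # point mass: no selection, constant hazard
  p <- hazard_law("point", r0 = 0.003)
  expect_equal(mean_hazard_surviving(p, c(0, 100, 365)), rep(0.003, 3))
  # two-point law: brute-force finite sum oracle
  law <- hazard_law("empirical", values = c(0.001, 0.004))
  t <- 200
  num <- 0.5 * (0.001 * exp(-0.001 * t) + 0.004 * exp(-0.004 * t))
  den <- 0.5 * (exp(-0.001 * t) + exp(-0.004 * t))
  expect_equal(mean_hazard_surviving(law, t), num / den, tolerance = 1e-12)
  expect_error(mean_hazard_surviving(g, -1), ">= 0")
})

test_that("survivor variance matches the gamma conjugacy and vanishes for deltas", {
  g <- hazard_law("gamma", shape = 1, rate = 400)
  expect_equal(variance_hazard_surviving(g, 200), 1 / 600^2, tolerance = 1e-12)
  expect_equal(variance_hazard_surviving(hazard_law("point", r0 = 1), 50), 0)
})

test_that("derivatives of the survivor mean equal higher cumulants (Fisher generalization)", {
  laws <- list(
    gamma = hazard_law("gamma", shape = 0.2, rate = 80),
    empirical = hazard_law("empirical", values = c(0.001, 0.003, 0.01),
                           weights = c(0.5, 0.3, 0.2)),
    product = hazard_law("gamma_beta", shape = 1, rate = 400,
                         ve_shape1 = 2, ve_shape2 = 2))
  for (law in laws) {
    for (ord in 1:3) {
      chk <- cgf_identity_check(law, t = 50, order = ord)
      expect_equal(chk$derivative, chk$cumulant,
                   tolerance = c(1e-6, 1e-4, 5e-3)[ord])
    }
  }
  # gamma closed forms at t = 100: the survivor law is Gamma(0.2, 180), so
  # d/dt(-rbar) = 0.2/180^2 and the next order is -2 * 0.2/180^3
  g <- hazard_law("gamma", shape = 0.2, rate = 80)
  chk1 <- cgf_identity_check(g, 100, order = 1)
  expect_equal(chk1$cumulant, 0.2 / 180^2, tolerance = 1e-12)
  chk2 <- cgf_identity_check(g, 100, order = 2)
  expect_equal(chk2$cumulant, -2 * 0.2 / 180^3, tolerance = 1e-10)
  # point mass: all derivatives vanish
  dp <- cgf_identity_check(hazard_law("point", r0 = 0.01), 100, order = 1)
  expect_equal(dp$derivative, 0, tolerance = 1e-12)
  expect_equal(dp$cumulant, 0, tolerance = 1e-15)
})

test_that("time rescaling integrates the force of infection", {
  expect_equal(rescale_time(1, 365), 365)
  expect_equal(rescale_time(0.0025, 100), 0.25)
  foi <- function(t) 0.005 * sin(pi * t / 365)^2
  closed <- function(t) 0.005 * (t / 2 - 365 * sin(2 * pi * t / 365) / (4 * pi))
  for (t in c(50, 200, 365)) {
    expect_equal(rescale_time(foi, t), closed(t), tolerance = 1e-8)
  }
  expect_error(rescale_time(function(t) -1 + 0 * t, 10), "non-negative")
})

test_that("hazard-ratio derivative formula reproduces the hand substitutions", {
  expect_equal(hr_derivative(0, 0, 0.5, 1), 0)
  expect_equal(hr_derivative(0.01, 0, 0.5, 1), -0.01)
  expect_equal(hr_derivative(0, 0.02, 0.5, 1), 0.01)
  expect_error(hr_derivative(0.1, 0.1, 0.5, 0), "positive")
})

test_that("leaky analytic trajectory equals the scaled-gamma closed form", {
  th <- predicted_hr_trajectory(frailty_spec(0.2, 80),
                                protection_spec("leaky", 0.5))
  v <- 0.5
  closed <- (1 - v) * (80 + th$day) / (80 + (1 - v) * th$day)
  expect_equal(th$hr, closed, tolerance = 1e-10)
  expect_equal(th$mve_pred[th$day == 0], 0.5)
})

test_that("homogeneous risk with beta protection starts at VE_NE and drifts up", {
  th <- predicted_hr_trajectory(0.0025,
                                protection_spec("beta", shape1 = 2, shape2 = 2))
  expect_equal(th$hr[1], 0.5, tolerance = 1e-9) # HR(0) = E[1 - VE]
  expect_true(all(diff(th$hr) < 0))             # HR falls, mVE rises
  # t = 0 always reproduces the no-epidemic efficacy
  th2 <- predicted_hr_trajectory(frailty_spec(1, 400),
                                 protection_spec("beta", shape1 = 2, shape2 = 2))
  expect_equal(th2$mve_pred[1], 0.5, tolerance = 1e-9)
})

test_that("finite-difference HR slope agrees with the variance formula", {
  th <- predicted_hr_trajectory(frailty_spec(0.5, 200),
                                protection_spec("beta", shape1 = 2, shape2 = 2),
                                times = c(99, 100, 101))
  fd <- (th$hr[3] - th$hr[1]) / 2
  an <- hr_derivative(th$var_v[2], th$var_u[2], th$rbar_v[2], th$rbar_u[2])
  expect_lt(abs(fd - an), 1e-6)
})

test_that("sign rule matches the moment substitution for reference parameter sets", {
  # strong frailty heterogeneity dominates: HR rises, mVE falls
  expect_equal(sign_rule(0.2, 2, 2), "increase")
  # weak frailty heterogeneity: protection heterogeneity wins, mVE rises
  expect_equal(sign_rule(5, 2, 2), "decrease")
  expect_equal(sign_rule(4, 2, 2), "zero")
  # leaky limit (protection heterogeneity vanishing): HR always rises
  expect_equal(sign_rule(3, 200, 200), "increase")
})

test_that("sign rule agrees with the finite-difference HR'(0) of the trajectory", {
  set.seed(77)
  n_checked <- 0
  while (n_checked < 50) {
    ag <- stats::runif(1, 0.1, 6)
    ab <- stats::runif(1, 0.3, 3)
    bb <- stats::runif(1, 0.3, 3)
    if (abs(ag - ab - bb) < 0.2) next # stay away from the zero boundary
    th <- predicted_hr_trajectory(frailty_spec(ag, ag / 0.0025),
                                  protection_spec("beta", shape1 = ab,
                                                  shape2 = bb),
                                  times = c(0, 2))
    fd_sign <- if (th$hr[2] > th$hr[1]) "increase" else "decrease"
    expect_equal(sign_rule(ag, ab, bb), fd_sign)
    n_checked <- n_checked + 1
  }
})

test_that("unsupported law combinations raise a clear error", {
  expect_error(predicted_hr_trajectory(frailty_spec(1, 400),
                                       protection_spec("all_or_nothing", 0.5)),
               "leaky or beta")
})
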