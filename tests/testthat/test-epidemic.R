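make_leaky_cohort <- function(n, frailty, ve = 0.5, frac = 0.4, seed = 1) {
  make_cohort(n, frac, frailty, protection_spec("leaky", ve), seed = seed)
}

test_that("zero force of infection yields no events, all censored at the horizon", {
  coh <- make_leaky_cohort(500, frailty_spec(0.2, 80))
  ev <- run_epidemic(coh, epidemic_config(foi_baseline = 0), seed = 1)
  expect_equal(sum(ev$event), 0)
  expect_true(all(ev$time == 365))
})

test_that("event tables satisfy their structural invariants", {
  coh <- make_leaky_cohort(20000, frailty_spec(0.2, 80))
  ev <- run_epidemic(coh, epidemic_config(), seed = 2)
  expect_equal(nrow(ev), 20000)                        # one record per agent
  expect_identical(sort(ev$agent_id), coh$agent_id)    # first infection only
  expect_true(all(ev$time > 0 & ev$time <= 365))
  expect_true(all(ev$time[ev$event == 0L] == 365))     # censored at horizon
  expect_true(all(ev$time[ev$event == 1L] == floor(ev$time[ev$event == 1L])))
})

test_that("simulation is byte-reproducible given the seed", {
  coh <- make_leaky_cohort(5000, frailty_spec(1, 400))
  ev1 <- run_epidemic(coh, epidemic_config(), seed = 9)
  ev2 <- run_epidemic(coh, epidemic_config(), seed = 9)
  expect_identical(ev1, ev2)
  cal <- calibrate_protection_scale(antibody_model(log_c_sd = 1),
                                    protection_map("risk_correlate"))
  coh2 <- make_cohort(5000, 0.4, frailty_spec(1, 400),
                      protection_spec("antibody", antibody = cal$model),
                      seed = 3)
  wv1 <- run_epidemic(coh2, epidemic_config(), map = cal$map, seed = 9)
  wv2 <- run_epidemic(coh2, epidemic_config(), map = cal$map, seed = 9)
  expect_identical(wv1, wv2)
})

test_that("homogeneous-risk attack rate matches the exponential closed form", {
  # daily p = 1 - exp(-h) makes 365-day survival exactly exp(-365 h)
  coh <- make_leaky_cohort(1e5, 0.0025, frac = 0)
  ev <- run_epidemic(coh, epidemic_config(), seed = 4)
  expected <- 1 - exp(-0.9125)
  mc_se <- sqrt(expected * (1 - expected) / 1e5)
  expect_lt(abs(mean(ev$event) - expected), 4 * mc_se)
})

test_that("gamma-frailty survival matches the Laplace-transform closed form", {
  # E[exp(-365 q)] = (beta/(beta+365))^alpha for q ~ Gamma(alpha, beta)
  coh <- make_leaky_cohort(1e5, frailty_spec(0.2, 80), frac = 0)
  ev <- run_epidemic(coh, epidemic_config(), seed = 5)
  expected <- (80 / 445)^0.2 # ~ 0.7095
  surv <- 1 - mean(ev$event)
  expect_lt(abs(surv - expected), 4 * sqrt(expected * (1 - expected) / 1e5))
})

test_that("survivor mean frailty follows the gamma conjugacy alpha/(beta+t)", {
  coh <- make_leaky_cohort(2e5, frailty_spec(1, 400), ve = 0.5, frac = 0)
  ev <- run_epidemic(coh, epidemic_config(), seed = 6)
  for (t in c(100, 250, 365)) {
    sel <- ev$time > t | (ev$time == t & ev$event == 0L)
    q_surv <- coh$frailty_q[sel]
    expected <- 1 / (400 + t)
    # survivor frailty is ~ Gamma(1, 400 + t); allow 4 MC standard errors
    mc_se <- sqrt(1 / (400 + t)^2 / sum(sel))
    expect_lt(abs(mean(q_surv) - expected), 4 * mc_se)
  }
})

test_that("doubling the FOI doubles the cumulative log-survival", {
  coh <- make_leaky_cohort(2e5, 1e-3, frac = 0) # q identical across agents
  ev1 <- run_epidemic(coh, epidemic_config(foi_baseline = 1), seed = 7)
  ev2 <- run_epidemic(coh, epidemic_config(foi_baseline = 2), seed = 8)
  s1 <- mean(ev1$event == 0L)
  s2 <- mean(ev2$event == 0L)
  # -log S at the horizon should double: 0.365 -> 0.73
  expect_lt(abs(-log(s2) + 2 * log(s1)), 0.02)
})

test_that("susceptible fraction series are non-increasing steps from 1", {
  coh <- make_leaky_cohort(50000, frailty_spec(0.2, 80))
  ev <- run_epidemic(coh, epidemic_config(), seed = 10)
  sf <- susceptible_fraction_series(ev)
  expect_equal(sf$unvaccinated[1], 1)
  expect_equal(sf$vaccinated[1], 1)
  expect_true(all(diff(sf$unvaccinated) <= 0))
  expect_true(all(diff(sf$vaccinated) <= 0))
  # protection keeps the vaccinated curve above the unvaccinated curve
  expect_true(all(sf$vaccinated[-1] >= sf$unvaccinated[-1]))
  # small worked case: one infection at day 10 in an arm of two agents
  toy <- structure(
    data.frame(agent_id = 1:2, vaccinated = c(0L, 0L),
               time = c(10, 20), event = c(1L, 0L)),
    horizon = 20, class = c("event_table", "data.frame"))
  sf2 <- susceptible_fraction_series(toy)
  expect_equal(sf2$unvaccinated[sf2$day == 9], 1)
  expect_equal(sf2$unvaccinated[sf2$day == 10], 0.5)
  # zero events: constant one
  toy$event <- c(0L, 0L); toy$time <- c(20, 20)
  expect_true(all(susceptible_fraction_series(toy)$unvaccinated == 1))
})
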