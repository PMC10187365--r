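# Independent oracles used across the test files.

# Hand-written Efron partial log-likelihood for a single time category
# (start, end], with the binary vaccine indicator as the only covariate.
# Risk set: agents still at risk when the category opens; events are the
# infections inside the category.  Written directly from the Efron formula
# so it is independent of survival::coxph.
efron_category_loglik <- function(beta, events, start, end) {
  at_risk <- events$time > start
  x <- events$vaccinated[at_risk]
  tt <- events$time[at_risk]
  ee <- events$event[at_risk] == 1 & tt <= end
  ll <- 0
  for (d in sort(unique(tt[ee]))) {
    dead <- ee & tt == d
    in_risk <- tt >= d
    s_risk <- sum(exp(beta * x[in_risk]))
    s_dead <- sum(exp(beta * x[dead]))
    nd <- sum(dead)
    ll <- ll + beta * sum(x[dead]) -
      sum(log(s_risk - (seq_len(nd) - 1) / nd * s_dead))
  }
  ll
}

efron_category_mle <- function(events, start, end) {
  stats::optimize(efron_category_loglik, c(-5, 5), events = events,
                  start = start, end = end, maximum = TRUE,
                  tol = 1e-10)$maximum
}

# Two-arm survival data with piecewise-constant true hazard ratio over the
# given category boundaries: unvaccinated hazard is `base_hazard`
# throughout, vaccinated hazard is base_hazard * hr[k] in category k.
# Continuous event times via inversion of the piecewise cumulative hazard,
# censored at the horizon (= last boundary).
gen_piecewise_hr <- function(n, breaks, hr, base_hazard, frac = 0.4,
                             seed = 1) {
  stopifnot(length(hr) == length(breaks) - 1L)
  horizon <- max(breaks)
  n_vax <- round(frac * n)
  vax <- c(rep(1L, n_vax), rep(0L, n - n_vax))
  set.seed(seed)
  E <- stats::rexp(n)
  widths <- diff(breaks)
  time <- numeric(n)
  for (i in seq_len(n)) {
    rates <- if (vax[i] == 1L) base_hazard * hr else rep(base_hazard, length(hr))
    cumH <- c(0, cumsum(rates * widths))
    if (E[i] >= cumH[length(cumH)]) {
      time[i] <- horizon
    } else {
      k <- findInterval(E[i], cumH)
      time[i] <- breaks[k] + (E[i] - cumH[k]) / rates[k]
    }
  }
  event <- as.integer(time < horizon)
  structure(data.frame(agent_id = seq_len(n), vaccinated = vax,
                       time = time, event = event),
            horizon = horizon, class = c("event_table", "data.frame"))
}

# Event-weighted average of the predicted mVE over a time category: the
# per-category Cox coefficient estimates an event-weighted average of the
# time-varying log hazard ratio, so the theory curve is summarized the
# same way (expected event intensity = arm size x survival x mean hazard).
category_weighted_pred <- function(th, start, end, frac_vax = 0.4) {
  dt <- diff(th$day)
  cum_u <- cumsum(c(0, (th$rbar_u[-1] + th$rbar_u[-nrow(th)]) / 2 * dt))
  cum_v <- cumsum(c(0, (th$rbar_v[-1] + th$rbar_v[-nrow(th)]) / 2 * dt))
  w <- (1 - frac_vax) * exp(-cum_u) * th$rbar_u +
    frac_vax * exp(-cum_v) * th$rbar_v
  sel <- th$day > start & th$day <= end
  sum(w[sel] * th$mve_pred[sel]) / sum(w[sel])
}

# Direct quadrature of the survivor-mean integral (numerator and
# denominator integrated separately) for a gamma density -- the
# independent route against the conjugacy closed form.  For shape < 1 the
# density is singular at 0; substituting r = u^(1/shape) makes the
# integrand bounded there.
gamma_mean_hazard_quadrature <- function(shape, rate, t) {
  int <- function(g) {
    if (shape >= 1) {
      stats::integrate(g, 0, Inf, rel.tol = 1e-10)$value
    } else {
      p <- 1 / shape
      stats::integrate(function(u) g(u^p) * p * u^(p - 1), 0, Inf,
                       rel.tol = 1e-10)$value
    }
  }
  num <- int(function(r) stats::dgamma(r, shape, rate) * exp(-r * t) * r)
  den <- int(function(r) stats::dgamma(r, shape, rate) * exp(-r * t))
  num / den
}
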