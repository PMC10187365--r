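#' Hazard-rate laws for selection theory
#'
#' A `hazard_law` is the time-0 probability law of individual hazard rates
#' in one study arm.  Supported representations:
#'
#' * `"gamma"`: `R ~ Gamma(shape, rate)` — the frailty law of the
#'   unvaccinated arm.
#' * `"scaled_gamma"`: `R = scale * Q`, `Q ~ Gamma(shape, rate)` — gamma
#'   frailty under a constant leaky vaccine with `scale = 1 - v`.
#' * `"gamma_beta"`: `R = Q * (1 - V)` with independent
#'   `Q ~ Gamma(shape, rate)` and `V ~ Beta(ve_shape1, ve_shape2)` — gamma
#'   frailty combined with beta-distributed protection.
#' * `"scaled_beta"`: `R = r0 * (1 - V)`, `V ~ Beta(ve_shape1, ve_shape2)`
#'   — homogeneous risk with beta protection.
#' * `"point"`: all mass at `r0` (a delta function; homogeneous arm).
#' * `"empirical"`: a finite sample / discrete law with `values` and
#'   optional `weights`.
#'
#' @param kind the representation.
#' @param shape,rate gamma parameters.
#' @param scale leaky multiplier in `(0, 1]`.
#' @param ve_shape1,ve_shape2 beta protection parameters
#'   \eqn{\alpha_\beta, \beta_\beta}.
#' @param r0 point mass / homogeneous hazard.
#' @param values,weights discrete support and probabilities.
#' @return an object of class `hazard_law`.
#' @export
#' @examples
#' mean_hazard_surviving(hazard_law("gamma", shape = 0.2, rate = 80), 365)
hazard_law <- function(kind = c("gamma", "scaled_gamma", "gamma_beta",
                                "scaled_beta", "point", "empirical"),
                       shape = NULL, rate = NULL, scale = 1,
                       ve_shape1 = NULL, ve_shape2 = NULL,
                       r0 = NULL, values = NULL, weights = NULL) {
  kind <- match.arg(kind)
  law <- list(kind = kind)
  if (kind %in% c("gamma", "scaled_gamma", "gamma_beta")) {
    if (is.null(shape) || is.null(rate) || shape <= 0 || rate <= 0)
      stop("gamma laws need positive 'shape' and 'rate'")
    law$shape <- shape; law$rate <- rate
  }
  if (kind == "scaled_gamma") {
    if (scale <= 0) stop("'scale' must be positive")
    law$scale <- scale
  }
  if (kind %in% c("gamma_beta", "scaled_beta")) {
    if (is.null(ve_shape1) || is.null(ve_shape2) || ve_shape1 <= 0 ||
        ve_shape2 <= 0)
      stop("beta protection needs positive 've_shape1' and 've_shape2'")
    law$ve_shape1 <- ve_shape1; law$ve_shape2 <- ve_shape2
  }
  if (kind %in% c("scaled_beta", "point")) {
    if (is.null(r0) || r0 < 0) stop("'r0' must be >= 0")
    law$r0 <- r0
  }
  if (kind == "empirical") {
    if (is.null(values) || any(values < 0)) stop("'values' must be >= 0")
    if (is.null(weights)) weights <- rep(1 / length(values), length(values))
    if (length(weights) != length(values) || any(weights < 0))
      stop("'weights' must match 'values' and be >= 0")
    law$values <- values; law$weights <- weights / sum(weights)
  }
  structure(law, class = "hazard_law")
}

# E[R^k e^{-R t}] under a hazard law; the workhorse behind the survivor
# moments.  Gamma integrals are closed-form; the beta mixtures reduce to a
# one-dimensional quadrature over w = 1 - V in (0, 1).
law_exp_moment <- function(law, t, k = 0) {
  stopifnot(inherits(law, "hazard_law"), t >= 0, k >= 0)
  gamma_part <- function(a, b, tt, k) {
    # E[Q^k e^{-Q tt}] for Q ~ Gamma(a, b)
    if (k == 0) return((b / (b + tt))^a)
    prod(a + seq_len(k) - 1) * b^a / (b + tt)^(a + k)
  }
  switch(law$kind,
    gamma = gamma_part(law$shape, law$rate, t, k),
    scaled_gamma = law$scale^k * gamma_part(law$shape, law$rate,
                                            law$scale * t, k),
    point = law$r0^k * exp(-law$r0 * t),
    empirical = sum(law$weights * law$values^k * exp(-law$values * t)),
    gamma_beta = {
      # w = 1 - V ~ Beta(ve_shape2, ve_shape1)
      f <- function(w) stats::dbeta(w, law$ve_shape2, law$ve_shape1) *
        w^k * vapply(w * t, function(s) gamma_part(law$shape, law$rate, s, k),
                     numeric(1))
      stats::integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 0,
                       subdivisions = 500L)$value
    },
    scaled_beta = {
      f <- function(w) stats::dbeta(w, law$ve_shape2, law$ve_shape1) *
        (law$r0 * w)^k * exp(-law$r0 * w * t)
      stats::integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 0,
                       subdivisions = 500L)$value
    })
}

#' Mean hazard among the not-yet-infected
#'
#' The average hazard rate of the survivors at time `t` under selection,
#' \deqn{\bar r(t) = \frac{\int f(r)\, e^{-rt}\, r\, dr}
#'                        {\int f(r)\, e^{-rt}\, dr},}
#' where `f(r)` is the (possibly generalized) density of hazard rates at
#' time 0.  Gamma laws use the conjugacy closed form
#' \eqn{\alpha/(\beta + t)}; mixture laws are evaluated by adaptive
#' quadrature (relative tolerance 1e-10).
#'
#' @param law a [hazard_law()].
#' @param t time(s) >= 0 (days, or rescaled time under a non-constant force
#'   of infection, see [rescale_time()]).
#' @return mean survivor hazard(s), non-negative and non-increasing in `t`.
#' @export
mean_hazard_surviving <- function(law, t) {
  stopifnot(inherits(law, "hazard_law"))
  if (any(t < 0)) stop("'t' must be >= 0")
  vapply(t, function(tt) {
    if (law$kind == "gamma") return(law$shape / (law$rate + tt))
    if (law$kind == "scaled_gamma")
      return(law$scale * law$shape / (law$rate + law$scale * tt))
    if (law$kind == "point") return(law$r0)
    m0 <- law_exp_moment(law, tt, 0)
    if (m0 <= 0) stop("survivor mass vanished: divergent selection integral")
    law_exp_moment(law, tt, 1) / m0
  }, numeric(1))
}

#' Variance of hazard rates among the not-yet-infected
#'
#' @inheritParams mean_hazard_surviving
#' @return survivor hazard variance(s) (gamma closed form
#'   \eqn{\alpha/(\beta + t)^2}; quadrature otherwise).
#' @export
variance_hazard_surviving <- function(law, t) {
  stopifnot(inherits(law, "hazard_law"))
  vapply(t, function(tt) {
    if (law$kind == "gamma") return(law$shape / (law$rate + tt)^2)
    if (law$kind == "scaled_gamma")
      return(law$scale^2 * law$shape / (law$rate + law$scale * tt)^2)
    if (law$kind == "point") return(0)
    m0 <- law_exp_moment(law, tt, 0)
    m1 <- law_exp_moment(law, tt, 1) / m0
    law_exp_moment(law, tt, 2) / m0 - m1^2
  }, numeric(1))
}

# Cumulant of -R among survivors at time t, orders 2..4 (order 1 is -rbar).
survivor_cumulant <- function(law, t, order) {
  stopifnot(order %in% 2:4)
  if (order == 2) return(variance_hazard_surviving(law, t))
  m0 <- law_exp_moment(law, t, 0)
  m <- vapply(1:4, function(k) law_exp_moment(law, t, k) / m0, numeric(1))
  mu2 <- m[2] - m[1]^2
  mu3 <- m[3] - 3 * m[1] * m[2] + 2 * m[1]^3
  if (order == 3) return(-mu3) # third cumulant of -R
  mu4 <- m[4] - 4 * m[1] * m[3] + 6 * m[1]^2 * m[2] - 3 * m[1]^4
  mu4 - 3 * mu2^2              # fourth cumulant (sign-even)
}

#' Check the cumulant-generating-function selection identity
#'
#' With `M(t)` and `K(t) = ln M(t)` the moment and cumulant generating
#' functions of `-R`, the survivor mean obeys \eqn{-\bar r(t) = K'(t)}, so
#' the n-th derivative of \eqn{-\bar r(t)} equals the (n+1)-th cumulant of
#' `-R` among the survivors — for n = 1, the survivor variance (a
#' generalization of Fisher's fundamental theorem of natural selection to
#' higher cumulants).  This helper returns both sides: the n-th numerical
#' derivative (central differences) of \eqn{-\bar r} and the (n+1)-th
#' survivor cumulant.
#'
#' @param law a [hazard_law()].
#' @param t evaluation time.
#' @param order derivative order n in 1..3.
#' @param h finite-difference step (default scales with `t` and `order`).
#' @return list with `derivative` and `cumulant`.
#' @export
#' @examples
#' chk <- cgf_identity_check(hazard_law("gamma", shape = 0.2, rate = 80), 50)
#' chk$derivative - chk$cumulant # ~ 0
cgf_identity_check <- function(law, t, order = 1, h = NULL) {
  stopifnot(order %in% 1:3, t >= 0)
  if (is.null(h))
    h <- c(`1` = 1e-4, `2` = 0.05, `3` = 0.5)[[as.character(order)]] *
      max(1, t)
  f <- function(tt) -mean_hazard_surviving(law, max(tt, 0))
  d <- switch(order,
    (f(t + h) - f(t - h)) / (2 * h),
    (f(t + h) - 2 * f(t) + f(t - h)) / h^2,
    (f(t + 2 * h) - 2 * f(t + h) + 2 * f(t - h) - f(t - 2 * h)) / (2 * h^3))
  list(derivative = d, cumulant = survivor_cumulant(law, t, order + 1))
}

#' Rescaled time under a time-varying force of infection
#'
#' With individual hazards `r_i = FOI(t) * q_i`, the selection identities
#' hold in the transformed time \eqn{s(t) = \int_0^t FOI(\tau) d\tau}
#' applied to the law of the relative hazards `q_i`.
#'
#' @param foi a non-negative function of time, or a single non-negative
#'   constant.
#' @param t time(s) >= 0.
#' @return rescaled time(s) `s(t)`; for constant FOI `c`, exactly `c * t`.
#' @export
#' @examples
#' rescale_time(0.0025, 100) # 0.25
rescale_time <- function(foi, t) {
  if (any(t < 0)) stop("'t' must be >= 0")
  if (is.numeric(foi)) {
    if (length(foi) != 1L || foi < 0) stop("constant FOI must be a single value >= 0")
    return(foi * t)
  }
  stopifnot(is.function(foi))
  vapply(t, function(tt) {
    if (tt == 0) return(0)
    probe <- foi(seq(0, tt, length.out = 101))
    if (any(probe < 0)) stop("FOI must be non-negative")
    stats::integrate(foi, 0, tt, rel.tol = 1e-10, abs.tol = 0,
                     subdivisions = 500L)$value
  }, numeric(1))
}

#' Rate of change of the hazard ratio under selection
#'
#' Applying the quotient rule to `HR(t) = rbar_v / rbar_u` and the Fisher
#' identity (the derivative of each arm's mean survivor hazard is minus its
#' survivor variance) gives
#' \deqn{\frac{d}{dt} HR = \frac{-\sigma_v^2\, \bar r_u +
#'       \sigma_u^2\, \bar r_v}{\bar r_u^2}.}
#' Vaccinated-arm heterogeneity pushes HR down (measured VE up);
#' unvaccinated-arm heterogeneity pushes HR up (measured VE down).
#'
#' @param sigma_v2,sigma_u2 survivor hazard variances (>= 0) in the
#'   vaccinated / unvaccinated arm.
#' @param rbar_v,rbar_u survivor mean hazards; `rbar_u > 0`.
#' @return dHR/dt.
#' @export
#' @examples
#' hr_derivative(0.01, 0, rbar_v = 0.5, rbar_u = 1) # -0.01
hr_derivative <- function(sigma_v2, sigma_u2, rbar_v, rbar_u) {
  if (any(rbar_u <= 0)) stop("'rbar_u' must be positive")
  if (any(sigma_v2 < 0) || any(sigma_u2 < 0)) stop("variances must be >= 0")
  (-sigma_v2 * rbar_u + sigma_u2 * rbar_v) / rbar_u^2
}

#' Initial direction of the hazard ratio under competing heterogeneities
#'
#' For independent Gamma(\eqn{\alpha_\gamma, \beta_\gamma}) frailty and
#' Beta(\eqn{\alpha_\beta, \beta_\beta}) protection, substituting the
#' time-0 moments into the hazard-ratio derivative ([hr_derivative()])
#' collapses to a parameter count:
#' \deqn{\mathrm{sign}\, HR'(0) = \mathrm{sign}(\alpha_\beta +
#'       \beta_\beta - \alpha_\gamma).}
#' (Writing \eqn{w = 1 - VE}, the sign of \eqn{HR'(0)} is the sign of
#' \eqn{V_q E[w(1-w)] - \mu_q^2 V_w}; for gamma frailty
#' \eqn{V_q/\mu_q^2 = 1/\alpha_\gamma} and for beta protection
#' \eqn{E[w(1-w)]/V_w = \alpha_\beta + \beta_\beta}, and the boundary is
#' \eqn{\alpha_\gamma = \alpha_\beta + \beta_\beta}.)  A positive sign —
#' strong frailty heterogeneity (small \eqn{\alpha_\gamma}) or weak
#' protection heterogeneity (large \eqn{\alpha_\beta + \beta_\beta}) —
#' means HR rises, i.e. measured VE initially declines (apparent waning);
#' negative means measured VE initially rises.
#'
#' @param alpha_gamma gamma frailty shape (> 0).
#' @param alpha_beta,beta_beta beta protection parameters (> 0).
#' @return `"increase"`, `"decrease"` or `"zero"` — the direction of
#'   `HR'(0)`.
#' @export
#' @examples
#' sign_rule(0.2, 2, 2) # "increase": HR rises, mVE falls (frailty wins)
#' sign_rule(5, 2, 2)   # "decrease": mVE rises initially
sign_rule <- function(alpha_gamma, alpha_beta, beta_beta) {
  stopifnot(alpha_gamma > 0, alpha_beta > 0, beta_beta > 0)
  d <- alpha_beta + beta_beta - alpha_gamma
  if (d > 0) "increase" else if (d < 0) "decrease" else "zero"
}

#' Analytic hazard-ratio trajectory under selection
#'
#' Computes the survivor mean hazards, variances, hazard ratio and
#' predicted measured VE (`1 - HR`) on a daily grid, from the time-0
#' hazard laws of the two arms.  Assumes individual hazards are constant
#' in time (no waning) and frailty independent of protection.  Supported
#' combinations: gamma or homogeneous frailty crossed with constant leaky
#' or beta-distributed protection.
#'
#' @param frailty a [frailty_spec()], or a single positive number for a
#'   homogeneous daily hazard.
#' @param protection a [protection_spec()] of kind `"leaky"` or `"beta"`.
#' @param foi constant force-of-infection multiplier (default 1; a common
#'   constant cancels from HR but scales the reported hazards).
#' @param horizon last day of the grid (default 365).
#' @param times evaluation days (default `0:horizon`).
#' @return an object of class `theory_prediction`: a `data.frame` with
#'   columns `day`, `rbar_u`, `rbar_v`, `var_u`, `var_v`, `hr`,
#'   `mve_pred`, with the input laws attached as attributes.  At `t = 0`
#'   the predicted mVE equals the no-epidemic mean efficacy.
#' @export
#' @examples
#' th <- predicted_hr_trajectory(frailty_spec(0.2, 80),
#'                               protection_spec("leaky", 0.5))
#' th$mve_pred[c(1, 366)] # 0.5 at day 0, ~0.15 at day 365
predicted_hr_trajectory <- function(frailty, protection, foi = 1,
                                    horizon = 365, times = 0:horizon) {
  stopifnot(inherits(protection, "protection_spec"))
  if (!is.numeric(foi) || length(foi) != 1L || foi <= 0)
    stop("'foi' must be a positive constant")
  homog <- is.numeric(frailty) && length(frailty) == 1L
  if (!homog) stopifnot(inherits(frailty, "frailty_spec"))

  law_u <- if (homog) hazard_law("point", r0 = foi * frailty)
           else hazard_law("gamma", shape = frailty$shape,
                           rate = frailty$rate / foi)
  law_v <- if (protection$kind == "leaky") {
    v <- protection$ve_level
    if (homog) hazard_law("point", r0 = foi * frailty * (1 - v))
    else if (v < 1) hazard_law("scaled_gamma", shape = frailty$shape,
                               rate = frailty$rate / foi, scale = 1 - v)
    else hazard_law("point", r0 = 0)
  } else if (protection$kind == "beta") {
    if (homog) hazard_law("scaled_beta", r0 = foi * frailty,
                          ve_shape1 = protection$shape1,
                          ve_shape2 = protection$shape2)
    else hazard_law("gamma_beta", shape = frailty$shape,
                    rate = frailty$rate / foi,
                    ve_shape1 = protection$shape1,
                    ve_shape2 = protection$shape2)
  } else {
    stop("analytic trajectories support constant leaky or beta protection only")
  }

  rbar_u <- mean_hazard_surviving(law_u, times)
  rbar_v <- mean_hazard_surviving(law_v, times)
  var_u <- variance_hazard_surviving(law_u, times)
  var_v <- variance_hazard_surviving(law_v, times)
  hr <- rbar_v / rbar_u
  structure(
    data.frame(day = times, rbar_u = rbar_u, rbar_v = rbar_v,
               var_u = var_u, var_v = var_v, hr = hr, mve_pred = 1 - hr),
    law_u = law_u, law_v = law_v,
    class = c("theory_prediction", "data.frame")
  )
}

#' @export
print.theory_prediction <- function(x, ...) {
  cat(sprintf(
    "Analytic selection trajectory over %d days: mVE %.3f at day 0 -> %.3f at day %g\n",
    max(x$day), x$mve_pred[1L], x$mve_pred[nrow(x)], max(x$day)))
  invisible(x)
}
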