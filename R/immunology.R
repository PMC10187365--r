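#' Power-law antibody waning model
#'
#' Antibody titre for an individual with scale \eqn{C} wanes as a power law
#' of study time,
#' \deqn{Ab(t) = C \left[ (t + t_0) / t_s \right]^{p},}
#' with offset \eqn{t_0 = 41} days, scale \eqn{t_s = 42} days and exponent
#' \eqn{p = -1} by default (relatively fast waning).  \eqn{C} varies across
#' vaccinees on a lognormal law with `log_c_sd` natural-log standard
#' deviation (plausible range 0.75-1.5).  All vaccinees are assumed fully
#' vaccinated before the study starts, so study day 0 is the same point on
#' every individual's waning curve.
#'
#' @param log_c_sd natural-log SD of the antibody scale `C` (>= 0).
#' @param log_c_median natural-log median of `C` (calibrated, see
#'   [calibrate_protection_scale()]).
#' @param waning_exponent power-law exponent (default -1).
#' @param time_offset,time_scale clock constants in days (defaults 41, 42).
#' @return an object of class `antibody_model`.
#' @export
#' @examples
#' am <- antibody_model(log_c_sd = 1)
#' antibody_at(1, 43, am) # half the day-1 titre
antibody_model <- function(log_c_sd = 1, log_c_median = 0,
                           waning_exponent = -1,
                           time_offset = 41, time_scale = 42) {
  if (!is.numeric(log_c_sd) || log_c_sd < 0) stop("'log_c_sd' must be >= 0")
  if (time_scale <= 0) stop("'time_scale' must be positive")
  structure(list(log_c_sd = log_c_sd, log_c_median = log_c_median,
                 waning_exponent = waning_exponent,
                 time_offset = time_offset, time_scale = time_scale),
            class = "antibody_model")
}

#' @export
print.antibody_model <- function(x, ...) {
  cat(sprintf(
    "Antibody waning Ab(t) = C [(t + %g)/%g]^%g, ln C ~ N(%.4g, sd %.3g)\n",
    x$time_offset, x$time_scale, x$waning_exponent, x$log_c_median, x$log_c_sd))
  invisible(x)
}

#' Antibody titre at a study time
#'
#' @param C individual antibody scale(s), positive.
#' @param t study time in days (>= 0); `C` and `t` recycle as usual.
#' @param model an [antibody_model()].
#' @return antibody titre(s), positive; strictly decreasing in `t` for a
#'   negative waning exponent.
#' @export
antibody_at <- function(C, t, model = antibody_model()) {
  stopifnot(inherits(model, "antibody_model"))
  if (any(t < 0)) stop("'t' must be >= 0")
  if (any(C <= 0, na.rm = TRUE)) stop("'C' must be positive")
  C * ((t + model$time_offset) / model$time_scale)^model$waning_exponent
}

#' Antibody-to-protection maps
#'
#' Two maps from an individual's current antibody titre `Ab` to their
#' instantaneous vaccine protection VE:
#'
#' * **risk-correlate** (`ve_risk_correlate()`):
#'   \eqn{1 - VE = \min(Ab^{e}, 1)} with conversion exponent `e = -0.5` by
#'   default (`-0.35` is the weaker, unadjusted alternative estimated from
#'   HAI titres alone).
#' * **within-host stochastic extinction** (`ve_within_host()`): the
#'   closed-form establishment probability of an inoculum of `m = 0.5`
#'   expected founder infections when virions die at rate `a = 10`,
#'   replicate with cell-level basic reproduction number `R0 = 10`, and are
#'   neutralized proportionally to the scaled titre `k * Ab`:
#'   \deqn{1 - VE = \max\left\{ \frac{1 - \exp(m/R_0 - m\,a/(a + k\,Ab))}
#'     {1 - \exp(m/R_0 - m)}, 0 \right\}.}
#'
#' Both maps are non-decreasing in `Ab` and return VE in `[0, 1]`.
#'
#' @param kind `"risk_correlate"` or `"within_host"`.
#' @param exponent risk-correlate conversion exponent (default -0.5).
#' @param a virion death rate per unit time (default 10).
#' @param r0 within-host, between-cell basic reproduction number (> 1,
#'   default 10).
#' @param m expected number of founder virions succeeding absent antibody
#'   (default 0.5).
#' @param k antibody scaling constant (calibrated, see
#'   [calibrate_protection_scale()]).
#' @return a `protection_map` object.
#' @export
#' @examples
#' pm <- protection_map("risk_correlate")
#' ve_from_antibody(4, pm) # 0.5
protection_map <- function(kind = c("risk_correlate", "within_host"),
                           exponent = -0.5, a = 10, r0 = 10, m = 0.5, k = 1) {
  kind <- match.arg(kind)
  if (kind == "within_host") {
    if (r0 <= 1) stop("'r0' must exceed 1 (otherwise the establishment ",
                      "probability denominator is non-positive)")
    if (a <= 0 || m <= 0 || k <= 0) stop("'a', 'm' and 'k' must be positive")
  }
  structure(list(kind = kind, exponent = exponent, a = a, r0 = r0, m = m, k = k),
            class = "protection_map")
}

#' @export
print.protection_map <- function(x, ...) {
  if (x$kind == "risk_correlate")
    cat(sprintf("Risk-correlate map: 1 - VE = min(Ab^%g, 1)\n", x$exponent))
  else
    cat(sprintf(
      "Within-host extinction map: a = %g, R0 = %g, m = %g, k = %.4g\n",
      x$a, x$r0, x$m, x$k))
  invisible(x)
}

#' @rdname protection_map
#' @param ab antibody titre(s); positive for the risk-correlate map,
#'   non-negative for the within-host map.
#' @export
ve_risk_correlate <- function(ab, exponent = -0.5) {
  if (any(ab <= 0, na.rm = TRUE)) stop("'ab' must be positive")
  1 - pmin(ab^exponent, 1)
}

#' @rdname protection_map
#' @param map a `protection_map` of kind `"within_host"` (or its parameters
#'   via `a`, `r0`, `m`, `k` defaults).
#' @export
ve_within_host <- function(ab, map = protection_map("within_host")) {
  stopifnot(inherits(map, "protection_map"))
  if (map$r0 <= 1) stop("'r0' must exceed 1")
  if (any(ab < 0, na.rm = TRUE)) stop("'ab' must be >= 0")
  num <- 1 - exp(map$m / map$r0 - map$m * map$a / (map$a + map$k * ab))
  den <- 1 - exp(map$m / map$r0 - map$m)
  1 - pmax(num / den, 0)
}

#' @rdname protection_map
#' @export
ve_from_antibody <- function(ab, map) {
  stopifnot(inherits(map, "protection_map"))
  if (map$kind == "risk_correlate") ve_risk_correlate(ab, map$exponent)
  else ve_within_host(ab, map)
}

#' Population mean antibody-derived protection (no epidemic)
#'
#' The mean VE at study time `t` over the lognormal antibody-scale
#' population, computed deterministically by Gauss-Hermite quadrature over
#' \eqn{\ln C} (64 nodes by default) — the no-epidemic efficacy VE_NE of
#' an antibody-derived protection law without sampling a cohort.
#'
#' @param model an [antibody_model()].
#' @param map a [protection_map()].
#' @param t study time in days.
#' @param nodes number of Gauss-Hermite nodes.
#' @return mean VE in `[0, 1]`.
#' @export
mean_ve_lognormal <- function(model, map, t = 0, nodes = 64L) {
  stopifnot(inherits(model, "antibody_model"), inherits(map, "protection_map"))
  wane <- ((t + model$time_offset) / model$time_scale)^model$waning_exponent
  if (model$log_c_sd == 0) {
    return(ve_from_antibody(exp(model$log_c_median) * wane, map))
  }
  gh <- pracma::gaussHermite(nodes)
  logC <- model$log_c_median + sqrt(2) * model$log_c_sd * gh$x
  sum(gh$w * ve_from_antibody(exp(logC) * wane, map)) / sqrt(pi)
}

#' Calibrate the antibody-protection scale
#'
#' Adjusts the free scale of a protection map so that the population mean
#' initial protection (over the lognormal antibody-scale distribution, by
#' Gauss-Hermite quadrature over \eqn{\ln C}) equals `target_mean_ve` —
#' by convention approximately 90% at `log_c_sd = 1`.  For the
#' risk-correlate map the knob is the lognormal location `log_c_median`;
#' for the within-host map `log_c_median` is pinned at 0 (it is confounded
#' with `k`) and the knob is the scaling constant `k`.  The calibrated
#' scale is then held fixed as `log_c_sd` varies, so the realized mean
#' initial VE drifts slightly away from the target at other SD levels.
#'
#' @param model an [antibody_model()] (conventionally with `log_c_sd = 1`).
#' @param map a [protection_map()].
#' @param target_mean_ve target population mean VE at `t = 0`, in (0, 1).
#' @param tol calibration tolerance on the achieved mean VE.
#' @return a list of class `ve_calibration`: `model` and `map` updated with
#'   the calibrated scale, `scale` (the calibrated `log_c_median` or `k`),
#'   and `mean_ve` (achieved mean initial VE).
#' @export
#' @examples
#' cal <- calibrate_protection_scale(antibody_model(log_c_sd = 1),
#'                                   protection_map("risk_correlate"))
#' cal$mean_ve # 0.900 to within 1e-6
calibrate_protection_scale <- function(model, map, target_mean_ve = 0.9,
                                       tol = 1e-9) {
  stopifnot(inherits(model, "antibody_model"), inherits(map, "protection_map"))
  if (!is.numeric(target_mean_ve) || target_mean_ve <= 0 || target_mean_ve >= 1)
    stop("'target_mean_ve' must lie strictly inside (0, 1)")

  if (map$kind == "risk_correlate") {
    f <- function(mu) {
      m2 <- model; m2$log_c_median <- mu
      mean_ve_lognormal(m2, map) - target_mean_ve
    }
    lo <- -30; hi <- 60
    if (f(hi) < 0 || f(lo) > 0)
      stop("calibration target unattainable for the risk-correlate map")
    mu <- stats::uniroot(f, c(lo, hi), tol = tol)$root
    model$log_c_median <- mu
    scale <- mu
  } else {
    model$log_c_median <- 0
    f <- function(logk) {
      m2 <- map; m2$k <- exp(logk)
      mean_ve_lognormal(model, m2) - target_mean_ve
    }
    lo <- -30; hi <- 30
    if (f(hi) < 0 || f(lo) > 0)
      stop("calibration target unattainable for the within-host map")
    logk <- stats::uniroot(f, c(lo, hi), tol = tol)$root
    map$k <- exp(logk)
    scale <- map$k
  }
  structure(list(model = model, map = map, scale = scale,
                 mean_ve = mean_ve_lognormal(model, map)),
            class = "ve_calibration")
}

#' @export
print.ve_calibration <- function(x, ...) {
  cat(sprintf("Calibrated %s scale: %.6g (mean initial VE %.4f)\n",
              x$map$kind, x$scale, x$mean_ve))
  invisible(x)
}

#' Population mean protection in the absence of an epidemic (VE_NE)
#'
#' The mean individual protection over the vaccinated arm at study time
#' `t`, with no selection by infection — the reference level against which
#' measured VE is compared.  For constant (leaky / all-or-nothing / beta)
#' protection this is time-invariant; for antibody-derived protection it
#' wanes with the antibody titre.
#'
#' @param cohort a [make_cohort()] cohort with at least one vaccinated
#'   agent.
#' @param t study time(s) in days.
#' @param map a [protection_map()] (required for antibody-derived
#'   protection).
#' @return mean VE in `[0, 1]`, one value per element of `t`.
#' @export
population_mean_ve <- function(cohort, t = 0, map = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (!any(cohort$vaccinated == 1L))
    stop("cohort has no vaccinated agents")
  vapply(t, function(tt) mean(protection_at(cohort, tt, map)), numeric(1))
}
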