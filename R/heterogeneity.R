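#' Gamma frailty specification
#'
#' Baseline (pre-vaccination) susceptibility is heterogeneous: each agent
#' carries a relative daily hazard \eqn{q_i} drawn from a gamma distribution
#' Gamma(shape \eqn{\alpha_\gamma}, rate \eqn{\beta_\gamma}), shared by the
#' vaccinated and unvaccinated arms.  The mean is \eqn{\alpha/\beta} (per
#' day) and the coefficient of variation is \eqn{\alpha^{-1/2}}.
#'
#' @param shape gamma shape \eqn{\alpha_\gamma > 0}.
#' @param rate gamma rate \eqn{\beta_\gamma > 0} (per day).
#' @return an object of class `frailty_spec` with elements `shape`, `rate`,
#'   `mean` and `cov` (the coefficient of variation, exactly `shape^-0.5`).
#' @seealso [frailty_from_cov()] to parameterize by CoV and mean,
#'   [sample_frailty()], [make_cohort()]
#' @export
#' @examples
#' fs <- frailty_spec(0.2, 80)
#' fs$mean # 0.0025 / day
#' fs$cov  # 2.236
frailty_spec <- function(shape, rate) {
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) || shape <= 0)
    stop("'shape' must be a positive number")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("'rate' must be a positive number")
  structure(
    list(shape = shape, rate = rate, mean = shape / rate, cov = shape^-0.5),
    class = "frailty_spec"
  )
}

#' @param cov target coefficient of variation (> 0).
#' @param mean target mean daily hazard (> 0).
#' @rdname frailty_spec
#' @export
frailty_from_cov <- function(cov, mean = 0.0025) {
  if (!is.numeric(cov) || length(cov) != 1L || !is.finite(cov) || cov <= 0)
    stop("'cov' must be a positive number")
  shape <- cov^-2
  frailty_spec(shape = shape, rate = shape / mean)
}

#' @export
print.frailty_spec <- function(x, ...) {
  cat(sprintf("Gamma frailty: shape %.4g, rate %.4g/day (mean %.4g/day, CoV %.4g)\n",
              x$shape, x$rate, x$mean, x$cov))
  invisible(x)
}

#' Vaccine-protection specification
#'
#' Describes the population law of per-agent vaccine protection (VE, the
#' proportional reduction of the infection hazard).  Supported kinds:
#'
#' * `"leaky"`: every vaccinee gets the same constant protection `ve_level`.
#' * `"all_or_nothing"`: a fraction `ve_level` is fully protected (VE = 1),
#'   the rest unprotected (VE = 0).
#' * `"beta"`: constant per-agent VE drawn from Beta(`shape1`, `shape2`)
#'   with mean `shape1 / (shape1 + shape2)`.
#' * `"antibody"`: per-agent protection derived from a waning antibody
#'   titre; the cohort stores each vaccinee's antibody scale \eqn{C_i}
#'   (lognormal) and the VE at time t comes from an [antibody_model()]
#'   plus a [protection_map()].
#'
#' @param kind one of `"leaky"`, `"all_or_nothing"`, `"beta"`, `"antibody"`.
#' @param ve_level protection level in `[0, 1]` (leaky) or protected
#'   fraction (all-or-nothing).
#' @param shape1,shape2 positive beta parameters \eqn{\alpha_\beta,
#'   \beta_\beta} (beta kind).
#' @param antibody an [antibody_model()] (antibody kind).
#' @return an object of class `protection_spec`.
#' @export
#' @examples
#' protection_spec("leaky", ve_level = 0.5)
#' protection_spec("beta", shape1 = 2, shape2 = 2)
protection_spec <- function(kind = c("leaky", "all_or_nothing", "beta", "antibody"),
                            ve_level = NULL, shape1 = NULL, shape2 = NULL,
                            antibody = NULL) {
  kind <- match.arg(kind)
  out <- list(kind = kind)
  if (kind %in% c("leaky", "all_or_nothing")) {
    if (is.null(ve_level) || !is.numeric(ve_level) || length(ve_level) != 1L ||
        is.na(ve_level) || ve_level < 0 || ve_level > 1)
      stop("'ve_level' must be a single number in [0, 1]")
    out$ve_level <- ve_level
    out$mean_ve <- ve_level
  } else if (kind == "beta") {
    if (is.null(shape1) || is.null(shape2) || shape1 <= 0 || shape2 <= 0)
      stop("beta protection needs positive 'shape1' and 'shape2'")
    out$shape1 <- shape1
    out$shape2 <- shape2
    out$mean_ve <- shape1 / (shape1 + shape2)
  } else { # antibody
    if (is.null(antibody) || !inherits(antibody, "antibody_model"))
      stop("antibody protection needs an 'antibody_model' object")
    out$antibody <- antibody
  }
  structure(out, class = "protection_spec")
}

#' @export
print.protection_spec <- function(x, ...) {
  switch(x$kind,
    leaky = cat(sprintf("Leaky protection: constant VE %.3f\n", x$ve_level)),
    all_or_nothing = cat(sprintf(
      "All-or-nothing protection: %.1f%% fully protected\n", 100 * x$ve_level)),
    beta = cat(sprintf("Beta(%.3g, %.3g) protection (mean VE %.3f)\n",
                       x$shape1, x$shape2, x$mean_ve)),
    antibody = {
      cat("Antibody-derived protection:\n  ")
      print(x$antibody)
    })
  invisible(x)
}

#' Sample relative frailties
#'
#' Draws i.i.d. relative daily hazards from a gamma [frailty_spec()].
#'
#' @param spec a [frailty_spec()].
#' @param n number of draws (>= 1).
#' @param seed optional integer seed (draw is deterministic given the seed;
#'   the caller's RNG state is restored).
#' @return numeric vector of `n` positive frailties.
#' @export
#' @examples
#' q <- sample_frailty(frailty_spec(1, 400), 1000, seed = 1)
#' mean(q) # ~ 0.0025
sample_frailty <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "frailty_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("'n' must be >= 1")
  with_seed(seed, stats::rgamma(n, shape = spec$shape, rate = spec$rate))
}

#' Sample per-agent vaccine protection
#'
#' Draws constant per-agent VE values for the `"leaky"`, `"all_or_nothing"`
#' and `"beta"` kinds.  For `"antibody"` protection the per-agent quantity is
#' the antibody scale \eqn{C_i}, drawn at cohort assembly ([make_cohort()]);
#' its time-varying VE requires a [protection_map()].
#'
#' @param spec a [protection_spec()].
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return numeric vector of `n` VE values in `[0, 1]`.
#' @export
#' @examples
#' sample_protection(protection_spec("leaky", 0.5), 3)
sample_protection <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "protection_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("'n' must be >= 1")
  with_seed(seed, switch(spec$kind,
    leaky = rep(spec$ve_level, n),
    all_or_nothing = as.numeric(stats::runif(n) < spec$ve_level),
    beta = stats::rbeta(n, spec$shape1, spec$shape2),
    antibody = stop("antibody-derived protection is sampled as an antibody scale; ",
                    "use make_cohort() and a protection_map()")
  ))
}

#' Assemble a simulation cohort
#'
#' Builds the agent population: arm labels (`vaccinated_fraction` of agents
#' vaccinated, count rounded half-to-even), relative frailties drawn from a
#' single gamma distribution common to both arms, and per-agent protection
#' parameters (VE for constant kinds, antibody scale \eqn{C_i} for the
#' antibody kind; unvaccinated agents have protection 0 at all times).
#' Frailty and protection draws are independent of each other, taken from
#' separate RNG sub-streams of `seed`.
#'
#' @param n_total cohort size (>= 1).
#' @param vaccinated_fraction fraction vaccinated in `[0, 1]`.
#' @param frailty a [frailty_spec()], or a single positive number for a
#'   homogeneous daily hazard (e.g. `0.0025`).
#' @param protection a [protection_spec()].
#' @param seed master integer seed.
#' @return an object of class `cohort`: a `data.frame` with columns
#'   `agent_id`, `vaccinated` (0/1), `frailty_q` (daily hazard scale) and
#'   `protection_param` (VE, or antibody scale `C` for antibody protection;
#'   `NA` for unvaccinated agents under antibody protection), carrying the
#'   specs as attributes.  Serializable directly with [utils::write.csv()].
#' @export
#' @examples
#' coh <- make_cohort(1000, 0.4, frailty_spec(1, 400),
#'                    protection_spec("leaky", 0.5), seed = 1)
#' table(coh$vaccinated)
make_cohort <- function(n_total, vaccinated_fraction, frailty, protection,
                        seed = NULL) {
  if (!is.numeric(n_total) || length(n_total) != 1L || n_total < 1)
    stop("'n_total' must be a positive count")
  if (!is.numeric(vaccinated_fraction) || vaccinated_fraction < 0 ||
      vaccinated_fraction > 1)
    stop("'vaccinated_fraction' must lie in [0, 1]")
  stopifnot(inherits(protection, "protection_spec"))
  n_total <- as.integer(n_total)
  n_vax <- as.integer(round(vaccinated_fraction * n_total)) # round half even
  vaccinated <- c(rep(1L, n_vax), rep(0L, n_total - n_vax))

  if (is.numeric(frailty) && length(frailty) == 1L) {
    if (frailty < 0) stop("homogeneous hazard must be non-negative")
    q <- rep(as.numeric(frailty), n_total)
    frailty <- NULL
  } else {
    stopifnot(inherits(frailty, "frailty_spec"))
    q <- sample_frailty(frailty, n_total,
                        seed = if (is.null(seed)) NULL
                               else substream_seed(seed, "frailty"))
  }

  pseed <- if (is.null(seed)) NULL else substream_seed(seed, "protection")
  if (protection$kind == "antibody") {
    am <- protection$antibody
    prot <- rep(NA_real_, n_total)
    if (n_vax > 0)
      prot[seq_len(n_vax)] <- with_seed(
        pseed, stats::rlnorm(n_vax, meanlog = am$log_c_median,
                             sdlog = am$log_c_sd))
  } else {
    prot <- numeric(n_total)
    if (n_vax > 0)
      prot[seq_len(n_vax)] <- sample_protection(protection, n_vax, seed = pseed)
  }

  structure(
    data.frame(agent_id = seq_len(n_total), vaccinated = vaccinated,
               frailty_q = q, protection_param = prot),
    frailty = frailty, protection = protection, seed = seed,
    class = c("cohort", "data.frame")
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort of %d agents (%d vaccinated, %d unvaccinated)\n",
              nrow(x), sum(x$vaccinated == 1L), sum(x$vaccinated == 0L)))
  fr <- attr(x, "frailty")
  if (is.null(fr)) {
    cat(sprintf("  homogeneous daily hazard %.4g/day\n", x$frailty_q[1L]))
  } else {
    cat("  "); print(fr)
  }
  cat("  "); print(attr(x, "protection"))
  invisible(x)
}

# Per-agent VE at study day t for the vaccinated members of a cohort.
# Constant-protection kinds ignore t; antibody protection needs a map.
protection_at <- function(cohort, t, map = NULL) {
  spec <- attr(cohort, "protection")
  idx <- cohort$vaccinated == 1L
  if (spec$kind == "antibody") {
    if (is.null(map)) stop("antibody-derived protection requires a 'protection_map'")
    ve_from_antibody(antibody_at(cohort$protection_param[idx], t, spec$antibody),
                     map)
  } else {
    cohort$protection_param[idx]
  }
}
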