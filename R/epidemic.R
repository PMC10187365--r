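#' Epidemic configuration
#'
#' The infection process is an external, constant background force of
#' infection: on each day `t = 1, ..., horizon` every not-yet-infected
#' agent `i` is infected with probability `1 - exp(-h_i(t))`, where
#' `h_i(t) = foi_baseline * q_i * (1 - VE_i(t))` and `VE_i(t) = 0` for
#' unvaccinated agents.  Infection is sterilizing for the remainder of the
#' horizon (first-infection outcome only); there is no transmission
#' feedback, seasonality or spatial structure.
#'
#' When frailties are drawn from a gamma law the sampled `q_i` is itself
#' the daily hazard rate and `foi_baseline` stays at 1; homogeneous-risk
#' cohorts carry the common daily hazard (e.g. 0.0025) in `frailty_q`.
#'
#' @param foi_baseline non-negative multiplier on the per-agent daily
#'   hazard (default 1).
#' @param horizon_days study length in days (default 365).
#' @param seed optional integer seed for the infection draws.
#' @return an object of class `epidemic_config`.
#' @export
epidemic_config <- function(foi_baseline = 1, horizon_days = 365, seed = NULL) {
  if (!is.numeric(foi_baseline) || foi_baseline < 0)
    stop("'foi_baseline' must be >= 0")
  if (!is.numeric(horizon_days) || horizon_days < 1)
    stop("'horizon_days' must be >= 1")
  structure(list(foi_baseline = foi_baseline,
                 horizon_days = as.integer(horizon_days), seed = seed),
            class = "epidemic_config")
}

#' Simulate the epidemic over a cohort
#'
#' Runs the daily Bernoulli infection process (see [epidemic_config()]) and
#' returns the right-censored time-to-first-infection records.  For
#' time-constant individual hazards (leaky, all-or-nothing or beta
#' protection) the infection day is drawn exactly as the ceiling of an
#' exponential time with the same daily survival probabilities; antibody-
#' derived, waning protection uses an explicit day loop.  Either way the
#' result is byte-reproducible given `seed`.
#'
#' @param cohort a [make_cohort()] cohort.
#' @param config an [epidemic_config()].
#' @param map a [protection_map()], required when the cohort's protection
#'   is antibody-derived.
#' @param seed integer seed (overrides `config$seed`).
#' @return an object of class `event_table`: a `data.frame` with one row
#'   per agent and columns `agent_id`, `vaccinated` (0/1), `time` (day of
#'   infection, or the horizon if censored) and `event` (1 infected,
#'   0 censored), with the horizon stored as an attribute.  This is the
#'   standard right-censored survival layout; write it with
#'   [utils::write.csv()].
#' @export
#' @examples
#' coh <- make_cohort(2000, 0.4, 0.0025, protection_spec("leaky", 0.5), seed = 1)
#' ev <- run_epidemic(coh, epidemic_config(), seed = 2)
#' mean(ev$event[ev$vaccinated == 0]) # unvaccinated attack rate
run_epidemic <- function(cohort, config = epidemic_config(), map = NULL,
                         seed = config$seed) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "epidemic_config"))
  if (nrow(cohort) == 0L) stop("cohort is empty")
  horizon <- config$horizon_days
  spec <- attr(cohort, "protection")
  n <- nrow(cohort)
  vax <- cohort$vaccinated == 1L

  if (spec$kind != "antibody") {
    # constant hazards: daily survival exp(-h) each day, so the infection
    # day is ceiling(E / h) with E ~ Exp(1) -- exact and fast
    ve <- numeric(n)
    ve[vax] <- cohort$protection_param[vax]
    h <- config$foi_baseline * cohort$frailty_q * (1 - ve)
    if (any(h < 0)) stop("internal error: negative hazard")
    day <- with_seed(seed, ceiling(stats::rexp(n) / h)) # h = 0 -> Inf -> censored
    event <- as.integer(is.finite(day) & day <= horizon)
    time <- ifelse(event == 1L, day, horizon)
  } else {
    if (is.null(map)) stop("antibody-derived protection requires 'map'")
    am <- spec$antibody
    q <- cohort$frailty_q
    C <- cohort$protection_param
    res <- with_seed(seed, {
      time <- rep(as.numeric(horizon), n)
      event <- integer(n)
      # unvaccinated hazards are constant: exact exponential sampling
      iu <- which(!vax)
      if (length(iu)) {
        hu <- config$foi_baseline * q[iu]
        du <- ceiling(stats::rexp(length(iu)) / hu)
        event[iu] <- as.integer(is.finite(du) & du <= horizon)
        time[iu] <- ifelse(event[iu] == 1L, du, horizon)
      }
      # vaccinated: day loop with waning VE(t)
      alive <- which(vax)
      for (d in seq_len(horizon)) {
        if (!length(alive)) break
        ab <- antibody_at(C[alive], d, am)
        hv <- config$foi_baseline * q[alive] * (1 - ve_from_antibody(ab, map))
        inf <- stats::runif(length(alive)) < (1 - exp(-hv))
        if (any(inf)) {
          hit <- alive[inf]
          event[hit] <- 1L
          time[hit] <- d
          alive <- alive[!inf]
        }
      }
      list(time = time, event = event)
    })
    time <- res$time
    event <- res$event
  }

  structure(
    data.frame(agent_id = cohort$agent_id, vaccinated = cohort$vaccinated,
               time = as.numeric(time), event = event),
    horizon = as.numeric(horizon),
    class = c("event_table", "data.frame")
  )
}

#' @export
print.event_table <- function(x, ...) {
  for (arm in c(0L, 1L)) {
    sel <- x$vaccinated == arm
    cat(sprintf("%-13s %6d agents, %6d infections (attack rate %.3f)\n",
                if (arm) "vaccinated:" else "unvaccinated:", sum(sel),
                sum(x$event[sel]), mean(x$event[sel])))
  }
  cat(sprintf("horizon %g days\n", attr(x, "horizon")))
  invisible(x)
}

#' Per-day susceptible fractions by arm
#'
#' Non-increasing step functions, one per arm, starting at 1 on day 0:
#' the fraction of each arm not yet infected at the end of each day.
#'
#' @param events an [run_epidemic()] `event_table`.
#' @return `data.frame` with columns `day` (0..horizon), `unvaccinated`
#'   and `vaccinated` susceptible fractions.
#' @export
susceptible_fraction_series <- function(events) {
  stopifnot(inherits(events, "event_table"))
  horizon <- attr(events, "horizon")
  days <- 0:horizon
  frac <- function(arm) {
    sel <- events$vaccinated == arm
    n <- sum(sel)
    if (n == 0L) return(rep(NA_real_, length(days)))
    inf_times <- events$time[sel & events$event == 1L]
    counts <- cumsum(tabulate(pmin(floor(inf_times), horizon) + 1L,
                              nbins = horizon + 1L))
    1 - counts / n
  }
  data.frame(day = days, unvaccinated = frac(0L), vaccinated = frac(1L))
}
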