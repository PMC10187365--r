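#' Default time-category boundaries
#'
#' Partition `(0, horizon]` into categories of nominal `width` days, the
#' last category absorbing any remainder shorter than a full width.  For
#' the default 365-day season this yields eleven 30-day categories and a
#' final 35-day category `(330, 365]`.
#'
#' @param horizon study length in days.
#' @param width nominal category width in days (default 30).
#' @return increasing numeric vector of boundaries from 0 to `horizon`.
#' @export
#' @examples
#' tvi_breaks(365)
tvi_breaks <- function(horizon = 365, width = 30) {
  if (horizon <= width) return(c(0, horizon))
  interior <- seq(width, horizon - width, by = width)
  c(0, interior, horizon)
}

#' Fit a time-category by vaccine interaction (TVI) Cox model
#'
#' Estimates measured vaccine effectiveness over time from right-censored
#' first-infection data.  Each agent's record is split at the category
#' boundaries into counting-process (start, stop] intervals, and a Cox
#' proportional-hazards partial likelihood is maximized with the vaccine
#' indicator interacted with category membership as the only covariates
#' (the baseline hazard absorbs time itself).  The per-category measured
#' VE is `mVE = 1 - exp(beta_category)`; it is always below 1 and can be
#' negative.  Ties (daily event times are heavily tied) are handled by the
#' Efron approximation.
#'
#' @param events an `event_table` from [run_epidemic()], or any
#'   `data.frame` with columns `vaccinated` (0/1), `time` (> 0) and
#'   `event` (0/1).
#' @param breaks category boundaries including 0 and the horizon; default
#'   [tvi_breaks()] on the table's horizon.
#' @return an object of class `tvi_fit` with components
#'   \describe{
#'     \item{table}{`data.frame` with one row per category:
#'       `category_start`, `category_end`, `log_hr`, `se`, `mve`,
#'       `mve_lo`, `mve_hi` (95% limits), `events_unvax`, `events_vax`.}
#'     \item{breaks}{the category boundaries.}
#'     \item{coxfit}{the underlying [survival::coxph()] fit.}
#'   }
#'   Categories with zero events in either arm have `NA` estimates and are
#'   flagged with a warning.
#' @seealso [predict.tvi_fit()] for the mVE step function,
#'   [plot.tvi_fit()], [coef.tvi_fit()]
#' @export
#' @examples
#' coh <- make_cohort(20000, 0.4, 0.0025, protection_spec("leaky", 0.5), seed = 1)
#' ev <- run_epidemic(coh, epidemic_config(), seed = 2)
#' fit <- fit_tvi(ev)
#' summary(fit)
fit_tvi <- function(events, breaks = NULL) {
  stopifnot(is.data.frame(events),
            all(c("vaccinated", "time", "event") %in% names(events)))
  if (is.null(breaks)) {
    horizon <- attr(events, "horizon")
    if (is.null(horizon)) horizon <- max(events$time)
    breaks <- tvi_breaks(horizon)
  }
  breaks <- sort(unique(as.numeric(breaks)))
  if (breaks[1L] != 0) stop("'breaks' must start at 0")
  if (max(events$time) > max(breaks)) stop("'breaks' must cover all event times")
  ncat <- length(breaks) - 1L
  if (sum(events$event[events$vaccinated == 1L]) == 0L)
    stop("no events in the vaccinated arm: mVE is not estimable")
  if (sum(events$event[events$vaccinated == 0L]) == 0L)
    stop("no events in the unvaccinated arm: mVE is not estimable")

  if (any(events$time <= 0)) stop("'time' must be positive")
  # Counting-process layout with censored intervals aggregated under integer
  # case weights (risk-set sums are weight-linear, so this is exact).  Event
  # rows stay individual: the Efron tie correction steps through tied deaths
  # one at a time and is not invariant to aggregating them.
  idx <- findInterval(events$time, breaks, left.open = TRUE)
  vax01 <- as.integer(events$vaccinated)
  is_ev <- events$event == 1L
  term_ev <- data.frame(time = events$time[is_ev], event = 1L,
                        vaccinated = vax01[is_ev], tcat = idx[is_ev],
                        weight = 1L)
  term_ev$tstart <- breaks[term_ev$tcat]
  term <- term_ev
  if (any(!is_ev)) {
    term_cens <- stats::aggregate(
      list(weight = rep(1L, sum(!is_ev))),
      by = list(time = events$time[!is_ev], event = rep(0L, sum(!is_ev)),
                vaccinated = vax01[!is_ev], tcat = idx[!is_ev]), FUN = sum)
    term_cens$tstart <- breaks[term_cens$tcat]
    term <- rbind(term_ev, term_cens[, names(term_ev)])
  }
  df <- term
  if (ncat > 1L) {
    full <- do.call(rbind, lapply(c(0L, 1L), function(a) {
      past <- tabulate(idx[vax01 == a], nbins = ncat) # terminal intervals
      at_risk_beyond <- rev(cumsum(rev(past)))        # enter category j + 1
      j <- seq_len(ncat - 1L)
      data.frame(time = breaks[j + 1L], event = 0L, vaccinated = a,
                 tcat = j, weight = at_risk_beyond[j + 1L], tstart = breaks[j])
    }))
    df <- rbind(term[, names(full)], full[full$weight > 0L, ])
  }
  df$tcat <- factor(df$tcat, levels = seq_len(ncat))

  fml <- if (ncat > 1L) Surv(tstart, time, event) ~ tcat:vaccinated
         else Surv(tstart, time, event) ~ vaccinated
  diagnostics <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, weights = df$weight, ties = "efron"),
    warning = function(w) {
      # divergent coefficients arise exactly in the zero-event categories,
      # which are detected and set NA below; keep the message as a diagnostic
      diagnostics <<- c(diagnostics, conditionMessage(w))
      if (grepl("beta may be infinite|Loglik converged", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })

  beta <- as.numeric(stats::coef(fit))
  se <- sqrt(diag(stats::vcov(fit)))
  ev_tab <- table(factor(idx[events$event == 1L], levels = seq_len(ncat)),
                  factor(vax01[events$event == 1L], levels = c(0, 1)))
  bad <- ev_tab[, 1L] == 0L | ev_tab[, 2L] == 0L
  beta[bad] <- NA_real_
  se[bad] <- NA_real_
  if (any(bad))
    warning(sprintf("%d categor%s with zero events in one arm: estimates set NA",
                    sum(bad), if (sum(bad) == 1L) "y" else "ies"))

  tab <- data.frame(
    category_start = breaks[-length(breaks)],
    category_end = breaks[-1L],
    log_hr = beta,
    se = se,
    mve = 1 - exp(beta),
    mve_lo = 1 - exp(beta + 1.96 * se),
    mve_hi = 1 - exp(beta - 1.96 * se),
    events_unvax = as.integer(ev_tab[, 1L]),
    events_vax = as.integer(ev_tab[, 2L])
  )
  structure(list(table = tab, breaks = breaks, coxfit = fit,
                 n = nrow(events), n_events = sum(events$event),
                 diagnostics = diagnostics),
            class = "tvi_fit")
}

#' @export
print.tvi_fit <- function(x, digits = 3, ...) {
  cat(sprintf("TVI Cox fit: %d categories, %d agents, %d events\n",
              nrow(x$table), x$n, x$n_events))
  cat(sprintf("End-of-season mVE: %.*f\n", digits, end_of_season_mve(x)))
  invisible(x)
}

#' @export
summary.tvi_fit <- function(object, ...) {
  structure(list(table = object$table, n = object$n,
                 n_events = object$n_events), class = "summary.tvi_fit")
}

#' @export
print.summary.tvi_fit <- function(x, digits = 3, ...) {
  cat(sprintf("TVI Cox fit (%d agents, %d events)\n", x$n, x$n_events))
  tab <- x$table
  tab[, 3:7] <- round(tab[, 3:7], digits)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.tvi_fit <- function(object, ...) {
  stats::setNames(object$table$log_hr,
                  sprintf("(%g,%g]", object$table$category_start,
                          object$table$category_end))
}

#' @export
vcov.tvi_fit <- function(object, ...) stats::vcov(object$coxfit)

#' mVE step function
#'
#' Evaluates the piecewise-constant measured-VE trajectory (and its 95%
#' pointwise band on the log hazard-ratio scale) at arbitrary times.
#'
#' @param object a [fit_tvi()] fit.
#' @param times days at which to evaluate (clamped into `(0, horizon]`).
#' @param ... unused.
#' @return `data.frame` with columns `time`, `mve`, `mve_lo`, `mve_hi`.
#' @export
predict.tvi_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- seq(1, max(object$breaks))
  idx <- findInterval(times, object$breaks, left.open = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(object$table))
  data.frame(time = times,
             mve = object$table$mve[idx],
             mve_lo = object$table$mve_lo[idx],
             mve_hi = object$table$mve_hi[idx])
}

#' @export
plot.tvi_fit <- function(x, true_ve = NULL, theory = NULL,
                         ylim = NULL, ...) {
  tab <- x$table
  tr <- predict(x)
  if (is.null(ylim))
    ylim <- range(c(tab$mve_lo, tab$mve_hi, true_ve, 0, 1), na.rm = TRUE)
  graphics::plot(tr$time, tr$mve, type = "s", ylim = ylim,
                 xlab = "day", ylab = "measured VE", ...)
  graphics::lines(tr$time, tr$mve_lo, type = "s", lty = 3)
  graphics::lines(tr$time, tr$mve_hi, type = "s", lty = 3)
  if (!is.null(true_ve)) graphics::abline(h = true_ve, lty = 2)
  if (!is.null(theory) && inherits(theory, "theory_prediction"))
    graphics::lines(theory$day, theory$mve_pred, col = "purple", lty = 2)
  invisible(x)
}

#' Final-category measured VE
#'
#' The end-of-season readout used throughout the scenario summaries: the
#' measured VE of the last time category.
#'
#' @param fit a [fit_tvi()] fit.
#' @return a single mVE value.
#' @export
end_of_season_mve <- function(fit) {
  stopifnot(inherits(fit, "tvi_fit"))
  fit$table$mve[nrow(fit$table)]
}
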