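#' Define a named simulation scenario
#'
#' A scenario bundles everything that determines a simulation experiment:
#' cohort size and coverage, the frailty and protection laws, the
#' antibody-protection map (when protection is antibody-derived), the
#' epidemic configuration, the estimation scheme and the replicate count.
#' Given its master seed a scenario determines every output exactly.
#'
#' @param name scenario label.
#' @param n_total cohort size (default 100000).
#' @param vaccinated_fraction vaccinated fraction (default 0.4).
#' @param frailty a [frailty_spec()] or a homogeneous daily hazard.
#' @param protection a [protection_spec()].
#' @param map a [protection_map()] (antibody protection only).
#' @param foi_baseline force-of-infection multiplier (default 1).
#' @param horizon study days (default 365).
#' @param breaks TVI category boundaries (default [tvi_breaks()]).
#' @param replicates number of seeded replicates (default 20).
#' @param seed master seed.
#' @return an object of class `scenario`.
#' @export
#' @examples
#' sc <- scenario("frailty_effect", frailty = frailty_spec(0.2, 80),
#'                protection = protection_spec("leaky", 0.5),
#'                replicates = 2, seed = 1)
scenario <- function(name, n_total = 100000, vaccinated_fraction = 0.4,
                     frailty, protection, map = NULL, foi_baseline = 1,
                     horizon = 365, breaks = tvi_breaks(horizon),
                     replicates = 20, seed = 1) {
  stopifnot(inherits(protection, "protection_spec"))
  if (protection$kind == "antibody" &&
      (is.null(map) || !inherits(map, "protection_map")))
    stop("antibody-derived protection requires a 'protection_map'")
  if (!is.numeric(replicates) || replicates < 1)
    stop("'replicates' must be >= 1")
  if (is.numeric(frailty)) {
    if (length(frailty) != 1L || frailty < 0)
      stop("homogeneous hazard must be a single value >= 0")
  } else stopifnot(inherits(frailty, "frailty_spec"))
  structure(list(name = name, n_total = n_total,
                 vaccinated_fraction = vaccinated_fraction,
                 frailty = frailty, protection = protection, map = map,
                 foi_baseline = foi_baseline, horizon = horizon,
                 breaks = breaks, replicates = as.integer(replicates),
                 seed = seed),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': n = %d (%.0f%% vaccinated), %d day(s), %d replicate(s), seed %s\n",
              x$name, x$n_total, 100 * x$vaccinated_fraction, x$horizon,
              x$replicates, format(x$seed)))
  invisible(x)
}

#' Run a scenario end to end
#'
#' For each replicate: assemble the cohort, simulate the epidemic, fit the
#' TVI Cox model.  Replicate seeds are deterministic sub-streams of the
#' scenario's master seed.  For constant (leaky / beta) protection with
#' gamma or homogeneous frailty the analytic selection trajectory
#' ([predicted_hr_trajectory()]) is attached.
#'
#' @param sc a [scenario()].
#' @param keep_fits keep the per-replicate [fit_tvi()] objects (default
#'   `FALSE`; the per-category tables are always kept).
#' @param outdir optional directory; when given, writes
#'   `mve_by_category.csv` (per replicate), `mve_mean.csv`, `ve_ne.csv`
#'   and, when available, `theory.csv` under it (byte-reproducible for a
#'   fixed master seed).
#' @return an object of class `scenario_result` with components `scenario`,
#'   `mve` (long `data.frame`: replicate x category estimates),
#'   `mve_mean` (per-category across-replicate mean mVE and the empirical
#'   2.5/97.5% band of end-of-season mVE), `end_mve` (per-replicate final-
#'   category mVE), `ve_ne` (no-epidemic mean efficacy at day 0 and
#'   averaged over the final category), `theory` (or `NULL`), and `fits`
#'   when requested.
#' @export
run_scenario <- function(sc, keep_fits = FALSE, outdir = NULL) {
  stopifnot(inherits(sc, "scenario"))
  cfg <- epidemic_config(sc$foi_baseline, sc$horizon)
  per_rep <- vector("list", sc$replicates)
  fits <- if (keep_fits) vector("list", sc$replicates)
  end_mve <- numeric(sc$replicates)
  for (r in seq_len(sc$replicates)) {
    coh <- make_cohort(sc$n_total, sc$vaccinated_fraction, sc$frailty,
                       sc$protection,
                       seed = substream_seed(sc$seed, paste0("cohort:", r)))
    ev <- run_epidemic(coh, cfg, map = sc$map,
                       seed = substream_seed(sc$seed, paste0("epidemic:", r)))
    fit <- fit_tvi(ev, breaks = sc$breaks)
    tab <- fit$table
    tab$replicate <- r
    per_rep[[r]] <- tab
    end_mve[r] <- end_of_season_mve(fit)
    if (keep_fits) fits[[r]] <- fit
  }
  mve <- do.call(rbind, per_rep)
  mve_mean <- stats::aggregate(
    mve[, c("log_hr", "mve")],
    by = list(category_start = mve$category_start,
              category_end = mve$category_end), FUN = mean)

  ve_ne <- scenario_ve_ne(sc)
  theory <- NULL
  if (sc$protection$kind %in% c("leaky", "beta"))
    theory <- predicted_hr_trajectory(sc$frailty, sc$protection,
                                      foi = sc$foi_baseline,
                                      horizon = sc$horizon)

  out <- structure(
    list(scenario = sc, mve = mve, mve_mean = mve_mean, end_mve = end_mve,
         mean_end_mve = mean(end_mve),
         end_band = stats::quantile(end_mve, c(0.025, 0.975), names = FALSE),
         ve_ne = ve_ne, theory = theory, fits = fits),
    class = "scenario_result")
  if (!is.null(outdir)) write_scenario_result(out, outdir)
  out
}

# No-epidemic mean efficacy at day 0 and averaged over the final category.
scenario_ve_ne <- function(sc) {
  final_days <- seq(sc$breaks[length(sc$breaks) - 1L] + 1L, sc$horizon)
  if (sc$protection$kind == "antibody") {
    am <- sc$protection$antibody
    c(day0 = mean_ve_lognormal(am, sc$map, 0),
      end = mean(vapply(final_days,
                        function(d) mean_ve_lognormal(am, sc$map, d),
                        numeric(1))))
  } else {
    c(day0 = sc$protection$mean_ve, end = sc$protection$mean_ve)
  }
}

write_scenario_result <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$mve, file.path(outdir, "mve_by_category.csv"),
                   row.names = FALSE)
  utils::write.csv(res$mve_mean, file.path(outdir, "mve_mean.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(quantity = names(res$ve_ne), value = res$ve_ne),
                   file.path(outdir, "ve_ne.csv"), row.names = FALSE)
  if (!is.null(res$theory))
    utils::write.csv(res$theory[, c("day", "rbar_u", "rbar_v", "hr", "mve_pred")],
                     file.path(outdir, "theory.csv"), row.names = FALSE)
  invisible(res)
}

#' @export
print.scenario_result <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("End-of-season mVE: %.3f (replicate band %.3f-%.3f); VE_NE end %.3f\n",
              x$mean_end_mve, x$end_band[1L], x$end_band[2L], x$ve_ne[["end"]]))
  invisible(x)
}

#' Offset fraction of the frailty-induced mVE deficit
#'
#' With `delta_frailty_only = VE_NE - mVE_end` under frailty heterogeneity
#' alone and `delta_both` the same quantity when vaccine-response
#' heterogeneity is added, the offset percentage is
#' `100 * (delta_frailty_only - delta_both) / delta_frailty_only`:
#' 0 when adding response heterogeneity changes nothing, 100 when it
#' cancels the deficit exactly, above 100 when mVE overshoots VE_NE.
#'
#' @param delta_frailty_only frailty-only deficit (nonzero).
#' @param delta_both deficit with both heterogeneities.
#' @return offset percentage.
#' @export
#' @examples
#' offset_fraction(10, -1) # 110: overshoot
offset_fraction <- function(delta_frailty_only, delta_both) {
  if (any(delta_frailty_only == 0))
    stop("offset undefined: 'delta_frailty_only' is zero")
  100 * (delta_frailty_only - delta_both) / delta_frailty_only
}

#' Heterogeneity grid of waning-protection scenarios
#'
#' Runs the antibody-waning simulations over a grid of antibody-scale SD
#' levels (natural-log SD of `C`; 0 = homogeneous vaccine response) by
#' frailty CoV levels (0 = homogeneous susceptibility, mean daily hazard
#' held at `mean_hazard`) for one or both antibody-to-protection maps.
#' Each map's free scale is calibrated once at `log_c_sd = 1` to
#' `target_mean_ve` mean initial protection and then held fixed across SD
#' levels.  For every cell the end-of-season mVE (final TVI category,
#' averaged over replicates) is compared with the no-epidemic efficacy
#' averaged over the final category, and — for cells with both
#' heterogeneities — the [offset_fraction()] is computed against the
#' SD = 0 cell at the same CoV and map.
#'
#' @param sd_levels antibody ln-SD levels (default `c(0, 0.75, 1.5)`).
#' @param cov_levels frailty CoV levels (default `c(0, 0.5, 1)`).
#' @param map_kinds protection maps to run (default both).
#' @param n_total,vaccinated_fraction,horizon cohort / epidemic settings.
#' @param mean_hazard mean daily hazard shared by all frailty levels
#'   (default 0.0025).
#' @param replicates replicates per cell (default 20).
#' @param target_mean_ve calibration target at SD = 1 (default 0.9).
#' @param correlate_exponent risk-correlate conversion exponent.
#' @param seed master seed.
#' @return an object of class `offset_grid`: a `data.frame` with one row
#'   per cell (`map`, `sd`, `cov`, `mve_end`, `ve_ne_end`, `delta`,
#'   `offset_pct`), with attributes `median_offset` (cells with both
#'   heterogeneities, pooled across maps), `median_by_map`, and the
#'   calibrated scales.
#' @export
grid_run <- function(sd_levels = c(0, 0.75, 1.5), cov_levels = c(0, 0.5, 1),
                     map_kinds = c("risk_correlate", "within_host"),
                     n_total = 100000, vaccinated_fraction = 0.4,
                     horizon = 365, mean_hazard = 0.0025, replicates = 20,
                     target_mean_ve = 0.9, correlate_exponent = -0.5,
                     seed = 1) {
  map_kinds <- match.arg(map_kinds, several.ok = TRUE)
  sd_levels <- sort(unique(sd_levels))
  cov_levels <- sort(unique(cov_levels))
  rows <- list()
  scales <- list()
  for (kind in map_kinds) {
    cal <- calibrate_protection_scale(
      antibody_model(log_c_sd = 1),
      protection_map(kind, exponent = correlate_exponent),
      target_mean_ve = target_mean_ve)
    scales[[kind]] <- cal$scale
    for (cov in cov_levels) {
      frailty <- if (cov > 0) frailty_from_cov(cov, mean_hazard)
                 else mean_hazard
      for (sd in sd_levels) {
        am <- cal$model; am$log_c_sd <- sd
        sc <- scenario(
          name = sprintf("%s_sd%g_cov%g", kind, sd, cov),
          n_total = n_total, vaccinated_fraction = vaccinated_fraction,
          frailty = frailty,
          protection = protection_spec("antibody", antibody = am),
          map = cal$map, horizon = horizon, replicates = replicates,
          seed = substream_seed(seed, sprintf("grid:%s:%g:%g", kind, sd, cov)))
        res <- run_scenario(sc)
        rows[[length(rows) + 1L]] <- data.frame(
          map = kind, sd = sd, cov = cov,
          mve_end = res$mean_end_mve, ve_ne_end = res$ve_ne[["end"]],
          delta = res$ve_ne[["end"]] - res$mean_end_mve)
      }
    }
  }
  grid <- do.call(rbind, rows)
  grid$offset_pct <- NA_real_
  for (i in seq_len(nrow(grid))) {
    if (grid$sd[i] > 0 && grid$cov[i] > 0) {
      ref <- grid$map == grid$map[i] & grid$cov == grid$cov[i] & grid$sd == 0
      if (any(ref) && grid$delta[which(ref)[1L]] != 0)
        grid$offset_pct[i] <- offset_fraction(grid$delta[which(ref)[1L]],
                                              grid$delta[i])
    }
  }
  both <- !is.na(grid$offset_pct)
  structure(grid,
            median_offset = stats::median(grid$offset_pct[both]),
            median_by_map = vapply(
              map_kinds,
              function(k) stats::median(grid$offset_pct[both & grid$map == k]),
              numeric(1)),
            calibrated_scales = scales,
            class = c("offset_grid", "data.frame"))
}

#' @export
print.offset_grid <- function(x, digits = 3, ...) {
  tab <- as.data.frame(x)
  tab$mve_end <- round(tab$mve_end, digits)
  tab$ve_ne_end <- round(tab$ve_ne_end, digits)
  tab$delta <- round(tab$delta, digits)
  tab$offset_pct <- round(tab$offset_pct, 1)
  print.data.frame(tab, row.names = FALSE)
  cat(sprintf("\nMedian offset over both-heterogeneity cells: %.1f%%\n",
              attr(x, "median_offset")))
  invisible(x)
}
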