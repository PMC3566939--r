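#' Observed cumulative incidence from complete follow-up
#'
#' Crude cumulative proportion: the incidence of an event type at year
#' \eqn{t} is the number of individuals whose first event of that type
#' occurred at or before \eqn{t}, divided by the cohort size. This requires
#' complete follow-up — every individual must either reach \code{horizon}
#' or die beforehand; censoring before the horizon is an error (pre-filter
#' the cohort, mirroring a complete-follow-up restriction). Competing death
#' bounds the nonfatal-event incidences naturally.
#'
#' @param events Event table as returned by \code{\link{generate_followup}}
#'   (columns \code{chd_year}, \code{stroke_year}, \code{cvd_death_year},
#'   \code{non_cvd_death_year}, \code{followup_years}).
#' @param event_type One of \code{event_types()}.
#' @param horizon Years over which to report.
#' @return Numeric vector of length \code{horizon}: incidence at years
#'   1..horizon (nondecreasing).
#' @export
observed_cumulative_incidence <- function(events, event_type, horizon) {
  col <- switch(event_type,
                CHD = "chd_year", STROKE = "stroke_year",
                CVD_DEATH = "cvd_death_year",
                NON_CVD_DEATH = "non_cvd_death_year",
                stop("unknown event type '", event_type, "'"))
  dead <- !is.na(events$cvd_death_year) | !is.na(events$non_cvd_death_year)
  censored_early <- !dead & events$followup_years < horizon
  if (any(censored_early)) {
    stop(sum(censored_early), " individual(s) censored before year ",
         horizon, " without a terminal event; restrict the cohort to ",
         "complete follow-up first")
  }
  yrs <- events[[col]]
  cnt <- tabulate(yrs[!is.na(yrs)], nbins = horizon)
  cumsum(cnt) / nrow(events)
}

#' Compare observed incidences with a simulated incidence surface
#'
#' Joins the observed cumulative incidence of each event with the simulated
#' mean and 2.5--97.5 percentile credibility band, year by year, and flags
#' whether the observed value lies inside the band.
#'
#' @param observed Named list: one numeric vector per event type (years
#'   1..horizon), e.g. from \code{\link{observed_cumulative_incidence}}.
#' @param surface A \code{cvd_surface} from \code{\link{run_three_level}}.
#' @param stratum Label stored in the report.
#' @return Object of class \code{cvd_validation}: data frame with columns
#'   \code{stratum}, \code{event}, \code{year}, \code{observed},
#'   \code{simulated}, \code{lo}, \code{hi}, \code{inside}.
#' @export
compare_incidence <- function(observed, surface, stratum = "overall") {
  stopifnot(is.list(observed), inherits(surface, "cvd_surface"))
  out <- list()
  for (ev in names(observed)) {
    sub <- surface[surface$event == ev, ]
    if (!nrow(sub)) stop("surface has no rows for event '", ev, "'")
    obs <- observed[[ev]]
    if (length(obs) != nrow(sub)) {
      stop("year mismatch for event '", ev, "': observed covers ",
           length(obs), " years, surface ", nrow(sub))
    }
    out[[ev]] <- data.frame(stratum = stratum, event = ev,
                            year = sub$year, observed = obs,
                            simulated = sub$mean, lo = sub$lo, hi = sub$hi,
                            inside = obs >= sub$lo & obs <= sub$hi)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("cvd_validation", "data.frame"))
}

#' @export
print.cvd_validation <- function(x, ...) {
  cat(sprintf("<cvd_validation> %d cells, %.1f%% inside the credibility band\n",
              nrow(x), 100 * mean(x$inside)))
  NextMethod()
}

#' Stratified validation
#'
#' Repeats the simulate-and-compare cycle within strata: overall, tertiles
#' of baseline age (cut points from the cohort itself) and each sex. Within
#' a stratum the simulation aggregates on the individual level (every
#' member simulated, no profile resampling).
#'
#' @param cohort Cohort table.
#' @param events Event table (see
#'   \code{\link{observed_cumulative_incidence}}).
#' @param parameter_sets List of parameter sets for the outer loop.
#' @param config A \code{\link{sim_config}};
#'   \code{aggregate_by_individual} is forced on.
#' @param event_type Event compared across strata (default CVD mortality, a
#'   clinically central outcome with enough events per stratum).
#' @param drift A \code{\link{drift_model}}.
#' @return A \code{cvd_validation} data frame covering all strata.
#' @export
stratified_validation <- function(cohort, events, parameter_sets,
                                  config = sim_config(),
                                  event_type = "CVD_DEATH",
                                  drift = default_drift()) {
  config$aggregate_by_individual <- TRUE
  tert <- stats::quantile(cohort$age, c(1, 2) / 3)
  strata <- list(
    overall = rep(TRUE, nrow(cohort)),
    age_tertile_1 = cohort$age <= tert[1],
    age_tertile_2 = cohort$age > tert[1] & cohort$age <= tert[2],
    age_tertile_3 = cohort$age > tert[2],
    male = cohort$male == 1,
    female = cohort$male == 0
  )
  reports <- lapply(names(strata), function(s) {
    keep <- strata[[s]]
    sub_cohort <- cohort[keep, , drop = FALSE]
    sub_events <- events[match(sub_cohort$id, events$id), , drop = FALSE]
    obs <- observed_cumulative_incidence(sub_events, event_type,
                                         config$horizon)
    if (sum(sub_events[[switch(event_type, CHD = "chd_year",
                               STROKE = "stroke_year",
                               CVD_DEATH = "cvd_death_year",
                               NON_CVD_DEATH = "non_cvd_death_year")]],
            na.rm = TRUE) == 0 && all(obs == 0)) {
      warning("stratum '", s, "' has zero observed ", event_type, " events")
    }
    surf <- run_three_level(sub_cohort, parameter_sets, config, drift)
    compare_incidence(stats::setNames(list(obs), event_type), surf,
                      stratum = s)
  })
  res <- do.call(rbind, reports)
  structure(res, class = c("cvd_validation", "data.frame"))
}

#' Plot observed versus simulated cumulative incidence
#'
#' One panel per event: simulated mean curve, shaded 95% credibility band,
#' observed incidences overlaid as points.
#'
#' @param report A \code{cvd_validation} data frame.
#' @return A ggplot object.
#' @export
plot_validation <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_validation requires the ggplot2 package")
  }
  ggplot2::ggplot(report, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$simulated),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 1.2) +
    ggplot2::facet_wrap(~ event + stratum, scales = "free_y") +
    ggplot2::labs(x = "year", y = "cumulative incidence",
                  title = "Observed (points) vs simulated (line, 95% band)") +
    ggplot2::theme_minimal()
}
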