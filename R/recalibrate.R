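# Breslow estimator of the centered cumulative baseline hazard with the
# linear predictor held fixed as an offset, on counting-process intervals:
# H0(t) = sum over event times t_i <= t of d_i / sum_{j at risk at t_i}
# exp(lp_j), the risk set being {j : tstart_j < t_i <= tstop_j}. With
# lp = beta'(x - xbar_new) this is the cumulative hazard of the new
# population's average baseline individual.
breslow_offset_h0 <- function(tstart, tstop, status, lp, horizon) {
  stopifnot(length(tstop) == length(status), length(lp) == length(tstop))
  elp <- exp(lp)
  et <- sort(unique(tstop[status == 1]))
  dh <- vapply(et, function(t) {
    d <- sum(status == 1 & tstop == t)
    denom <- sum(elp[tstart < t & t <= tstop])
    d / denom
  }, numeric(1))
  sf <- stats::stepfun(et, c(0, cumsum(dh)), right = FALSE)
  h0 <- sf(0:horizon)
  h0[1] <- 0
  h0
}

#' Recalibrate a fitted model to a new population
#'
#' Adapts transition functions to a new cohort by substituting (i) the
#' centering means with the new cohort's risk-factor means and (ii) the
#' centered cumulative baseline hazards with Breslow estimates computed in
#' the new cohort's follow-up while holding the coefficients fixed (the
#' linear predictor enters as an offset). The coefficients — the relative
#' strengths of the risk-factor associations — are left untouched; this is
#' recalibration, not refitting. Applied per bootstrap replicate, so
#' parameter uncertainty is preserved in the recalibrated model.
#'
#' The new cohort's records are expanded into the same annual
#' counting-process intervals as in \code{\link{fit_all_transitions}}, so
#' the substituted baseline hazards are free of the new cohort's own
#' secular ageing, exactly like the originals.
#'
#' @param parameter_sets List of \code{\link{parameter_set}} objects (or a
#'   single one).
#' @param new_cohort Baseline cohort table of the target population.
#' @param new_followup Long follow-up record table of the target population
#'   (same format as \code{\link{fit_all_transitions}}); must contain
#'   records for every transition being recalibrated.
#' @param events Which event types to recalibrate; the default recalibrates
#'   the two mortality transition families (every transition into
#'   \code{CVD_DEATH} and \code{NON_CVD_DEATH}), matching an external
#'   validation restricted to mortality. Use \code{event_types()} to
#'   recalibrate the full model.
#' @param horizon Last integer year of the new baseline-hazard grid;
#'   defaults to each transition's existing grid length.
#' @param drift Covariate path used for the interval expansion; must match
#'   the drift used at simulation time.
#' @return Recalibrated parameter set(s), same shape as the input.
#' @export
recalibrate <- function(parameter_sets, new_cohort, new_followup,
                        events = c("CVD_DEATH", "NON_CVD_DEATH"),
                        horizon = NULL, drift = default_drift()) {
  single <- inherits(parameter_sets, "cvd_parameter_set")
  if (single) parameter_sets <- list(parameter_sets)
  new_cohort <- ensure_baseline_state(new_cohort)
  topo <- transition_topology()

  # expand each recalibrated transition's records once
  keys <- names(parameter_sets[[1]]$transitions)
  keys <- keys[vapply(parameter_sets[[1]]$transitions,
                      function(f) f$event %in% events, logical(1))]
  expanded <- list()
  for (k in keys) {
    fn <- parameter_sets[[1]]$transitions[[k]]
    rec <- new_followup[new_followup$transition_source == fn$source &
                          new_followup$transition_target == fn$target, ]
    if (!nrow(rec)) {
      stop("new cohort supplies no follow-up records for transition ",
           fn$source, " -> ", fn$target)
    }
    if (sum(rec$event) == 0) {
      stop("zero events in the new cohort for transition ",
           fn$source, " -> ", fn$target)
    }
    row <- match(rec$id, new_cohort$id)
    if (anyNA(row)) stop("follow-up records reference unknown ids")
    ex <- expand_counting(new_cohort[row, , drop = FALSE], rec$time_years,
                          rec$event, drift)
    expanded[[k]] <- list(x = profile_covariates(ex),
                          xbase = profile_covariates(new_cohort[row, ,
                                                                drop = FALSE]),
                          tstart = ex$tstart, tstop = ex$tstop,
                          status = ex$event)
  }

  out <- lapply(parameter_sets, function(ps) {
    trans <- ps$transitions
    for (k in keys) {
      fn <- trans[[k]]
      e <- expanded[[k]]
      wanted <- names(fn$coefficients)
      missing <- setdiff(wanted, colnames(e$x))
      if (length(missing)) {
        stop("new cohort lacks covariate(s): ",
             paste(missing, collapse = ", "))
      }
      # center on the transition's own at-risk population (baseline values
      # of the individuals contributing records), as the fit does
      new_means <- colMeans(e$xbase[, wanted, drop = FALSE])
      lp <- as.vector(e$x[, wanted, drop = FALSE] %*% fn$coefficients) -
        sum(fn$coefficients * new_means)
      hz <- if (is.null(horizon)) length(fn$baseline_cum_hazard) - 1L
            else horizon
      h0 <- breslow_offset_h0(e$tstart, e$tstop, e$status, lp, hz)
      trans[[k]] <- cox_transition(fn$source, fn$event,
                                   coefficients = fn$coefficients,
                                   means = new_means,
                                   baseline_cum_hazard = h0)
    }
    parameter_set(trans, replicate_id = ps$replicate_id)
  })
  if (single) out[[1]] else out
}
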