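#' Fit one centered Cox transition function
#'
#' Fits a cause-specific Cox proportional-hazards model (Breslow tie
#' handling) for a single state-to-state transition and packages it as a
#' \code{\link{cox_transition}}: coefficients \eqn{\hat\beta}, centering
#' means \eqn{\bar x}, and the centered Breslow cumulative baseline hazard
#' reported at integer years 0..\code{horizon}.
#'
#' Two record layouts are accepted. The simple layout has columns
#' \code{time_years} and \code{event} with one row per individual and
#' covariates fixed at baseline. The counting-process layout has columns
#' \code{tstart}, \code{tstop}, \code{event} with one row per
#' person-interval and covariates at their current (aged, drifted) values;
#' this is the layout produced by \code{\link{fit_all_transitions}}, and
#' the one under which the fitted baseline hazard carries no secular trend
#' of the cohort itself — the form the simulation engine assumes. The
#' centering means are the baseline (first-interval) covariate means.
#'
#' @param data Data frame in either layout, with one numeric column per
#'   covariate.
#' @param covariate_names Character vector of covariate columns to include.
#' @param source,event_type Transition identity (see
#'   \code{\link{transition_topology}}).
#' @param horizon Last integer year at which H0 is reported; defaults to
#'   the ceiling of the largest observed time.
#' @return A \code{\link{cox_transition}}.
#' @export
fit_transition <- function(data, covariate_names, source, event_type,
                           horizon = NULL) {
  stopifnot(is.data.frame(data), "event" %in% names(data))
  counting <- all(c("tstart", "tstop") %in% names(data))
  if (!counting && !"time_years" %in% names(data)) {
    stop("records need either 'time_years' or 'tstart'/'tstop' columns")
  }
  missing <- setdiff(covariate_names, names(data))
  if (length(missing)) {
    stop("records are missing covariate column(s): ",
         paste(missing, collapse = ", "))
  }
  tmax <- if (counting) data$tstop else data$time_years
  if (any(tmax <= (if (counting) data$tstart else 0))) {
    stop("all follow-up intervals must have positive length")
  }
  if (!all(data$event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(data$event) < 2) {
    stop("fewer than 2 events for transition ", source, " -> ", event_type)
  }
  # center on the baseline covariates of the individuals at risk
  base <- if (counting) data[data$tstart == 0, , drop = FALSE] else data
  x <- as.matrix(base[covariate_names])
  const <- apply(as.matrix(data[covariate_names]), 2,
                 function(v) diff(range(v)) == 0)
  if (any(const)) {
    stop("covariate(s) constant across records: ",
         paste(covariate_names[const], collapse = ", "))
  }
  if (is.null(horizon)) horizon <- ceiling(max(tmax))

  surv <- if (counting) "survival::Surv(tstart, tstop, event)"
          else "survival::Surv(time_years, event)"
  fml <- stats::as.formula(paste(surv, "~",
                                 paste(covariate_names, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converged before", conditionMessage(w))) {
        stop("Cox fit for ", source, " -> ", event_type,
             " shows separation: ", conditionMessage(w), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  if (fit$iter >= 100) {
    stop("Cox fit for ", source, " -> ", event_type,
         " did not converge after ", fit$iter, " iterations")
  }
  beta <- stats::coef(fit)
  if (any(!is.finite(beta)) || any(abs(beta) > 15)) {
    stop("Cox fit for ", source, " -> ", event_type,
         " shows separation (|beta| diverging): ",
         paste(sprintf("%s=%.2f", names(beta), beta), collapse = ", "))
  }
  xbar <- colMeans(x)

  # Breslow cumulative baseline hazard at x = 0, shifted to the centering
  # means so H0 is the cumulative hazard of the average baseline individual
  bh <- survival::basehaz(fit, centered = FALSE)
  h_centered <- bh$hazard * exp(sum(beta * xbar))
  sf <- stats::stepfun(bh$time, c(0, h_centered), right = FALSE)
  h0 <- sf(0:horizon)
  h0[1] <- 0

  cox_transition(source, event_type, coefficients = beta, means = xbar,
                 baseline_cum_hazard = h0,
                 se = stats::setNames(sqrt(diag(fit$var)), names(beta)))
}

#' Default covariate subsets per transition
#'
#' Which risk factors enter which transition equation is configurable; this
#' default assigns the classical predictors to the common transitions and a
#' reduced set (age, sex) to the sparse post-event transitions, where event
#' counts in a cohort of a few thousand would not support a richer model.
#'
#' @return Named list keyed \code{"SOURCE->EVENT"}, each element a character
#'   vector of covariate names.
#' @export
default_covariate_map <- function() {
  list(
    "WELL->CHD" = c("age", "male", "smoke_current", "smoke_former", "sbp",
                    "total_chol", "hdl", "diabetes", "prevalent_cvd"),
    "WELL->STROKE" = c("age", "male", "smoke_current", "sbp", "hypertension",
                       "atrial_fib", "diabetes", "prevalent_cvd"),
    "WELL->CVD_DEATH" = c("age", "male", "smoke_current", "sbp", "total_chol",
                          "diabetes", "prevalent_cvd"),
    "WELL->NON_CVD_DEATH" = c("age", "male", "smoke_current", "smoke_former",
                              "bmi"),
    "CHD->STROKE" = c("age", "male", "sbp"),
    "CHD->CVD_DEATH" = c("age", "male", "diabetes"),
    "CHD->NON_CVD_DEATH" = c("age", "smoke_current"),
    "STROKE->CHD" = c("age", "male"),
    "STROKE->CVD_DEATH" = c("age", "male"),
    "STROKE->NON_CVD_DEATH" = c("age"),
    "CHD_AND_STROKE->CVD_DEATH" = c("age"),
    "CHD_AND_STROKE->NON_CVD_DEATH" = c("age")
  )
}

# Expand one individual's record (exit time, event flag) into annual
# counting-process intervals with covariates on the deterministic path
# (age + 5-yearly drift), matching the covariate path the engine applies.
expand_counting <- function(cohort_rows, time, status, drift) {
  n <- nrow(cohort_rows)
  nint <- ceiling(time)
  idx <- rep(seq_len(n), nint)
  year0 <- unlist(lapply(nint, seq_len)) - 1L  # interval start year
  out <- suppressMessages(update_profile(cohort_rows[idx, , drop = FALSE],
                                         drift, year0))
  out$tstart <- year0
  out$tstop <- pmin(year0 + 1, time[idx])
  last <- year0 == (nint[idx] - 1L)
  out$event <- as.integer(last & status[idx] == 1)
  out
}

# Build, per transition, the analysis data set: person-intervals of the
# individuals whose baseline state is the transition's source, with the
# aged/drifted covariates merged in. Also returns a per-id row index used
# by the bootstrap.
prepare_transition_data <- function(cohort, followup, covariate_map,
                                    drift = default_drift()) {
  stopifnot(all(c("id", "transition_source", "transition_target",
                  "time_years", "event") %in% names(followup)))
  topo <- transition_topology()
  out <- list()
  for (k in names(covariate_map)) {
    parts <- strsplit(k, "->", fixed = TRUE)[[1]]
    src <- parts[1]; ev <- parts[2]
    tgt <- topo$target[topo$source == src & topo$event == ev]
    rec <- followup[followup$transition_source == src &
                      followup$transition_target == tgt, ]
    if (!nrow(rec)) {
      stop("no follow-up records for transition ", src, " -> ", tgt)
    }
    row <- match(rec$id, cohort$id)
    if (anyNA(row)) stop("follow-up records reference unknown individual id(s)")
    ex <- expand_counting(cohort[row, , drop = FALSE], rec$time_years,
                          rec$event, drift)
    d <- cbind(ex["id"],
               as.data.frame(profile_covariates(ex)),
               ex[c("tstart", "tstop", "event")])
    out[[k]] <- list(data = d,
                     by_id = split(seq_len(nrow(d)), factor(d$id)))
  }
  out
}

#' Fit every transition of the model on one cohort
#'
#' Expands the per-individual follow-up records into annual
#' counting-process intervals along the deterministic covariate path
#' (annual ageing, 5-yearly drift — the same updating the simulation
#' engine applies) and fits each transition with
#' \code{\link{fit_transition}}.
#'
#' @param cohort Baseline cohort table (see \code{\link{read_cohort}}).
#' @param followup Long follow-up record table with columns \code{id},
#'   \code{transition_source}, \code{transition_target}, \code{time_years},
#'   \code{event}; one row per individual per transition out of their
#'   baseline state.
#' @param covariate_map See \code{\link{default_covariate_map}}.
#' @param horizon Integer year up to which baseline hazards are reported.
#' @param drift The \code{\link{drift_model}} describing the covariate
#'   path; must match the drift used at simulation time.
#' @param replicate_id Stored in the returned set.
#' @return A \code{\link{parameter_set}}.
#' @export
fit_all_transitions <- function(cohort, followup,
                                covariate_map = default_covariate_map(),
                                horizon = 13, drift = default_drift(),
                                replicate_id = 0L) {
  prep <- prepare_transition_data(cohort, followup, covariate_map, drift)
  fit_prepared(prep, covariate_map, horizon, replicate_id)
}

fit_prepared <- function(prep, covariate_map, horizon, replicate_id) {
  trans <- lapply(names(covariate_map), function(k) {
    parts <- strsplit(k, "->", fixed = TRUE)[[1]]
    fit_transition(prep[[k]]$data, covariate_map[[k]],
                   source = parts[1], event_type = parts[2],
                   horizon = horizon)
  })
  parameter_set(trans, replicate_id = replicate_id)
}

#' Bootstrap-linked parameter sets
#'
#' Draws \code{n_replicates} bootstrap resamples of the calibration cohort
#' (individuals resampled with replacement) and refits \emph{every}
#' transition function on each resample, yielding linked sets that preserve
#' the dependence between coefficients across transitions. Refitting the
#' Breslow baseline hazard inside each resample also propagates baseline
#' hazard uncertainty. Replicates in which any fit fails (e.g. separation in
#' a sparse transition) are redrawn, up to \code{max_retries} per replicate.
#'
#' @inheritParams fit_all_transitions
#' @param n_replicates Number of bootstrap replicates (default 100).
#' @param seed Integer seed; the procedure is deterministic given it.
#' @param max_retries Redraw cap per replicate.
#' @param resample_fn Optional hook mapping the row indices \code{1..n} to a
#'   resample (used in tests; default is iid sampling with replacement).
#' @return List of \code{n_replicates} \code{\link{parameter_set}} objects.
#' @export
bootstrap_parameter_sets <- function(cohort, followup,
                                     covariate_map = default_covariate_map(),
                                     horizon = 13, drift = default_drift(),
                                     n_replicates = 100, seed = 1,
                                     max_retries = 10, resample_fn = NULL) {
  prep <- prepare_transition_data(cohort, followup, covariate_map, drift)
  n <- nrow(cohort)
  ids <- as.character(cohort$id)
  set.seed(as.integer(seed))
  sets <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    fitted <- NULL
    failures <- character(0)
    for (attempt in seq_len(max_retries)) {
      idx <- if (is.null(resample_fn)) sample.int(n, n, replace = TRUE)
             else resample_fn(seq_len(n))
      sampled_ids <- ids[idx]
      prep_r <- lapply(prep, function(p) {
        rows <- unlist(p$by_id[sampled_ids], use.names = FALSE)
        list(data = p$data[rows, , drop = FALSE])
      })
      fitted <- tryCatch(
        fit_prepared(prep_r, covariate_map, horizon, replicate_id = r),
        error = function(e) {
          failures <<- c(failures, conditionMessage(e))
          NULL
        })
      if (!is.null(fitted)) break
    }
    if (is.null(fitted)) {
      stop("bootstrap replicate ", r, " failed after ", max_retries,
           " redraws; failures:\n  ", paste(failures, collapse = "\n  "))
    }
    if (length(failures)) {
      message("bootstrap replicate ", r, ": ", length(failures),
              " resample(s) redrawn")
    }
    sets[[r]] <- fitted
  }
  sets
}
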