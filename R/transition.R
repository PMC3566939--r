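#' Names of the model risk factors used as Cox covariates
#'
#' Smoking status (never/former/current) enters the covariate vector as two
#' indicator variables, \code{smoke_former} and \code{smoke_current}, with
#' never-smokers as the reference category.
#'
#' @return Character vector of the 22 covariate names.
#' @export
risk_factor_names <- function() {
  c("age", "male", "smoke_former", "smoke_current", "bmi", "whr",
    "sbp", "dbp", "hypertension", "total_chol", "hdl", "glucose",
    "creatinine", "diabetes", "angina", "atrial_fib", "claudication",
    "tia", "prevalent_cvd", "fam_hist_mi", "fam_hist_cvd", "abi")
}

#' Expand a cohort table into the numeric covariate matrix
#'
#' Converts the categorical \code{smoking} column into the two indicator
#' covariates and returns the cohort as a numeric matrix whose columns are
#' \code{risk_factor_names()}.
#'
#' @param cohort Data frame with one row per individual (see
#'   \code{\link{read_cohort}} for the column contract).
#' @return Numeric matrix, one row per individual, 22 named columns.
#' @export
profile_covariates <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (!"smoking" %in% names(cohort)) {
    stop("cohort is missing required column 'smoking'")
  }
  smoking <- as.character(cohort$smoking)
  bad <- !smoking %in% c("never", "former", "current")
  if (any(bad)) {
    stop("invalid smoking category: ", paste(unique(smoking[bad]), collapse = ", "))
  }
  covs <- setdiff(risk_factor_names(), c("smoke_former", "smoke_current"))
  missing <- setdiff(covs, names(cohort))
  if (length(missing)) {
    stop("cohort is missing required column(s): ", paste(missing, collapse = ", "))
  }
  x <- as.matrix(cohort[covs])
  storage.mode(x) <- "double"
  out <- cbind(x,
               smoke_former  = as.numeric(smoking == "former"),
               smoke_current = as.numeric(smoking == "current"))
  out[, risk_factor_names(), drop = FALSE]
}

#' Construct a centered Cox transition function
#'
#' One state-to-state hazard of the model: a coefficient vector \eqn{\beta},
#' centering means \eqn{\bar x} and an annual centered cumulative baseline
#' hazard \eqn{H_0(t)} given at integer years \eqn{0..T}. The baseline
#' hazard is "centered": it is the cumulative hazard of an individual whose
#' covariates equal \eqn{\bar x}, so that the hazard of any individual is
#' \eqn{dH_0(t)\,e^{\beta'(x - \bar x)}}.
#'
#' @param source Source state label (must not be absorbing).
#' @param event Event type; the destination follows via
#'   \code{\link{transition_target}}.
#' @param coefficients Named numeric vector \eqn{\beta}.
#' @param means Named numeric vector \eqn{\bar x}; must have exactly the
#'   same names as \code{coefficients}.
#' @param baseline_cum_hazard Numeric vector \eqn{H_0(0), \dots, H_0(T)};
#'   must start at 0 and be nondecreasing.
#' @param se Optional named numeric vector of coefficient standard errors
#'   (carried by fitted transitions; not part of the file format).
#' @return Object of class \code{cvd_transition}.
#' @export
cox_transition <- function(source, event, coefficients, means,
                           baseline_cum_hazard, se = NULL) {
  if (is_absorbing(source)) {
    stop("source state '", source, "' is absorbing and has no outgoing transitions")
  }
  target <- transition_target(source, event)
  coefficients <- unlist(coefficients)
  means <- unlist(means)
  if (is.null(names(coefficients)) || is.null(names(means)) ||
      !setequal(names(coefficients), names(means))) {
    stop("coefficients and means must be named and share an identical key set")
  }
  means <- means[names(coefficients)]
  h0 <- as.numeric(baseline_cum_hazard)
  if (length(h0) < 2 || abs(h0[1]) > 1e-12) {
    stop("baseline_cum_hazard must start at H0(0) = 0 and cover at least year 1")
  }
  if (any(diff(h0) < -1e-12)) stop("baseline_cum_hazard must be nondecreasing")
  if (any(!is.finite(c(coefficients, means, h0)))) {
    stop("non-finite value in transition function")
  }
  h0[1] <- 0
  if (!is.null(se)) se <- unlist(se)[names(coefficients)]
  structure(
    list(source = source, event = event, target = target,
         coefficients = coefficients, means = means,
         baseline_cum_hazard = h0, se = se),
    class = "cvd_transition"
  )
}

#' @export
print.cvd_transition <- function(x, ...) {
  cat(sprintf("<cvd_transition> %s -> %s (event %s)\n", x$source, x$target, x$event))
  cat(sprintf("  %d covariates; H0 over years 0..%d, H0(T) = %.4f\n",
              length(x$coefficients), length(x$baseline_cum_hazard) - 1L,
              max(x$baseline_cum_hazard)))
  invisible(x)
}

#' Centered linear predictor of a transition function
#'
#' Computes \eqn{\sum_k \beta_k (x_k - \bar x_k)} for one risk profile.
#'
#' @param profile Named numeric vector (or one-row data frame / list) giving
#'   the covariate values; must supply every covariate named in
#'   \code{fn$coefficients}.
#' @param fn A \code{\link{cox_transition}}.
#' @return The linear predictor (scalar).
#' @export
#' @examples
#' fn <- cox_transition("WELL", "CHD", c(age = 0.5), c(age = 60), c(0, 0.01))
#' linear_predictor(c(age = 62), fn)  # 0.5 * (62 - 60) = 1
linear_predictor <- function(profile, fn) {
  stopifnot(inherits(fn, "cvd_transition"))
  profile <- unlist(profile)
  wanted <- names(fn$coefficients)
  missing <- setdiff(wanted, names(profile))
  if (length(missing)) {
    stop("profile is missing covariate(s): ", paste(missing, collapse = ", "))
  }
  x <- as.numeric(profile[wanted])
  if (any(!is.finite(x))) {
    stop("non-finite covariate value(s): ",
         paste(wanted[!is.finite(x)], collapse = ", "))
  }
  sum(fn$coefficients * (x - fn$means))
}

# increment of the centered cumulative baseline hazard over cycle
# (year, year + 1]; errors rather than extrapolating beyond the H0 domain
delta_h0 <- function(fn, year) {
  h0 <- fn$baseline_cum_hazard
  if (any(year < 0) || any(year + 2 > length(h0))) {
    stop("cycle year ", paste(year[year + 2 > length(h0) | year < 0], collapse = ", "),
         " outside the domain of H0 (years 0..", length(h0) - 1L,
         "); no extrapolation is performed")
  }
  h0[year + 2] - h0[year + 1]
}

#' Annual transition probability from a Cox transition function
#'
#' The probability that the transition occurs during cycle
#' \eqn{(year, year+1]} for a given profile, using the survival identity
#' \eqn{p = 1 - \exp(-\Delta H_0 \, e^{lp})} with
#' \eqn{\Delta H_0 = H_0(year+1) - H_0(year)}.
#'
#' @inheritParams linear_predictor
#' @param year Integer cycle index (0-based: \code{year = 0} is the first
#'   simulated year); \code{year + 1} must lie within the domain of H0.
#' @return Probability in \eqn{[0, 1]}.
#' @export
cycle_probability <- function(fn, profile, year) {
  lp <- linear_predictor(profile, fn)
  dh <- delta_h0(fn, year)
  -expm1(-dh * exp(lp))
}

#' Resolve competing transitions within one cycle
#'
#' Several transitions compete for the same cycle. Given the cycle
#' cause-specific cumulative hazards \eqn{h_c = \Delta H_{0,c}\, e^{lp_c}},
#' the probability of leaving the state is \eqn{1 - \exp(-\sum_c h_c)} and,
#' conditional on leaving, the destination is drawn proportionally to
#' \eqn{h_c}. This is the exact distribution of the first event of competing
#' constant-rate processes observed over one cycle. A single uniform draw
#' \code{u} decides both questions, so the outcome is deterministic given
#' \code{u}.
#'
#' @param cause_hazards Named nonnegative numeric vector of cycle cumulative
#'   hazards, one per competing event type.
#' @param u A single uniform(0,1) draw.
#' @return The name of the chosen event, or \code{"stay"}.
#' @export
#' @examples
#' resolve_competing(c(CHD = 0, STROKE = 0), u = 0.5)  # "stay"
resolve_competing <- function(cause_hazards, u) {
  h <- unlist(cause_hazards)
  if (any(!is.finite(h)) || any(h < 0)) {
    stop("cause hazards must be finite and nonnegative")
  }
  tot <- sum(h)
  if (tot == 0) return("stay")
  p_any <- -expm1(-tot)
  if (u >= p_any) return("stay")
  # conditional destination: reuse u rescaled to (0, 1)
  v <- u / p_any
  cum <- cumsum(h) / tot
  names(h)[which(v <= cum)[1]]
}
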