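#' Cohort specification for the synthetic generator
#'
#' Describes the marginal distributions (and a latent Gaussian-copula
#' correlation structure) of the 21 baseline risk factors, from which
#' \code{\link{generate_profiles}} draws cohorts. Continuous factors are
#' normal or (for right-skewed laboratory values) log-normal, parameterised
#' by their target mean and central 95% range; binary factors by their
#' prevalence; smoking by the three category probabilities.
#'
#' @param name Label for the spec.
#' @param n Default cohort size.
#' @param continuous Named list; each element
#'   \code{list(dist = "normal"|"lognormal", mean =, lo =, hi =)} with
#'   \code{lo}/\code{hi} the 2.5th/97.5th percentiles.
#' @param binary Named numeric vector of prevalences in (0, 1).
#' @param smoking Probabilities \code{c(never =, former =, current =)}.
#' @param correlation Latent correlation matrix over
#'   \code{c(names(continuous), "male", "smoking", names(binary) without
#'   male)}; must be symmetric positive-definite.
#' @param age_floor Minimum age (recruitment lower bound).
#' @param prevalent_split Probabilities over the baseline state of a
#'   prevalent-CVD individual. A share stays in \code{WELL}: prevalent CVD
#'   is a broader clinical history (e.g. prior revascularisation) than the
#'   model's post-event states, which is also what makes the
#'   \code{prevalent_cvd} covariate estimable within the WELL risk set.
#' @return Object of class \code{cvd_cohort_spec}.
#' @export
cohort_spec <- function(name, n, continuous, binary, smoking, correlation,
                        age_floor = 45,
                        prevalent_split = c(WELL = 0.35, CHD = 0.40,
                                            STROKE = 0.20,
                                            CHD_AND_STROKE = 0.05)) {
  stopifnot(abs(sum(smoking) - 1) < 1e-8, all(binary > 0 & binary < 1),
            abs(sum(prevalent_split) - 1) < 1e-8)
  dims <- latent_dims(continuous, binary)
  if (!identical(dim(correlation), c(length(dims), length(dims)))) {
    stop("correlation matrix must be ", length(dims), " x ", length(dims),
         " over: ", paste(dims, collapse = ", "))
  }
  if (max(abs(correlation - t(correlation))) > 1e-10) {
    stop("correlation matrix must be symmetric")
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("correlation matrix is not positive-definite (min eigenvalue ",
         format(min(ev)), "); consider projecting to the nearest ",
         "positive-definite matrix, e.g. Matrix::nearPD()")
  }
  structure(list(name = name, n = n, continuous = continuous,
                 binary = binary, smoking = smoking,
                 correlation = correlation, age_floor = age_floor,
                 prevalent_split = prevalent_split),
            class = "cvd_cohort_spec")
}

latent_dims <- function(continuous, binary) {
  c(names(continuous), "male", "smoking", setdiff(names(binary), "male"))
}

# build a correlation matrix from a pair list, validating PD via cohort_spec
build_correlation <- function(dims, pairs) {
  r <- diag(length(dims))
  dimnames(r) <- list(dims, dims)
  for (p in pairs) {
    r[p[[1]], p[[2]]] <- r[p[[2]], p[[1]]] <- p[[3]]
  }
  r
}

default_correlation_pairs <- function() {
  list(
    list("age", "sbp", 0.25), list("age", "creatinine", 0.15),
    list("age", "abi", -0.20), list("age", "atrial_fib", 0.20),
    list("age", "tia", 0.15), list("age", "prevalent_cvd", 0.25),
    list("sbp", "dbp", 0.60), list("sbp", "hypertension", 0.55),
    list("dbp", "hypertension", 0.30), list("sbp", "bmi", 0.20),
    list("sbp", "abi", -0.15),
    list("bmi", "whr", 0.45), list("bmi", "glucose", 0.25),
    list("bmi", "diabetes", 0.20),
    list("glucose", "diabetes", 0.60),
    list("total_chol", "hdl", -0.15),
    list("male", "whr", 0.45), list("male", "creatinine", 0.40),
    list("male", "hdl", -0.30), list("male", "smoking", 0.20),
    list("prevalent_cvd", "angina", 0.50),
    list("prevalent_cvd", "tia", 0.40),
    list("prevalent_cvd", "claudication", 0.30),
    list("angina", "claudication", 0.15),
    list("abi", "claudication", -0.30),
    list("fam_hist_mi", "fam_hist_cvd", 0.60)
  )
}

#' Built-in cohort specifications
#'
#' \code{rotterdam_like_spec()} emulates the published baseline profile of
#' an elderly Dutch population-based cohort (mean age 69, 39% male, 17.8%
#' prevalent CVD); \code{epic_like_spec()} a younger, healthier British one
#' (mean age 59.2, 45% male, 4.3% prevalent CVD). Ankle-brachial index is
#' not tabulated in the source material; a plausible distribution is used.
#'
#' @param n Cohort size (defaults: 3,478 and 25,492).
#' @return A \code{\link{cohort_spec}}.
#' @export
rotterdam_like_spec <- function(n = 3478) {
  continuous <- list(
    age        = list(dist = "normal",    mean = 69.0,  lo = 62,    hi = 75),
    bmi        = list(dist = "normal",    mean = 26.3,  lo = 23.8,  hi = 28.5),
    whr        = list(dist = "normal",    mean = 0.91,  lo = 0.84,  hi = 0.97),
    sbp        = list(dist = "normal",    mean = 140.0, lo = 124,   hi = 155),
    dbp        = list(dist = "normal",    mean = 74.1,  lo = 66,    hi = 82),
    total_chol = list(dist = "normal",    mean = 6.67,  lo = 5.8,   hi = 7.4),
    hdl        = list(dist = "normal",    mean = 1.34,  lo = 1.1,   hi = 1.5),
    glucose    = list(dist = "lognormal", mean = 6.93,  lo = 5.5,   hi = 7.5),
    creatinine = list(dist = "lognormal", mean = 82.5,  lo = 72,    hi = 91),
    abi        = list(dist = "normal",    mean = 1.05,  lo = 0.75,  hi = 1.30)
  )
  binary <- c(male = 0.39, hypertension = 0.364, diabetes = 0.107,
              angina = 0.104, atrial_fib = 0.025, claudication = 0.021,
              tia = 0.051, prevalent_cvd = 0.178, fam_hist_mi = 0.163,
              fam_hist_cvd = 0.230)
  smoking <- c(never = 0.345, former = 0.419, current = 0.236)
  corr <- build_correlation(latent_dims(continuous, binary),
                            default_correlation_pairs())
  cohort_spec("rotterdam_like", n, continuous, binary, smoking, corr,
              age_floor = 55)
}

#' @rdname rotterdam_like_spec
#' @export
epic_like_spec <- function(n = 25492) {
  continuous <- list(
    age        = list(dist = "normal",    mean = 59.2,  lo = 51,    hi = 67),
    bmi        = list(dist = "normal",    mean = 26.3,  lo = 23.7,  hi = 28.4),
    whr        = list(dist = "normal",    mean = 0.86,  lo = 0.78,  hi = 0.93),
    sbp        = list(dist = "normal",    mean = 135.5, lo = 122.5, hi = 146.5),
    dbp        = list(dist = "normal",    mean = 82.5,  lo = 74.5,  hi = 89.5),
    total_chol = list(dist = "normal",    mean = 6.19,  lo = 5.4,   hi = 6.9),
    hdl        = list(dist = "normal",    mean = 1.41,  lo = 1.1,   hi = 1.6),
    glucose    = list(dist = "lognormal", mean = 6.67,  lo = 5.5,   hi = 7.3),
    creatinine = list(dist = "lognormal", mean = 86.7,  lo = 76,    hi = 97),
    abi        = list(dist = "normal",    mean = 1.10,  lo = 0.85,  hi = 1.35)
  )
  binary <- c(male = 0.45, hypertension = 0.299, diabetes = 0.122,
              angina = 0.092, atrial_fib = 0.029, claudication = 0.015,
              tia = 0.048, prevalent_cvd = 0.043, fam_hist_mi = 0.184,
              fam_hist_cvd = 0.233)
  smoking <- c(never = 0.460, former = 0.423, current = 0.117)
  corr <- build_correlation(latent_dims(continuous, binary),
                            default_correlation_pairs())
  cohort_spec("epic_like", n, continuous, binary, smoking, corr,
              age_floor = 45)
}

#' Draw a cohort of correlated risk-factor profiles
#'
#' Gaussian copula: a multivariate standard normal draw with the spec's
#' latent correlation matrix is mapped through the marginal distributions —
#' normal or log-normal quantiles for continuous factors, thresholding at
#' the prevalence quantile for binary factors, two ordered thresholds for
#' the smoking categories. Age is truncated below at the spec's recruitment
#' floor. Prevalent-CVD individuals are assigned a baseline disease state
#' (CHD / STROKE / CHD_AND_STROKE) according to the spec's split.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param n Cohort size (default \code{spec$n}).
#' @param seed Integer seed; the draw is deterministic given it.
#' @return Cohort data frame (one row per individual) with an \code{id}
#'   column, the 21 risk factors (smoking as a category column) and
#'   \code{baseline_state}.
#' @export
generate_profiles <- function(spec, n = spec$n, seed = 1) {
  stopifnot(inherits(spec, "cvd_cohort_spec"))
  set.seed(as.integer(seed))
  dims <- latent_dims(spec$continuous, spec$binary)
  z <- matrix(stats::rnorm(n * length(dims)), n) %*% chol(spec$correlation)
  colnames(z) <- dims

  out <- data.frame(id = seq_len(n))
  for (f in names(spec$continuous)) {
    m <- spec$continuous[[f]]
    sig <- if (m$dist == "lognormal") (log(m$hi) - log(m$lo)) / (2 * stats::qnorm(0.975))
           else (m$hi - m$lo) / (2 * stats::qnorm(0.975))
    out[[f]] <- if (m$dist == "lognormal") {
      exp(log(m$mean) - sig^2 / 2 + sig * z[, f])
    } else {
      m$mean + sig * z[, f]
    }
  }
  out$age <- pmax(out$age, spec$age_floor)
  # physiological floors for the remaining continuous factors
  for (f in setdiff(names(spec$continuous), "age")) {
    out[[f]] <- pmax(out[[f]], 0.01)
  }
  for (f in names(spec$binary)) {
    out[[f]] <- as.integer(z[, f] > stats::qnorm(1 - spec$binary[[f]]))
  }
  cuts <- stats::qnorm(cumsum(spec$smoking))
  out$smoking <- c("never", "former", "current")[
    1L + (z[, "smoking"] > cuts[1]) + (z[, "smoking"] > cuts[2])]

  out$baseline_state <- "WELL"
  prev <- which(out$prevalent_cvd == 1)
  if (length(prev)) {
    out$baseline_state[prev] <- sample(names(spec$prevalent_split),
                                       length(prev), replace = TRUE,
                                       prob = spec$prevalent_split)
  }
  out[c("id", setdiff(risk_factor_names(),
                      c("smoke_former", "smoke_current")),
        "smoking", "baseline_state")]
}

# ---- ground-truth parameter sets -------------------------------------------

truth_coefficients <- function() {
  list(
    "WELL->CHD" = c(age = 0.055, male = 0.45, smoke_current = 0.50,
                    smoke_former = 0.20, sbp = 0.010, total_chol = 0.16,
                    hdl = -0.45, diabetes = 0.50, prevalent_cvd = 0.60),
    "WELL->STROKE" = c(age = 0.070, male = 0.25, smoke_current = 0.40,
                       sbp = 0.014, hypertension = 0.30, atrial_fib = 0.80,
                       diabetes = 0.40, prevalent_cvd = 0.50),
    "WELL->CVD_DEATH" = c(age = 0.090, male = 0.40, smoke_current = 0.50,
                          sbp = 0.010, total_chol = 0.10, diabetes = 0.50,
                          prevalent_cvd = 0.80),
    "WELL->NON_CVD_DEATH" = c(age = 0.095, male = 0.45, smoke_current = 0.70,
                              smoke_former = 0.25, bmi = -0.02),
    "CHD->STROKE" = c(age = 0.060, male = 0.20, sbp = 0.012),
    "CHD->CVD_DEATH" = c(age = 0.080, male = 0.35, diabetes = 0.40),
    "CHD->NON_CVD_DEATH" = c(age = 0.090, smoke_current = 0.60),
    "STROKE->CHD" = c(age = 0.050, male = 0.40),
    "STROKE->CVD_DEATH" = c(age = 0.080, male = 0.30),
    "STROKE->NON_CVD_DEATH" = c(age = 0.090),
    "CHD_AND_STROKE->CVD_DEATH" = c(age = 0.080),
    "CHD_AND_STROKE->NON_CVD_DEATH" = c(age = 0.090)
  )
}

# annual centered baseline-hazard increments of the older-cohort truth,
# chosen so that 13-year incidences fall near published magnitudes
# (CHD ~ 10.6%, stroke ~ 9.9%, CVD death ~ 14.2%, non-CVD death ~ 24.3%)
truth_base_rates <- function() {
  c("WELL->CHD" = 0.0077, "WELL->STROKE" = 0.0056,
    "WELL->CVD_DEATH" = 0.0035, "WELL->NON_CVD_DEATH" = 0.0098,
    "CHD->STROKE" = 0.0130, "CHD->CVD_DEATH" = 0.0234,
    "CHD->NON_CVD_DEATH" = 0.0207, "STROKE->CHD" = 0.0133,
    "STROKE->CVD_DEATH" = 0.0301, "STROKE->NON_CVD_DEATH" = 0.0207,
    "CHD_AND_STROKE->CVD_DEATH" = 0.0469,
    "CHD_AND_STROKE->NON_CVD_DEATH" = 0.0249)
}

spec_means <- function(spec) {
  m <- vapply(spec$continuous, function(x) x$mean, numeric(1))
  out <- c(m, spec$binary,
           smoke_former = unname(spec$smoking["former"]),
           smoke_current = unname(spec$smoking["current"]))
  out[risk_factor_names()]
}

build_truth <- function(spec, rates, horizon) {
  coefs <- truth_coefficients()
  means <- spec_means(spec)
  trans <- lapply(names(coefs), function(k) {
    parts <- strsplit(k, "->", fixed = TRUE)[[1]]
    b <- coefs[[k]]
    cox_transition(parts[1], parts[2], coefficients = b,
                   means = means[names(b)],
                   baseline_cum_hazard = rates[[k]] * (0:horizon))
  })
  parameter_set(trans, replicate_id = 0L)
}

#' Ground-truth parameter sets of the synthetic world
#'
#' \code{rotterdam_truth()} is the data-generating model of the
#' older-cohort world: fixed coefficients, centering means equal to the
#' \code{\link{rotterdam_like_spec}} targets, constant annual baseline
#' hazard increments. \code{epic_truth()} shares the same coefficients (the
#' relative strengths of the risk-factor associations are identical in both
#' worlds, which is exactly the situation recalibration assumes) but has
#' its own centering means and genuinely lower baseline hazards, so that a
#' model calibrated in the older world overestimates incidence in the
#' younger one until it is recalibrated.
#'
#' @param horizon Last year of the baseline-hazard grid.
#' @return A \code{\link{parameter_set}}.
#' @export
rotterdam_truth <- function(horizon = 15) {
  build_truth(rotterdam_like_spec(), truth_base_rates(), horizon)
}

#' @rdname rotterdam_truth
#' @export
epic_truth <- function(horizon = 15) {
  spec_r <- rotterdam_like_spec()
  spec_e <- epic_like_spec()
  coefs <- truth_coefficients()
  means_r <- spec_means(spec_r)
  means_e <- spec_means(spec_e)
  # hazard of a given covariate vector x in the younger world is a fixed
  # fraction (75%) of the older world's: scale the centered baseline
  # accordingly, so an unrecalibrated older-world model overestimates
  # younger-world incidence by ~1/0.75
  scale <- c(CHD = 0.75, STROKE = 0.75, CVD_DEATH = 0.75,
             NON_CVD_DEATH = 0.75)
  rates_r <- truth_base_rates()
  rates_e <- rates_r
  for (k in names(rates_e)) {
    b <- coefs[[k]]
    ev <- strsplit(k, "->", fixed = TRUE)[[1]][2]
    shift <- sum(b * (means_e[names(b)] - means_r[names(b)]))
    rates_e[k] <- rates_r[k] * scale[[ev]] * exp(shift)
  }
  build_truth(spec_e, rates_e, horizon)
}

# ---- ground-truth follow-up ------------------------------------------------

#' Simulate ground-truth event histories for a cohort
#'
#' Continuous-time competing-risks sampling from a truth parameter set:
#' within each year the cause-specific hazard rates are constant
#' (\eqn{\lambda_c = \Delta H_{0,c} e^{lp_c}}, with covariates aged/drifted
#' to the start of the year); event times are drawn exponentially, state
#' changes take effect immediately and update the hazards for the rest of
#' the year. Event years are the integer year within which the event fell.
#'
#' @param cohort Cohort data frame (with \code{baseline_state}).
#' @param truth A \code{\link{parameter_set}} covering the full topology.
#' @param horizon Follow-up years; everyone still alive is
#'   administratively censored at \code{horizon}.
#' @param seed Integer seed.
#' @param drift The \code{\link{drift_model}} of the truth.
#' @return List with \code{events} — one row per individual: first-event
#'   year per tracked event type (NA if none), death cause, continuous exit
#'   time from the baseline state — and \code{records} — the long
#'   per-transition survival records (columns \code{id},
#'   \code{transition_source}, \code{transition_target},
#'   \code{time_years}, \code{event}) for transitions out of each
#'   individual's baseline state, ready for \code{\link{fit_all_transitions}}.
#' @export
generate_followup <- function(cohort, truth, horizon = 13, seed = 1,
                              drift = default_drift()) {
  stopifnot(inherits(truth, "cvd_parameter_set"))
  cohort <- ensure_baseline_state(cohort)
  set.seed(as.integer(seed))
  n <- nrow(cohort)
  state <- cohort$baseline_state
  pc <- as.numeric(cohort$prevalent_cvd)
  evs <- event_types()
  fe <- matrix(NA_integer_, n, 4, dimnames = list(NULL, evs))
  exit_time <- rep(NA_real_, n)    # continuous time of first exit from the
  exit_target <- rep(NA_character_, n)  # baseline state
  topo <- transition_topology()

  for (y in seq_len(horizon)) {
    pre <- precompute_year(cohort, truth, drift, y)
    t_in <- rep(0, n)
    pending <- which(!is_absorbing(state))
    while (length(pending)) {
      nxt <- integer(0)
      pending_state <- state[pending]  # freeze: movers re-enter via nxt only
      for (src in c("WELL", "CHD", "STROKE", "CHD_AND_STROKE")) {
        w <- pending[pending_state == src]
        if (!length(w)) next
        events <- topo$event[topo$source == src]
        keys <- transition_key(src, events)
        lam <- matrix(0, length(w), length(keys))
        for (j in seq_along(keys)) {
          k <- keys[j]
          lam[, j] <- pre$dh0[[k]] *
            exp(pre$lp0[[k]][w] + pre$bpcvd[k] * pc[w])
        }
        tot <- rowSums(lam)
        tau <- ifelse(tot > 0, stats::rexp(length(w)) / tot, Inf)
        hit <- t_in[w] + tau < 1
        if (!any(hit)) next
        wm <- w[hit]
        pick <- lam[hit, , drop = FALSE] / tot[hit]
        if (ncol(pick) > 1) {
          for (j in 2:ncol(pick)) pick[, j] <- pick[, j] + pick[, j - 1]
          v <- stats::runif(length(wm))
          dest_j <- 1L + rowSums(v > pick[, -ncol(pick), drop = FALSE])
        } else dest_j <- rep(1L, length(wm))
        ev <- events[dest_j]
        t_event <- y - 1 + t_in[wm] + tau[hit]
        first_exit <- is.na(exit_time[wm]) &
          state[wm] == cohort$baseline_state[wm]
        exit_time[wm[first_exit]] <- t_event[first_exit]
        exit_target[wm[first_exit]] <-
          topo$target[match(paste(src, ev[first_exit]),
                            paste(topo$source, topo$event))]
        for (e in unique(ev)) {
          we <- wm[ev == e]
          col <- match(e, evs)
          unset <- is.na(fe[we, col])
          fe[we[unset], col] <- y
        }
        state[wm] <- topo$target[match(paste(src, ev),
                                       paste(topo$source, topo$event))]
        pc[wm[ev %in% c("CHD", "STROKE")]] <- 1
        t_in[wm] <- t_in[wm] + tau[hit]
        nxt <- c(nxt, wm[!is_absorbing(state[wm])])
      }
      pending <- nxt
    }
  }

  death_cause <- ifelse(!is.na(fe[, "CVD_DEATH"]), "CVD_DEATH",
                        ifelse(!is.na(fe[, "NON_CVD_DEATH"]),
                               "NON_CVD_DEATH", NA))
  events_df <- data.frame(
    id = cohort$id,
    chd_year = fe[, "CHD"], stroke_year = fe[, "STROKE"],
    cvd_death_year = fe[, "CVD_DEATH"],
    non_cvd_death_year = fe[, "NON_CVD_DEATH"],
    death_cause = death_cause,
    followup_years = horizon)

  # long per-transition records out of the baseline state
  rec <- list()
  for (i in seq_len(nrow(topo))) {
    src <- topo$source[i]; tgt <- topo$target[i]
    who <- which(cohort$baseline_state == src)
    if (!length(who)) next
    tm <- ifelse(is.na(exit_time[who]), horizon, exit_time[who])
    rec[[i]] <- data.frame(
      id = cohort$id[who], transition_source = src,
      transition_target = tgt, time_years = tm,
      event = as.integer(!is.na(exit_target[who]) & exit_target[who] == tgt))
  }
  list(events = events_df, records = do.call(rbind, rec))
}

# year-y hazard pieces for the generator: linear predictors (excluding the
# dynamic prevalent-CVD term) and the annual baseline increments
precompute_year <- function(cohort, truth, drift, y) {
  prof_y <- update_profile(cohort, drift, y - 1L)
  x <- profile_covariates(prof_y)
  keys <- names(truth$transitions)
  lp0 <- list(); bpcvd <- stats::setNames(numeric(length(keys)), keys)
  dh0 <- stats::setNames(numeric(length(keys)), keys)
  for (k in keys) {
    fn <- truth$transitions[[k]]
    b <- fn$coefficients
    stat_names <- setdiff(names(b), "prevalent_cvd")
    v <- as.vector(x[, stat_names, drop = FALSE] %*% b[stat_names]) -
      sum(b[stat_names] * fn$means[stat_names])
    if ("prevalent_cvd" %in% names(b)) {
      v <- v - b[["prevalent_cvd"]] * fn$means[["prevalent_cvd"]]
      bpcvd[k] <- b[["prevalent_cvd"]]
    }
    lp0[[k]] <- v
    dh0[k] <- delta_h0(fn, y - 1L)
  }
  list(lp0 = lp0, bpcvd = bpcvd, dh0 = dh0)
}
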