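#' Simulation configuration
#'
#' Defaults follow the reference three-level design: 100 parameter-
#' uncertainty replicates (outer loop), 2,000 risk-factor profiles drawn
#' from the cohort (middle loop, heterogeneity), and 200 random walks per
#' profile (inner loop, stochastic uncertainty), over a 13-year horizon.
#'
#' @param n_outer Outer-loop replicates (parameter uncertainty).
#' @param n_profiles Profiles sampled with replacement per replicate;
#'   ignored when \code{aggregate_by_individual} is \code{TRUE}, in which
#'   case every individual in the cohort is simulated.
#' @param n_walks Random walks per profile.
#' @param horizon Simulated years.
#' @param seed Master seed; all randomness derives from it.
#' @param drift_enabled Apply 5-yearly risk-factor drift during simulation.
#' @param aggregate_by_individual Iterate all individuals instead of
#'   sampling profiles (used for stratified analyses).
#' @return Object of class \code{cvd_sim_config}.
#' @export
sim_config <- function(n_outer = 100, n_profiles = 2000, n_walks = 200,
                       horizon = 13, seed = 1, drift_enabled = TRUE,
                       aggregate_by_individual = FALSE) {
  stopifnot(n_outer >= 1, n_profiles >= 1, n_walks >= 1, horizon >= 1)
  structure(list(n_outer = as.integer(n_outer),
                 n_profiles = as.integer(n_profiles),
                 n_walks = as.integer(n_walks),
                 horizon = as.integer(horizon),
                 seed = as.integer(seed),
                 drift_enabled = isTRUE(drift_enabled),
                 aggregate_by_individual = isTRUE(aggregate_by_individual)),
            class = "cvd_sim_config")
}

#' Five-yearly risk-factor drift
#'
#' Risk factors show secular trends with ageing; the model applies an
#' additive change to each continuous factor every 5 simulated years
#' (binary factors are never drifted; age advances every year regardless).
#' Values are clamped at physiological floors.
#'
#' @param slopes Named numeric vector: additive change per 5-year update.
#' @param floors Named numeric vector of lower clamps.
#' @return Object of class \code{cvd_drift}.
#' @export
drift_model <- function(slopes,
                        floors = c(bmi = 12, whr = 0.5, sbp = 70, dbp = 40,
                                   total_chol = 1, hdl = 0.3, glucose = 2,
                                   creatinine = 30, abi = 0.3)) {
  slopes <- unlist(slopes)
  allowed <- c("bmi", "whr", "sbp", "dbp", "total_chol", "hdl", "glucose",
               "creatinine", "abi")
  bad <- setdiff(names(slopes), allowed)
  if (length(bad)) {
    stop("drift is only defined for continuous factors; offending: ",
         paste(bad, collapse = ", "))
  }
  structure(list(slopes = slopes, floors = floors), class = "cvd_drift")
}

#' @rdname drift_model
#' @export
zero_drift <- function() drift_model(c(total_chol = 0))

#' Default drift: plausible 5-year trends in an ageing cohort
#'
#' Total cholesterol declines with age while systolic pressure and glucose
#' rise; magnitudes are typical of elderly European cohort follow-up and
#' are configuration values, not estimates.
#'
#' @return A \code{\link{drift_model}}.
#' @export
default_drift <- function() {
  drift_model(c(total_chol = -0.15, hdl = -0.02, sbp = 3, dbp = -1.5,
                bmi = -0.3, whr = 0.01, glucose = 0.15, creatinine = 3,
                abi = -0.02))
}

#' Age and drift a baseline profile to a given simulation year
#'
#' Pure function of the baseline profile: age advances by \code{sim_year}
#' years; every continuous factor with a drift slope changes additively at
#' each completed 5-year mark (\code{floor(sim_year / 5)} updates). Two
#' consecutive 5-year updates therefore equal one 10-year update with
#' doubled change. Drifted values are clamped at the drift model's floors.
#'
#' @param profile Cohort data frame (one or more rows).
#' @param drift A \code{\link{drift_model}}.
#' @param sim_year Completed simulated years (0 = baseline); either a
#'   scalar or one value per profile row.
#' @return The profile(s) as of \code{sim_year}.
#' @export
update_profile <- function(profile, drift, sim_year) {
  stopifnot(inherits(drift, "cvd_drift"), all(sim_year >= 0),
            length(sim_year) %in% c(1L, nrow(profile)))
  out <- profile
  out$age <- out$age + sim_year
  steps <- floor(sim_year / 5)
  if (any(steps > 0)) {
    for (f in names(drift$slopes)) {
      if (!f %in% names(out)) next
      v <- out[[f]] + steps * drift$slopes[[f]]
      fl <- drift$floors[[f]]
      if (!is.null(fl) && any(v < fl)) {
        message("drift clamped ", sum(v < fl), " value(s) of ", f,
                " at floor ", fl)
        v <- pmax(v, fl)
      }
      out[[f]] <- v
    }
  }
  out
}

# ---- internal vectorized stepping ------------------------------------------

# Precompute, per transition, the linear predictor of every (profile, year)
# with the prevalent-CVD contribution split out: lp = LP0 + beta_pcvd * pcvd.
# Returns list(lp0 = list of n x horizon matrices, bpcvd = named numeric,
# dh0 = list of length-horizon vectors).
precompute_replicate <- function(cohort, params, drift, config) {
  horizon <- config$horizon
  keys <- names(params$transitions)
  n <- nrow(cohort)
  lp0 <- lapply(keys, function(k) matrix(0, n, horizon))
  names(lp0) <- keys
  bpcvd <- stats::setNames(numeric(length(keys)), keys)
  dh0 <- lapply(keys, function(k) {
    fn <- params$transitions[[k]]
    vapply(seq_len(horizon), function(y) delta_h0(fn, y - 1L), numeric(1))
  })
  names(dh0) <- keys

  eff_drift <- if (config$drift_enabled) drift else zero_drift()
  for (y in seq_len(horizon)) {
    prof_y <- update_profile(cohort, eff_drift, y - 1L)
    x <- profile_covariates(prof_y)
    for (k in keys) {
      fn <- params$transitions[[k]]
      b <- fn$coefficients
      stat_names <- setdiff(names(b), "prevalent_cvd")
      v <- as.vector(x[, stat_names, drop = FALSE] %*% b[stat_names]) -
        sum(b[stat_names] * fn$means[stat_names])
      if ("prevalent_cvd" %in% names(b)) {
        v <- v - b[["prevalent_cvd"]] * fn$means[["prevalent_cvd"]]
        bpcvd[k] <- b[["prevalent_cvd"]]
      }
      lp0[[k]][, y] <- v
    }
  }
  list(lp0 = lp0, bpcvd = bpcvd, dh0 = dh0)
}

# One outer replicate: simulate n_walks walks for each selected profile and
# return the 4 x horizon matrix of cumulative incidences plus (optionally)
# the walker state matrix.
simulate_replicate <- function(cohort, params, config, drift, sel,
                               keep_states = FALSE) {
  horizon <- config$horizon
  pre <- precompute_replicate(cohort[sel, , drop = FALSE], params, drift,
                              config)
  nw <- length(sel) * config$n_walks
  pidx <- rep(seq_along(sel), each = config$n_walks)
  state <- rep(cohort$baseline_state[sel], each = config$n_walks)
  pc <- rep(as.numeric(cohort$prevalent_cvd[sel]), each = config$n_walks)
  evs <- event_types()
  fe <- matrix(NA_integer_, nw, 4, dimnames = list(NULL, evs))
  topo <- transition_topology()
  states_mat <- if (keep_states)
    matrix(NA_character_, nw, horizon + 1L) else NULL
  if (keep_states) states_mat[, 1] <- state

  for (y in seq_len(horizon)) {
    for (src in c("WELL", "CHD", "STROKE", "CHD_AND_STROKE")) {
      w <- which(state == src)
      if (!length(w)) next
      events <- topo$event[topo$source == src]
      keys <- transition_key(src, events)
      h <- matrix(0, length(w), length(keys))
      for (j in seq_along(keys)) {
        k <- keys[j]
        h[, j] <- pre$dh0[[k]][y] *
          exp(pre$lp0[[k]][pidx[w], y] + pre$bpcvd[k] * pc[w])
      }
      tot <- rowSums(h)
      p_any <- -expm1(-tot)
      u <- stats::runif(length(w))
      moved <- u < p_any
      if (!any(moved)) next
      wm <- w[moved]
      v <- u[moved] / p_any[moved]
      cum <- h[moved, , drop = FALSE] / tot[moved]
      if (ncol(cum) > 1) {
        for (j in 2:ncol(cum)) cum[, j] <- cum[, j] + cum[, j - 1]
        dest_j <- 1L + rowSums(v > cum[, -ncol(cum), drop = FALSE])
      } else {
        dest_j <- rep(1L, length(wm))
      }
      ev <- events[dest_j]
      # record first occurrence of each tracked event type
      for (e in unique(ev)) {
        we <- wm[ev == e]
        col <- match(e, evs)
        unset <- is.na(fe[we, col])
        fe[we[unset], col] <- y
      }
      state[wm] <- topo$target[match(paste(src, ev), paste(topo$source, topo$event))]
      pc[wm[ev %in% c("CHD", "STROKE")]] <- 1
    }
    if (keep_states) states_mat[, y + 1L] <- state
  }

  inc <- matrix(0, 4, horizon, dimnames = list(evs, NULL))
  for (i in 1:4) {
    cnt <- tabulate(fe[, i], nbins = horizon)
    inc[i, ] <- cumsum(cnt) / nw
  }
  list(incidence = inc, first_event = fe, states = states_mat)
}

#' Run the three-level nested simulation
#'
#' Outer loop: one linked parameter set per replicate (parameter
#' uncertainty). Middle loop: \code{n_profiles} risk-factor profiles
#' sampled with replacement from the cohort (heterogeneity), or every
#' individual when \code{aggregate_by_individual}. Inner loop:
#' \code{n_walks} random walks per profile (stochastic uncertainty). Within
#' a replicate the cumulative incidence of each tracked event at year
#' \eqn{t} is the proportion of walks whose first event of that type
#' occurred at or before \eqn{t}; the mean and the 2.5th/97.5th percentiles
#' across replicates form the credibility band.
#'
#' @param cohort Cohort data frame; must contain a \code{baseline_state}
#'   column (defaulting to \code{WELL} when absent).
#' @param parameter_sets List of \code{\link{parameter_set}} objects, at
#'   least \code{config$n_outer} of them (a single set is recycled with a
#'   degenerate band).
#' @param config A \code{\link{sim_config}}.
#' @param drift A \code{\link{drift_model}}.
#' @return Object of class \code{cvd_surface}: data frame with columns
#'   \code{event}, \code{year}, \code{mean}, \code{lo}, \code{hi}; the raw
#'   per-replicate incidence array is in \code{attr(x, "raw")}.
#' @export
run_three_level <- function(cohort, parameter_sets, config = sim_config(),
                            drift = default_drift()) {
  if (inherits(parameter_sets, "cvd_parameter_set")) {
    parameter_sets <- list(parameter_sets)
  }
  if (!nrow(cohort)) stop("cohort is empty")
  if (length(parameter_sets) == 1 && config$n_outer > 1) {
    parameter_sets <- rep(parameter_sets, config$n_outer)
  }
  if (length(parameter_sets) < config$n_outer) {
    stop("need at least n_outer = ", config$n_outer,
         " parameter sets, got ", length(parameter_sets))
  }
  cohort <- ensure_baseline_state(cohort)
  n <- nrow(cohort)
  horizon <- config$horizon
  set.seed(config$seed)
  rep_seeds <- sample.int(2147483646L, config$n_outer)

  raw <- array(0, dim = c(config$n_outer, 4, horizon),
               dimnames = list(NULL, event_types(), NULL))
  for (r in seq_len(config$n_outer)) {
    set.seed(rep_seeds[r])
    sel <- if (config$aggregate_by_individual) seq_len(n)
           else sample.int(n, config$n_profiles, replace = TRUE)
    raw[r, , ] <- simulate_replicate(cohort, parameter_sets[[r]], config,
                                     drift, sel)$incidence
  }
  incidence_surface(raw)
}

# build the mean / 2.5% / 97.5% summary data frame from the raw
# replicate x event x year incidence array
incidence_surface <- function(raw) {
  evs <- dimnames(raw)[[2]]
  horizon <- dim(raw)[3]
  df <- do.call(rbind, lapply(seq_along(evs), function(i) {
    m <- raw[, i, , drop = FALSE]
    dim(m) <- dim(raw)[c(1, 3)]
    data.frame(event = evs[i], year = seq_len(horizon),
               mean = colMeans(m),
               lo = apply(m, 2, stats::quantile, probs = 0.025),
               hi = apply(m, 2, stats::quantile, probs = 0.975))
  }))
  rownames(df) <- NULL
  structure(df, raw = raw, class = c("cvd_surface", "data.frame"))
}

ensure_baseline_state <- function(cohort) {
  if (!"baseline_state" %in% names(cohort)) {
    cohort$baseline_state <- "WELL"
  }
  bad <- !cohort$baseline_state %in%
    c("WELL", "CHD", "STROKE", "CHD_AND_STROKE")
  if (any(bad)) stop("invalid baseline_state value(s): ",
                     paste(unique(cohort$baseline_state[bad]), collapse = ", "))
  cohort
}

# ---- scalar walk interface --------------------------------------------------

#' Fresh tracker state
#' @return List with monotone event flags and first-event times.
#' @export
new_trackers <- function() {
  list(had_chd = 0L, had_stroke = 0L,
       time_first_chd = NA_real_, time_first_stroke = NA_real_)
}

#' Advance one individual by one annual cycle
#'
#' Computes the cycle cause-specific hazards of every transition out of the
#' current state for the supplied profile (with the prevalent-CVD covariate
#' switched on once a CHD or stroke event has been tracked), resolves the
#' competing transitions with a single uniform draw, and updates the
#' trackers.
#'
#' @param state Current (non-absorbing) state label.
#' @param profile One-row cohort data frame, already aged/drifted to the
#'   current year (see \code{\link{update_profile}}).
#' @param trackers See \code{\link{new_trackers}}.
#' @param params A \code{\link{parameter_set}}.
#' @param year 0-based cycle index into the baseline hazards.
#' @param u Uniform(0,1) draw (default: one draw from the session RNG).
#' @return List with elements \code{state}, \code{trackers}, \code{event}
#'   (the event type or \code{"stay"}).
#' @export
step_individual <- function(state, profile, trackers, params, year,
                            u = stats::runif(1)) {
  if (is_absorbing(state)) stop("state '", state, "' is absorbing")
  x <- profile_covariates(profile)[1, ]
  x["prevalent_cvd"] <- max(x["prevalent_cvd"],
                            trackers$had_chd, trackers$had_stroke)
  topo <- transition_topology()
  events <- topo$event[topo$source == state]
  h <- vapply(events, function(e) {
    fn <- get_transition(params, state, e)
    delta_h0(fn, year) * exp(linear_predictor(x, fn))
  }, numeric(1))
  ev <- resolve_competing(h, u)
  if (ev == "stay") {
    return(list(state = state, trackers = trackers, event = "stay"))
  }
  new_state <- transition_target(state, ev)
  if (ev == "CHD" && !trackers$had_chd) {
    trackers$had_chd <- 1L
    trackers$time_first_chd <- year + 1
  }
  if (ev == "STROKE" && !trackers$had_stroke) {
    trackers$had_stroke <- 1L
    trackers$time_first_stroke <- year + 1
  }
  list(state = new_state, trackers = trackers, event = ev)
}

#' Simulate one random walk
#'
#' Iterates \code{\link{step_individual}} over years 1..horizon with annual
#' ageing and 5-yearly drift, stopping early at death.
#'
#' @inheritParams step_individual
#' @param profile One-row cohort data frame (baseline values).
#' @param horizon Years to simulate.
#' @param drift A \code{\link{drift_model}}.
#' @param drift_enabled Apply drift (age always advances).
#' @return Object of class \code{cvd_walk}: list with \code{states}
#'   (length horizon + 1, starting state first), \code{trackers}, and
#'   \code{first_event} (named year-of-first-occurrence vector, NA if the
#'   event never occurred).
#' @export
run_walk <- function(profile, params, horizon = 13, drift = default_drift(),
                     drift_enabled = TRUE) {
  profile <- ensure_baseline_state(profile)
  state <- profile$baseline_state[1]
  trackers <- new_trackers()
  states <- character(horizon + 1L)
  states[1] <- state
  fe <- stats::setNames(rep(NA_real_, 4), event_types())
  eff_drift <- if (drift_enabled) drift else zero_drift()
  for (y in seq_len(horizon)) {
    if (is_absorbing(state)) {
      states[y + 1L] <- state
      next
    }
    prof_y <- suppressMessages(update_profile(profile, eff_drift, y - 1L))
    res <- step_individual(state, prof_y, trackers, params, year = y - 1L)
    state <- res$state
    trackers <- res$trackers
    states[y + 1L] <- state
    if (res$event != "stay" && is.na(fe[res$event])) fe[res$event] <- y
  }
  structure(list(states = states, trackers = trackers, first_event = fe),
            class = "cvd_walk")
}
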