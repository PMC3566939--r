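# shared fixtures; heavyweight objects are built once per test run

# one WELL individual with unremarkable risk factors
make_profile <- function(...) {
  p <- data.frame(id = 1L, age = 69, male = 0, smoking = "never",
                  bmi = 26, whr = 0.9, sbp = 140, dbp = 74,
                  hypertension = 0, total_chol = 6.7, hdl = 1.3,
                  glucose = 6.9, creatinine = 82, diabetes = 0, angina = 0,
                  atrial_fib = 0, claudication = 0, tia = 0,
                  prevalent_cvd = 0, fam_hist_mi = 0, fam_hist_cvd = 0,
                  abi = 1.05, baseline_state = "WELL",
                  stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  p
}

# parameter set with neutral coefficients (beta = 0 on age) and a constant
# annual baseline-hazard increment per transition; rates named by
# "SOURCE->EVENT", unnamed transitions get rate 0
make_flat_params <- function(rates = numeric(0), horizon = 15) {
  topo <- transition_topology()
  trans <- lapply(seq_len(nrow(topo)), function(i) {
    k <- paste(topo$source[i], topo$event[i], sep = "->")
    r <- if (k %in% names(rates)) rates[[k]] else 0
    cox_transition(topo$source[i], topo$event[i],
                   coefficients = c(age = 0), means = c(age = 69),
                   baseline_cum_hazard = r * (0:horizon))
  })
  parameter_set(trans)
}

# reduced covariate map for small-cohort unit tests: common, well-supported
# covariates only, so fits never run into separation at n of a few hundred
small_covariate_map <- function() {
  list(
    "WELL->CHD" = c("age", "male", "sbp"),
    "WELL->STROKE" = c("age", "sbp"),
    "WELL->CVD_DEATH" = c("age", "male"),
    "WELL->NON_CVD_DEATH" = c("age", "male", "smoke_current"),
    "CHD->STROKE" = c("age"),
    "CHD->CVD_DEATH" = c("age"),
    "CHD->NON_CVD_DEATH" = c("age"),
    "STROKE->CHD" = c("age"),
    "STROKE->CVD_DEATH" = c("age"),
    "STROKE->NON_CVD_DEATH" = c("age"),
    "CHD_AND_STROKE->CVD_DEATH" = c("age"),
    "CHD_AND_STROKE->NON_CVD_DEATH" = c("age")
  )
}

# hand-coded Breslow log partial likelihood for a single covariate,
# independent of survival::coxph (the brute-force oracle)
breslow_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    d <- which(status == 1 & time == t)
    risk <- which(time >= t)
    ll <- ll + sum(beta * x[d]) -
      length(d) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# memoised end-to-end pipeline at desk scale, shared across test files
pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- generate_profiles(rotterdam_like_spec(), n = 3000, seed = 101)
      fu <- generate_followup(coh, rotterdam_truth(), horizon = 13,
                              seed = 102)
      sets <- suppressMessages(
        bootstrap_parameter_sets(coh, fu$records, horizon = 13,
                                 n_replicates = 20, seed = 103))
      cache <<- list(cohort = coh, followup = fu, sets = sets)
    }
    cache
  }
})

epic_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- generate_profiles(epic_like_spec(), n = 8000, seed = 104)
      fu <- generate_followup(coh, epic_truth(), horizon = 10, seed = 105)
      cache <<- list(cohort = coh, followup = fu)
    }
    cache
  }
})
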