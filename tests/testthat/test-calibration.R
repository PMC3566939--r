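test_that("a symmetric two-group dataset yields a zero coefficient", {
  d <- data.frame(time_years = rep(c(1, 2, 3, 4), 2),
                  event = rep(c(1, 1, 0, 1), 2),
                  grp = rep(c(0, 1), each = 4))
  fn <- fit_transition(d, "grp", "WELL", "CHD", horizon = 4)
  expect_lt(abs(fn$coefficients[["grp"]]), 1e-6)
})

test_that("the fit matches a brute-force partial-likelihood maximizer", {
  time <- 1:6
  status <- c(1, 1, 0, 1, 0, 1)
  x <- c(1, 0, 0, 1, 1, 0)
  d <- data.frame(time_years = time, event = status, x = x)
  fn <- fit_transition(d, "x", "WELL", "CHD", horizon = 6)
  # golden-section maximization of the hand-coded Breslow log likelihood
  oracle <- stats::optimize(function(b) breslow_loglik(b, time, status, x),
                            interval = c(-5, 5), maximum = TRUE,
                            tol = 1e-9)$maximum
  expect_equal(fn$coefficients[["x"]], oracle, tolerance = 1e-4)
  # log partial likelihood at the optimum is no worse than at beta = 0
  expect_gte(breslow_loglik(fn$coefficients[["x"]], time, status, x),
             breslow_loglik(0, time, status, x))
  # score equation solved: numerical gradient at beta-hat is ~ 0
  h <- 1e-5
  grad <- (breslow_loglik(fn$coefficients[["x"]] + h, time, status, x) -
             breslow_loglik(fn$coefficients[["x"]] - h, time, status, x)) /
    (2 * h)
  expect_lt(abs(grad), 1e-6)
})

test_that("coefficients are recovered from simulated survival data", {
  set.seed(11)
  n <- 2000
  x1 <- stats::rnorm(n)
  x2 <- stats::rbinom(n, 1, 0.4)
  beta_true <- c(x1 = 0.5, x2 = -0.3)
  lp <- beta_true[["x1"]] * x1 + beta_true[["x2"]] * x2
  t_ev <- stats::rexp(n, rate = 0.1 * exp(lp))
  cens <- 8
  d <- data.frame(time_years = pmin(t_ev, cens),
                  event = as.integer(t_ev <= cens), x1 = x1, x2 = x2)
  fn <- fit_transition(d, c("x1", "x2"), "WELL", "CHD", horizon = 8)
  for (k in c("x1", "x2")) {
    expect_lt(abs(fn$coefficients[[k]] - beta_true[[k]]), 3 * fn$se[[k]])
  }
  # centered Breslow H0 tracks the true cumulative hazard of the average
  # individual: H0(t) ~ 0.1 * t * E[exp(lp - lp_bar)] -- check within 15%
  expect_equal(fn$baseline_cum_hazard[6] / 5,
               0.1 * mean(exp(lp - mean(lp))), tolerance = 0.15)
})

test_that("degenerate inputs are rejected with informative errors", {
  d <- data.frame(time_years = 1:5, event = c(1, 0, 0, 0, 0), x = 1:5 / 5)
  expect_error(fit_transition(d, "x", "WELL", "CHD"), "fewer than 2 events")
  d2 <- data.frame(time_years = 1:5, event = c(1, 1, 0, 1, 0),
                   x = rep(2, 5))
  expect_error(fit_transition(d2, "x", "WELL", "CHD"), "constant")
  d3 <- data.frame(time_years = c(0, 1:4), event = c(1, 1, 0, 1, 0),
                   x = 1:5)
  expect_error(fit_transition(d3, "x", "WELL", "CHD"), "positive")
})

test_that("identity resample reproduces the fit on the original data", {
  coh <- generate_profiles(rotterdam_like_spec(), n = 800, seed = 51)
  fu <- generate_followup(coh, rotterdam_truth(), horizon = 8, seed = 52)
  cmap <- small_covariate_map()
  ps0 <- fit_all_transitions(coh, fu$records, cmap, horizon = 8)
  boot <- bootstrap_parameter_sets(coh, fu$records, cmap, horizon = 8,
                                   n_replicates = 1, seed = 53,
                                   resample_fn = identity)
  for (k in names(ps0$transitions)) {
    expect_equal(boot[[1]]$transitions[[k]]$coefficients,
                 ps0$transitions[[k]]$coefficients, tolerance = 1e-12)
    expect_equal(boot[[1]]$transitions[[k]]$baseline_cum_hazard,
                 ps0$transitions[[k]]$baseline_cum_hazard,
                 tolerance = 1e-12)
  }
})

test_that("bootstrap is seed-deterministic and varies the baseline hazard", {
  coh <- generate_profiles(rotterdam_like_spec(), n = 800, seed = 51)
  fu <- generate_followup(coh, rotterdam_truth(), horizon = 8, seed = 52)
  cmap <- small_covariate_map()
  b1 <- suppressMessages(bootstrap_parameter_sets(coh, fu$records, cmap,
                                                  horizon = 8,
                                                  n_replicates = 4,
                                                  seed = 99))
  b2 <- suppressMessages(bootstrap_parameter_sets(coh, fu$records, cmap,
                                                  horizon = 8,
                                                  n_replicates = 4,
                                                  seed = 99))
  b3 <- suppressMessages(bootstrap_parameter_sets(coh, fu$records, cmap,
                                                  horizon = 8,
                                                  n_replicates = 4,
                                                  seed = 100))
  k <- "WELL->CVD_DEATH"
  expect_identical(lapply(b1, function(p) p$transitions[[k]]$coefficients),
                   lapply(b2, function(p) p$transitions[[k]]$coefficients))
  expect_false(identical(b1[[1]]$transitions[[k]]$coefficients,
                         b3[[1]]$transitions[[k]]$coefficients))
  # replicate ids recorded; linked sets cover the full topology
  expect_equal(vapply(b1, function(p) p$replicate_id, integer(1)), 1:4)
  # baseline-hazard uncertainty: H0(5) varies across replicates
  h05 <- vapply(b1, function(p) p$transitions[[k]]$baseline_cum_hazard[6],
                numeric(1))
  expect_gt(stats::var(h05), 0)
  # log partial likelihood at the fit is never worse than at beta = 0:
  # spot-check via the single-covariate oracle on a reduced model
  d <- data.frame(time_years = fu$records$time_years[
                    fu$records$transition_source == "WELL" &
                    fu$records$transition_target == "CVD_DEATH"],
                  event = fu$records$event[
                    fu$records$transition_source == "WELL" &
                    fu$records$transition_target == "CVD_DEATH"])
  d$x <- coh$age[match(fu$records$id[
    fu$records$transition_source == "WELL" &
    fu$records$transition_target == "CVD_DEATH"], coh$id)]
  fn <- fit_transition(d, "x", "WELL", "CVD_DEATH", horizon = 8)
  expect_gte(breslow_loglik(fn$coefficients[["x"]], d$time_years, d$event,
                            d$x),
             breslow_loglik(0, d$time_years, d$event, d$x))
})

test_that("bootstrap percentile intervals cover the truth", {
  # single-transition analogue at reduced scale: 20 experiments, 50
  # bootstrap refits each, 2.5-97.5 percentile interval of beta-hat should
  # cover the generating coefficient in >= 90% of (experiment, coefficient)
  # pairs
  set.seed(77)
  beta_true <- c(x1 = 0.6, x2 = -0.4)
  covered <- 0; total <- 0
  for (exp_i in 1:25) {
    n <- 800
    x1 <- stats::rnorm(n); x2 <- stats::rbinom(n, 1, 0.5)
    lp <- beta_true[["x1"]] * x1 + beta_true[["x2"]] * x2
    t_ev <- stats::rexp(n, 0.12 * exp(lp))
    d <- data.frame(time_years = pmin(t_ev, 6),
                    event = as.integer(t_ev <= 6), x1 = x1, x2 = x2)
    bhat <- replicate(80, {
      i <- sample.int(n, n, replace = TRUE)
      fit <- survival::coxph(survival::Surv(time_years, event) ~ x1 + x2,
                             data = d[i, ], ties = "breslow")
      stats::coef(fit)
    })
    for (k in c("x1", "x2")) {
      ci <- stats::quantile(bhat[k, ], c(0.025, 0.975))
      covered <- covered + (beta_true[[k]] >= ci[1] && beta_true[[k]] <= ci[2])
      total <- total + 1
    }
  }
  expect_gte(covered / total, 0.90)
})
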