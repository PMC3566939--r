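test_that("profile updating ages continuously and drifts five-yearly", {
  p <- make_profile()
  drift <- drift_model(c(total_chol = -0.1, sbp = 3))
  # zero drift: only age differs
  p3 <- update_profile(p, zero_drift(), 3)
  expect_equal(p3$age, 72)
  expect_equal(p3[setdiff(names(p3), "age")], p[setdiff(names(p), "age")])
  # before the first 5-year mark nothing but age changes
  expect_equal(update_profile(p, drift, 4)$total_chol, p$total_chol)
  # at year 5 the cholesterol slope is applied once
  expect_equal(update_profile(p, drift, 5)$total_chol, p$total_chol - 0.1)
  expect_equal(update_profile(p, drift, 5)$sbp, p$sbp + 3)
  # additivity: two 5-year updates equal one 10-year doubled change
  expect_equal(update_profile(p, drift, 10)$total_chol, p$total_chol - 0.2)
  # non-physical drift is clamped at the floor, with a message
  harsh <- drift_model(c(total_chol = -10))
  expect_message(p5 <- update_profile(p, harsh, 5), "clamped")
  expect_equal(p5$total_chol, 1)
})

test_that("one cycle steps the state and trackers correctly", {
  p <- make_profile()
  # all hazards flat: the state never changes
  flat <- make_flat_params()
  res <- step_individual("WELL", p, new_trackers(), flat, year = 0, u = 0.01)
  expect_equal(res$state, "WELL")
  expect_equal(res$event, "stay")
  # an overwhelming CVD-death hazard kills, leaving event trackers unset
  lethal <- make_flat_params(c("WELL->CVD_DEATH" = 50))
  res <- step_individual("WELL", p, new_trackers(), lethal, year = 0, u = 0.5)
  expect_equal(res$state, "CVD_DEATH")
  expect_equal(res$trackers$had_chd, 0L)
  # a CHD event from the stroke state lands in the combined state and sets
  # the CHD tracker with its first-occurrence time
  chd_after_stroke <- make_flat_params(c("STROKE->CHD" = 50))
  tr <- new_trackers(); tr$had_stroke <- 1L; tr$time_first_stroke <- 2
  res <- step_individual("STROKE", p, tr, chd_after_stroke, year = 3, u = 0.5)
  expect_equal(res$state, "CHD_AND_STROKE")
  expect_equal(res$trackers$had_chd, 1L)
  expect_equal(res$trackers$time_first_chd, 4)
  expect_equal(res$trackers$time_first_stroke, 2)
  expect_error(step_individual("CVD_DEATH", p, new_trackers(), flat, 0),
               "absorbing")
})

test_that("the prevalent-CVD covariate switches on after a tracked event", {
  p <- make_profile()
  # transition whose hazard depends only on prevalent CVD
  topo <- transition_topology()
  trans <- lapply(seq_len(nrow(topo)), function(i) {
    b <- if (topo$source[i] == "CHD" && topo$event[i] == "CVD_DEATH")
      c(prevalent_cvd = 2) else c(age = 0)
    m <- if (topo$source[i] == "CHD" && topo$event[i] == "CVD_DEATH")
      c(prevalent_cvd = 0) else c(age = 69)
    cox_transition(topo$source[i], topo$event[i], b, m, 0.01 * (0:15))
  })
  ps <- parameter_set(trans)
  tr_naive <- new_trackers()
  tr_post <- new_trackers(); tr_post$had_chd <- 1L
  tr_post$time_first_chd <- 1
  # same state, same profile: the tracked CHD history multiplies the
  # death hazard by e^2, which shows up in the transition probability
  u_between <- 1 - exp(-0.01 * exp(2) * 0.6)  # exceeds p(no history)
  res_naive <- step_individual("CHD", p, tr_naive, ps, 2, u = u_between)
  res_post <- step_individual("CHD", p, tr_post, ps, 2, u = u_between)
  expect_equal(res_naive$event, "stay")
  expect_equal(res_post$event, "CVD_DEATH")
})

test_that("random walks terminate at death and keep consistent trackers", {
  p <- make_profile()
  # all hazards zero: thirteen WELL states, no events
  w <- run_walk(p, make_flat_params(), horizon = 13)
  expect_equal(w$states, rep("WELL", 14))
  expect_true(all(is.na(w$first_event)))
  # busy world: absorbing persistence and tracker consistency over walks
  busy <- make_flat_params(c("WELL->CHD" = 0.15, "WELL->STROKE" = 0.1,
                             "WELL->CVD_DEATH" = 0.1,
                             "WELL->NON_CVD_DEATH" = 0.1,
                             "CHD->STROKE" = 0.15, "CHD->CVD_DEATH" = 0.2,
                             "CHD->NON_CVD_DEATH" = 0.1,
                             "STROKE->CHD" = 0.15,
                             "STROKE->CVD_DEATH" = 0.2,
                             "STROKE->NON_CVD_DEATH" = 0.1,
                             "CHD_AND_STROKE->CVD_DEATH" = 0.3,
                             "CHD_AND_STROKE->NON_CVD_DEATH" = 0.1))
  set.seed(5)
  for (i in 1:100) {
    w <- run_walk(p, busy, horizon = 13)
    dead_at <- which(is_absorbing(w$states))
    if (length(dead_at)) {
      k <- min(dead_at)
      expect_true(all(w$states[k:14] == w$states[k]))
    }
    expect_equal(!is.na(w$first_event[["CHD"]]), w$trackers$had_chd == 1L)
    expect_equal(!is.na(w$first_event[["STROKE"]]),
                 w$trackers$had_stroke == 1L)
    if ("CHD_AND_STROKE" %in% w$states) {
      expect_true(w$trackers$had_chd == 1L && w$trackers$had_stroke == 1L)
    }
    # at most one death, and death cause matches the terminal state
    expect_lte(sum(!is.na(w$first_event[c("CVD_DEATH", "NON_CVD_DEATH")])),
               1)
  }
})

test_that("walk event times follow the closed-form exponential law", {
  # single cause, constant annual cumulative hazard h: the fraction of
  # walks with the event by year t is 1 - exp(-h t)
  h <- 0.08
  ps <- make_flat_params(c("WELL->CVD_DEATH" = h))
  cfg <- sim_config(n_outer = 1, n_profiles = 200, n_walks = 50,
                    horizon = 13, seed = 61)
  surf <- run_three_level(make_profile(), ps, cfg)
  n_walks_total <- 200 * 50
  sub <- surf[surf$event == "CVD_DEATH", ]
  for (t in 1:13) {
    p_true <- 1 - exp(-h * t)
    se <- sqrt(p_true * (1 - p_true) / n_walks_total)
    expect_lt(abs(sub$mean[sub$year == t] - p_true), 3 * se)
  }
})

test_that("the three-level simulation obeys its structural invariants", {
  fx <- pipeline_fixture()
  cfg <- sim_config(n_outer = 10, n_profiles = 300, n_walks = 30,
                    horizon = 13, seed = 62)
  surf <- run_three_level(fx$cohort, fx$sets, cfg)
  # credibility band ordering and monotone cumulative incidences
  expect_true(all(surf$lo <= surf$mean + 1e-12))
  expect_true(all(surf$mean <= surf$hi + 1e-12))
  for (ev in event_types()) {
    sub <- surf[surf$event == ev, ]
    expect_true(all(diff(sub$mean) >= -1e-12))
    expect_true(all(diff(sub$lo) >= -1e-12))
    expect_true(all(diff(sub$hi) >= -1e-12))
  }
  # identical parameter sets degenerate to a zero-width band
  cfg1 <- sim_config(n_outer = 3, n_profiles = 100, n_walks = 20,
                     horizon = 5, seed = 63)
  surf1 <- run_three_level(fx$cohort, rep(fx$sets[1], 3), cfg1)
  # same parameters but different walk realisations: band is walk noise
  # only; with a single replicate it is exactly zero
  cfg0 <- sim_config(n_outer = 1, n_profiles = 100, n_walks = 20,
                     horizon = 5, seed = 63)
  surf0 <- run_three_level(fx$cohort, fx$sets[[1]], cfg0)
  expect_equal(surf0$lo, surf0$mean)
  expect_equal(surf0$hi, surf0$mean)
  expect_error(run_three_level(fx$cohort[0, ], fx$sets, cfg),
               "empty")
  expect_error(run_three_level(fx$cohort, fx$sets[1:3], cfg),
               "n_outer")
})

test_that("state occupancy sums to one and death causes partition mortality", {
  fx <- pipeline_fixture()
  cfg <- sim_config(n_outer = 1, n_profiles = 200, n_walks = 20,
                    horizon = 13, seed = 64)
  coh <- cvdsim:::ensure_baseline_state(fx$cohort)
  set.seed(64)
  sel <- sample.int(nrow(coh), 200, replace = TRUE)
  rep1 <- cvdsim:::simulate_replicate(coh, fx$sets[[1]], cfg,
                                      default_drift(), sel,
                                      keep_states = TRUE)
  # every walker occupies exactly one valid state each year
  expect_true(all(rep1$states %in% health_states()))
  occ <- apply(rep1$states, 2, function(s) sum(table(s)))
  expect_true(all(occ == nrow(rep1$states)))
  # mutually exclusive death causes: cumulative incidences add up to total
  # mortality
  fe <- rep1$first_event
  for (t in c(5, 13)) {
    total_dead <- mean((!is.na(fe[, "CVD_DEATH"]) & fe[, "CVD_DEATH"] <= t) |
                       (!is.na(fe[, "NON_CVD_DEATH"]) &
                          fe[, "NON_CVD_DEATH"] <= t))
    expect_equal(unname(rep1$incidence["CVD_DEATH", t] +
                          rep1$incidence["NON_CVD_DEATH", t]), total_dead,
                 tolerance = 1e-12)
  }
})

test_that("identical seeds reproduce the surface bit for bit", {
  fx <- pipeline_fixture()
  cfg <- sim_config(n_outer = 4, n_profiles = 150, n_walks = 20,
                    horizon = 8, seed = 65)
  s1 <- run_three_level(fx$cohort, fx$sets, cfg)
  s2 <- run_three_level(fx$cohort, fx$sets, cfg)
  expect_identical(s1$mean, s2$mean)
  expect_identical(attr(s1, "raw"), attr(s2, "raw"))
  cfg2 <- cfg; cfg2$seed <- 66L
  s3 <- run_three_level(fx$cohort, fx$sets, cfg2)
  expect_false(identical(s1$mean, s3$mean))
})

test_that("fifty walks already pin year-13 means to within a point", {
  fx <- pipeline_fixture()
  base <- sim_config(n_outer = 5, n_profiles = 300, n_walks = 200,
                     horizon = 13, seed = 67)
  small <- sim_config(n_outer = 5, n_profiles = 300, n_walks = 50,
                      horizon = 13, seed = 68)
  s200 <- run_three_level(fx$cohort, fx$sets, base)
  s50 <- run_three_level(fx$cohort, fx$sets, small)
  for (ev in event_types()) {
    m200 <- s200$mean[s200$event == ev & s200$year == 13]
    m50 <- s50$mean[s50$event == ev & s50$year == 13]
    expect_lt(abs(m200 - m50), 0.01)
  }
})
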