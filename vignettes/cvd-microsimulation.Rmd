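---
title: "Methods: a Cox-equation microsimulation of cardiovascular disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Cox-equation microsimulation of cardiovascular disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdsim)
```

## The model

`cvdsim` simulates individual cardiovascular histories in a discrete-time
state-transition model with six health states: `WELL` (alive, no coronary
heart disease or stroke), `CHD`, `STROKE`, `CHD_AND_STROKE`, and the two
absorbing states `CVD_DEATH` and `NON_CVD_DEATH`. Twelve transitions are
permitted (`transition_topology()`): from `WELL` to first CHD, first
stroke, or either death; from each nonfatal disease state to the other
event (landing in the combined state) or death. Repeat events of a kind
already suffered do not change the state and are not counted again;
incident events are recorded once per type by tracker variables.

Each transition carries a centered Cox proportional-hazards equation. For
an individual with covariate vector $x$ the cause-specific hazard over the
annual cycle $(t, t+1]$ is

$$\Delta H_{0}(t)\, e^{\beta'(x - \bar x)}, \qquad
  \Delta H_0(t) = H_0(t{+}1) - H_0(t),$$

where $H_0$ is the cumulative baseline hazard of the *average* individual
($x = \bar x$), kept as a step function on integer years. Centering is
what makes the model portable: transplanting it to another population
only requires substituting $\bar x$ and $H_0$.

Twenty-two covariates are supported (`risk_factor_names()`): age, sex,
smoking (two indicators, never-smokers as reference), body-mass index,
waist-to-hip ratio, systolic and diastolic pressure, hypertension, total
and HDL cholesterol, glucose, creatinine, diabetes, angina, atrial
fibrillation, claudication, TIA, prevalent CVD, two family-history flags
and the ankle-brachial index. Any subset may enter any transition; the
engine is schema-driven through the named coefficient vectors.

### Competing events within a cycle

Within a cycle the competing transitions out of the current state are
resolved by the cause-specific-hazard partition: with cycle hazards
$h_c$, the probability of leaving the state is $1 - e^{-\sum_c h_c}$ and,
conditional on leaving, destination $c$ is chosen with probability
$h_c / \sum_c h_c$. A single uniform draw decides both, which makes the
rule order-invariant and exact in the continuous-time limit of
year-constant rates. No half-cycle correction is applied: validation
compares annual cumulative incidences, not life-years, and events are
attributed to the cycle in which they occur.

### Event feedback

Trackers feed back into the hazards in two ways: the state itself (the
post-event transitions have their own equations), and the
`prevalent_cvd` covariate, which switches on at the first tracked CHD or
stroke event and enters every subsequent linear predictor that uses it.

## Calibration

`fit_transition()` fits one cause-specific Cox model per transition with
Breslow tie handling (delegated to `survival::coxph`, convergence
tolerance `1e-9`, at most 100 iterations; divergence of a coefficient
beyond $|\beta| > 15$ or a flagged infinite-likelihood direction is
raised as a separation error rather than returned as an estimate).

A structural point decides how the records enter the fit. The engine
applies hazards to the *current* covariates: age advances every year and
the continuous factors drift every 5 years. If the Cox model were fitted
on baseline covariates over a 13-year window, the risk set's own ageing
would be absorbed into $\hat H_0(t)$, and a simulation that then also
ages the covariates would count ageing twice (we measured roughly a
1.7-fold overestimate of 10-year mortality in that configuration).
`fit_all_transitions()` therefore expands each record into annual
counting-process intervals whose covariates follow the same deterministic
path the engine applies — age plus the 5-yearly drift schedule — so the
fitted baseline hazard carries no secular trend and the calibration is
exactly consistent with the simulation. This is the model's own
covariate updating, not externally measured time-dependent covariates;
extrapolating beyond the calibration window then amounts to reusing the
per-year baseline hazards with updated profiles, which is precisely the
mechanism that makes predictive (beyond-window) validation meaningful.
Centering means $\bar x$ are the baseline covariate means of the
individuals at risk for that transition.

Risk sets are formed from baseline state membership: transitions out of
state $S$ are fitted on the individuals who *start* in $S$. The synthetic
cohorts provide such baseline-state subcohorts (including post-event
states, via the prevalent-CVD split below); late-entry risk sets are not
used.

### Parameter uncertainty

`bootstrap_parameter_sets()` resamples individuals with replacement, then
refits *all* transitions on the same resample, giving linked sets that
preserve the cross-transition dependence of the coefficients. The Breslow
baseline hazard is refitted within each resample, so baseline-hazard
uncertainty is propagated for free. Replicates in which any fit fails
(separation in a sparse transition) are redrawn up to a cap, with a
message.

## The three-level simulation

`run_three_level()` nests three Monte Carlo levels:

* **outer** (default 100): one linked parameter set per replicate —
  parameter uncertainty;
* **middle** (default 2,000): risk-factor profiles sampled with
  replacement from the cohort — heterogeneity. Sampling *with*
  replacement keeps the cohort representation unbiased at any size; for
  stratified analyses `aggregate_by_individual` iterates every individual
  instead;
* **inner** (default 200): random walks per profile — first-order
  stochastic uncertainty.

Within a replicate, the cumulative incidence of each tracked event at
year $t$ is the proportion of walks whose first event of that type
occurred by $t$; the mean and the 2.5th/97.5th percentiles across outer
replicates form the 95% credibility band.

All randomness flows from the single configuration seed: per-replicate
seeds are derived from it, and draws inside a replicate are vectorized
over walkers. Reruns with the same configuration are bit-identical. (A
counter-based per-(replicate, profile, walk) stream would additionally
make parallel execution reproducible; base R exposes no such generator,
and execution here is serial, so derived per-replicate seeds are used.)

### Risk-factor drift

`drift_model()` holds additive 5-year changes for the continuous factors,
applied at years 5, 10, ... while age advances annually. The default
(`default_drift()`) encodes plausible trends of an ageing European
cohort — total cholesterol falling by 0.15 mmol/L and systolic pressure
rising by 3 mmHg per 5 years, and so on — and is a configuration value,
not an estimate: estimating trends from repeated measurements is outside
the package's scope. Drifted values are clamped at physiological floors
(e.g. total cholesterol 1 mmol/L), with a message. The same drift object
must be used for calibration and simulation; it is part of the model.

## Recalibration

`recalibrate()` adapts a fitted model to a new population by replacing,
per transition, the centering means with the new cohort's means and the
centered cumulative baseline hazard with an offset-Breslow estimate from
the new cohort's follow-up, holding $\beta$ fixed:

$$\hat H_0(t) = \sum_{t_i \le t} \frac{d_i}{\sum_{j \in R(t_i)}
  e^{\beta'(x_j - \bar x_{\text{new}})}}.$$

The coefficients — the relative strengths of the risk-factor
associations — are untouched; re-estimating them would be refitting, not
recalibration. Recalibration is applied per bootstrap replicate, so the
recalibrated model retains parameter uncertainty. By default only the
transitions into the two death states are recalibrated, matching an
external validation restricted to mortality (nonfatal event ascertainment
is typically not comparable across cohorts); pass
`events = event_types()` to recalibrate everything. The new-cohort
records are expanded into the same annual counting-process intervals as
in calibration, so recalibrating a model on its own calibration cohort
reproduces the original baseline hazards to numerical precision, and the
operation is idempotent.

## Validation

`observed_cumulative_incidence()` computes crude cumulative proportions —
first events of a type by year $t$ over cohort size — and deliberately
not Kaplan–Meier or Aalen–Johansen estimates: the intended use restricts
the cohort to complete follow-up (individuals censored before the horizon
without a terminal event are an error), and competing death then bounds
the nonfatal incidences exactly as the simulation counts them.
`compare_incidence()` joins observed incidences with the simulated band
and flags coverage; `stratified_validation()` repeats the comparison
within age tertiles (cut points from the cohort itself) and by sex,
simulating every stratum member individually. `plot_validation()` draws
the standard curve-band-points panel per event.

## The synthetic world

Because the source cohorts of such models are not redistributable, the
package ships a generator that emulates their published baseline
structure and provides exact ground truth.

`rotterdam_like_spec()` targets an elderly population-based cohort (mean
age 69, 39% male, 17.8% prevalent CVD, total cholesterol 6.67 mmol/L,
...); `epic_like_spec()` a younger one (59.2 years, 45% male, 4.3%
prevalent CVD). Profiles are drawn through a Gaussian copula: latent
multivariate normals with a plausible, configuration-overridable
correlation structure (blood pressures correlate with hypertension, BMI
with waist-to-hip ratio and glucose, and so on), mapped through normal
marginals — log-normal for the right-skewed laboratory values (glucose,
creatinine) — thresholded at prevalence quantiles for binaries, and cut
twice for the three smoking categories. The published tables do not
include the ankle-brachial index; a plausible distribution is used. Age
is truncated at the recruitment floor (55 and 45 years respectively).
Non-positive-definite correlation matrices are rejected with a pointer to
`Matrix::nearPD()`.

Prevalent-CVD individuals are assigned a baseline state by a fixed split
(35% `WELL`, 40% `CHD`, 20% `STROKE`, 5% `CHD_AND_STROKE`): prevalent CVD
is a broader clinical history than the model's post-event states (e.g.
prior revascularisation), and the `WELL` share is what makes the
`prevalent_cvd` coefficient estimable within the `WELL` risk set under
baseline-state calibration.

`generate_followup()` draws event histories in continuous time from a
ground-truth parameter set: within each year the cause-specific rates are
constant, event times are exponential, and a nonfatal event updates the
state, the trackers and hence the hazards for the remainder of the year.
This generator is deliberately *not* the simulation engine — it is the
independent oracle the engine is tested against; the two agree in
distribution up to the engine's one-transition-per-cycle discretisation,
whose effect on 13-year incidences is an order of magnitude below
Monte-Carlo error at the cohort sizes used.

The ground-truth coefficients (`rotterdam_truth()`) are fixed, moderate
log-hazard ratios (age 0.05–0.095 per year, male 0.2–0.45, and so on),
and the annual baseline increments were chosen once so that the 13-year
incidences of the older synthetic world land near published magnitudes
for such a cohort — CHD ≈ 10.6%, stroke ≈ 9.9%, CVD death ≈ 14.2%,
non-CVD death ≈ 24.3%; the implied 5-year incidences then come out close
to published early-window values without being targeted. The younger
world (`epic_truth()`) shares the same coefficients — exactly the
assumption under which recalibration is the right adjustment — but its
baseline hazards are a uniform 25% lower than the older world's risk
equations imply for the same covariates. An unrecalibrated older-world
model therefore overestimates younger-world mortality by roughly a third,
reproducing the qualitative external-validation pattern; we chose to
preserve this overestimation ratio rather than the absolute younger-world
mortality level, because with Table-level marginals and these moderate
risk gradients both cannot hold at once (the synthetic younger world's
10-year mortality is ~2.3%/5.5% for CVD/non-CVD death).

### What the synthetic world does and does not establish

Passing the round-trip tests shows that calibration recovers generating
coefficients, that the engine reproduces the generator's incidences, and
that recalibration corrects a known proportional miscalibration — all
*within the model class*. Real cohorts violate the class: hazards are not
piecewise-constant in years, trends are not linear-additive, covariates
are measured with error and missingness, and event adjudication differs
between cohorts. Agreement on synthetic data is therefore a necessary
software-correctness property, not evidence about any real population.

## Numerical choices and problem sizes

* Cycle length 1 year; baseline hazards on integer-year grids; requests
  beyond the grid raise an error (no silent extrapolation).
* Breslow tie handling everywhere, matching the Breslow baseline
  estimator; ties are measure-zero in the synthetic world anyway.
* Cox convergence: `eps = 1e-9`, max 100 iterations; separation raises an
  error, and inside the bootstrap triggers a logged redraw of the
  resample.
* Transition probabilities use `expm1` for numerical accuracy at small
  hazards.
* The default test and acceptance runs use desk-scale sizes chosen for
  tight-enough Monte-Carlo error at interactive runtimes: calibration
  cohorts of 3,000, 20 bootstrap replicates, and a 20 × 500 × 50
  three-level design (500,000 walks per analysis); the full reference
  design (100 × 2,000 × 200) is the package default in `sim_config()`.
* Sparse post-event transitions get reduced covariate sets by default
  (`default_covariate_map()`); with a few dozen events, richer models
  separate.

## Limitations

* No interventions or treatment effects; only observed ("current
  practice") history is simulated. No costs, QALYs or discounting.
* No late-entry (counting-process) risk sets for post-event transitions:
  calibration uses baseline-state membership only.
* Within-cycle event ordering is not modelled beyond the competing-risk
  partition; at most one transition occurs per cycle.
* The drift model is linear-additive per 5-year block and deterministic.
* Stratified simulation refits nothing per stratum; it reuses the cohort-
  level parameter sets.
* The credibility band quantifies parameter uncertainty *around the
  fitted model*: all bootstrap replicates share the point fit's sampling
  error. When a model calibrated on a few thousand individuals is
  transported to a markedly different population, that shared error can
  occasionally push even the recalibrated band marginally off the
  observed curve for some calibration realisations — a genuine feature of
  bootstrap bands, not a defect of the recalibration; larger calibration
  cohorts shrink it.
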