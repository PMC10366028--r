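# Agent simulator: determinism, planted covariate effects, trait
# monotonicity, covariate proxies, distractor effect, log validity.

test_that("identical seeds give identical cohorts, sessions and ratings", {
  model <- default_population_model()
  c1 <- sample_participants(model, 20L, 42L)
  c2 <- sample_participants(model, 20L, 42L)
  expect_identical(c1, c2)

  spec <- default_task_spec()
  tr <- epelir:::traits_from_row(c1$traits, 3L)
  s1 <- simulate_session(tr, spec, assign_condition(2L, spec), 9L)
  s2 <- simulate_session(tr, spec, assign_condition(2L, spec), 9L)
  expect_identical(s1$scenario_logs, s2$scenario_logs)

  expect_identical(simulate_ratings(tr, 5L), simulate_ratings(tr, 5L))
  expect_identical(simulate_recall_score(tr, 5L), simulate_recall_score(tr, 5L))
})

test_that("trait sampling follows the planted covariate maps", {
  model <- default_population_model()

  # null model: no age effect -> near-zero correlation (|r| < 0.05); a large
  # cohort keeps the sampling noise of r (~1/sqrt(n)) well inside the bound
  null_model <- model
  null_model$traits <- lapply(model$traits, function(tr) {
    tr$b_age <- 0; tr$b_girl <- 0
    tr
  })
  coh <- sample_participants(null_model, 10000L, 7L)
  r <- cor(coh$covariates$age_years, coh$traits$encode_p)
  expect_lt(abs(r), 0.05)

  # planted age slope on the encoding trait recovered within +/-20%
  coh <- sample_participants(model, 2000L, 8L)
  keep <- coh$traits$encode_p > 0.051 & coh$traits$encode_p < 0.979 # unclipped
  fit <- lm(coh$traits$encode_p[keep] ~ coh$covariates$age_years[keep] +
              coh$covariates$gender[keep])
  slope <- unname(coef(fit)[2L])
  expect_gt(slope, model$traits$encode_p$b_age * 0.8)
  expect_lt(slope, model$traits$encode_p$b_age * 1.2)
})

test_that("nothing encoded means nothing scored", {
  spec <- default_task_spec()
  tr <- agent_traits(encode_p = 0, impulsivity_rate = 0)
  sess <- simulate_session(tr, spec, assign_condition(0L, spec), 3L)
  expect_equal(aggregate_session(sess, spec)$session$total_score, 0)
})

test_that("mean total score tracks the encoding probability binomially", {
  spec <- default_task_spec()
  model <- default_population_model()
  # all other fidelity traits ideal, so completion = encoding exactly
  tr <- agent_traits(encode_p = 0.6, impulsivity_rate = 0, nav_noise_p = 0,
                     timing_sd_s = 0, cue_response_p = 1)
  n <- 200L
  totals <- vapply(seq_len(n), function(j) {
    sess <- simulate_session(tr, spec, assign_condition(j %% 2L, spec),
                             seed = 7000L + j, model)
    aggregate_session(sess, spec)$session$total_score
  }, 0)
  mu <- 70 * 0.6
  half <- qnorm(0.995) * sqrt(70 * 0.6 * 0.4 / n)
  expect_gt(mean(totals), mu - half)
  expect_lt(mean(totals), mu + half)
})

test_that("expected measures are monotone in their driving traits", {
  spec <- default_task_spec()
  model <- default_population_model()
  mean_measure <- function(traits, measure, n = 200L, seed0 = 0L) {
    mean(vapply(seq_len(n), function(j) {
      sess <- simulate_session(traits, spec,
                               assign_condition(j %% 2L, spec),
                               seed = seed0 + j, model)
      aggregate_session(sess, spec)$session[[measure]]
    }, 0))
  }
  base <- agent_traits()

  lo <- base; lo$encode_p <- 0.4
  hi <- base; hi$encode_p <- 0.9
  expect_lt(mean_measure(lo, "total_score", seed0 = 1000L),
            mean_measure(hi, "total_score", seed0 = 2000L))

  lo <- base; lo$impulsivity_rate <- 0.02
  hi <- base; hi$impulsivity_rate <- 0.2
  expect_lt(mean_measure(lo, "total_actions", seed0 = 3000L),
            mean_measure(hi, "total_actions", seed0 = 4000L))

  lo <- base; lo$motor_level <- 30
  hi <- base; hi$motor_level <- 120
  expect_lt(mean_measure(lo, "controller_motion_deg", seed0 = 5000L),
            mean_measure(hi, "controller_motion_deg", seed0 = 6000L))

  lo <- base; lo$monitor_rate <- 1
  hi <- base; hi$monitor_rate <- 6
  expect_lt(mean_measure(lo, "clock_checks", seed0 = 7000L),
            mean_measure(hi, "clock_checks", seed0 = 8000L))

  lo <- base; lo$nav_noise_p <- 0
  hi <- base; hi$nav_noise_p <- 0.5
  expect_gt(mean_measure(lo, "navigation_efficacy", seed0 = 9000L),
            mean_measure(hi, "navigation_efficacy", seed0 = 10000L))
})

test_that("distractors lower task efficacy in matched scenarios", {
  spec <- default_task_spec()
  model <- default_population_model()
  res <- simulate_and_score_cohort(model, 60L, 17L, spec)
  scen <- res$scenario_scores
  on <- scen$task_efficacy[scen$distractors_on]
  off <- scen$task_efficacy[!scen$distractors_on]
  expect_lt(mean(on, na.rm = TRUE), mean(off, na.rm = TRUE))
})

test_that("recall score and ratings carry the planted relations", {
  model <- default_population_model()
  tr1 <- agent_traits(encode_p = 1)
  tr0 <- agent_traits(encode_p = 0)
  expect_equal(simulate_recall_score(tr1, 1L), model$recall$items)
  expect_equal(simulate_recall_score(tr0, 1L), 0L)

  # zero-noise monotonicity of the behavioral-regulation analog
  m0 <- model
  m0$ratings$bri$sd <- 0; m0$ratings$mi$sd <- 0
  lo <- agent_traits(impulsivity_rate = 0.02)
  hi <- agent_traits(impulsivity_rate = 0.2)
  expect_lt(simulate_ratings(lo, 1L, m0)[["bri"]],
            simulate_ratings(hi, 1L, m0)[["bri"]])

  # cohort-level signs at n = 500: recall correlates with total score,
  # the global rating composite correlates negatively with task efficacy
  spec <- default_task_spec()
  res <- simulate_and_score_cohort(model, 500L, 23L, spec)
  tab <- merge(res$session_scores, res$covariates, by = "participant_id")
  expect_gt(cor(tab$recall_score, tab$total_score), 0)
  expect_lt(cor(tab$gec, tab$task_efficacy, use = "complete.obs"), 0)
})

test_that("every generated session passes log validation", {
  spec <- default_task_spec()
  model <- default_population_model()
  coh <- sample_participants(model, 6L, 19L)
  for (i in 1:6) {
    tr <- epelir:::traits_from_row(coh$traits, i)
    sess <- simulate_session(tr, spec, assign_condition(i - 1L, spec),
                             seed = 400L + i, model)
    v <- do.call(rbind, lapply(sess$scenario_logs, validate_log, spec = spec))
    expect_equal(nrow(v), 0L)
  }
})
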