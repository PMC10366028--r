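# Replay engine and the eight measures, against hand-traced logs on the
# two-room mini spec (entry wA at (0,0), wB at (3,4), edge length 5).

# Hand trace used below (execution clock):
#   5.0  click oA1   (at wA, reach 1)          -> completes t01_1
#   7.0  pickup oMov (at wA, reach 1)          -> advances t01_2
#   9.0  teleport wB                            (walk 5)
#  12.0  drop oMov at wB                       -> completes t01_2
#  20.0  click irrX  (at wB, reach 3)          -> irrelevant
#  30.0  cue_onset c1
#  41.0  click oB1   (at wB, reach 1)          -> completes t01_3 (target 40)
#  80.0  clock_check
hand_log <- function() {
  tiny_log(make_events(
    t = c(5, 7, 9, 12, 20, 30, 41, 80),
    type = c("click_object", "pickup", "click_waypoint", "drop",
             "click_object", "cue_onset", "click_object", "clock_check"),
    object = c("oA1", "oMov", NA, "oMov", "irrX", NA, "oB1", NA),
    waypoint = c(NA, NA, "wB", "wB", NA, NA, NA, NA),
    cue = c(NA, NA, NA, NA, NA, "c1", NA, NA)))
}

test_that("replay reproduces the hand trace: completions, end time, distances", {
  spec <- tiny_spec()
  out <- replay_scenario(hand_log(), spec = spec)

  expect_setequal(names(out$completed), c("t01_1", "t01_2", "t01_3"))
  expect_equal(unname(out$completed[c("t01_1", "t01_2", "t01_3")]),
               c(5, 12, 41))
  expect_equal(out$end_time_s, 90) # two subtasks missing -> full limit
  expect_equal(out$distance_walked_m, 5)
  expect_equal(out$object_reach_m, 1 + 1 + 3 + 1)

  expect_equal(score_total(out), 3)
  expect_equal(score_task_efficacy(out), 4 / 5) # 4 relevant of 5 non-waypoint
  expect_equal(score_navigation_efficacy(out), 3 / 11)
  expect_equal(score_tbpm(out, spec$scenarios[[1L]]), 1) # |41 - 40| <= 10
  expect_equal(score_ebpm(out, spec$scenarios[[1L]], spec$ebpm_window_s), 0)
  expect_equal(count_clock_checks(hand_log()), 1)
  expect_equal(count_total_actions(hand_log()), 5) # waypoint click excluded
})

test_that("scenario ends at the last completion when everything is done", {
  spec <- tiny_spec()
  log <- tiny_log(make_events(
    t = c(5, 7, 9, 12, 30, 39.9, 41, 60),
    type = c("click_object", "pickup", "click_waypoint", "drop", "cue_onset",
             "click_object", "click_object", "click_object"),
    object = c("oA1", "oMov", NA, "oMov", NA, "oA2", "oB1", "oA3"),
    waypoint = c(NA, NA, "wB", "wB", NA, NA, NA, NA),
    cue = c(NA, NA, NA, NA, "c1", NA, NA, NA)))
  out <- replay_scenario(log, spec = spec)
  expect_equal(length(out$completed), 5L)
  expect_equal(out$end_time_s, 60)
  # cue response 9.9 s after onset is inside the inclusive window
  expect_equal(score_ebpm(out, spec$scenarios[[1L]]), 1)
})

test_that("an empty execution phase scores zero everywhere", {
  spec <- tiny_spec()
  ev <- make_events(t = 30, type = "cue_onset", cue = "c1")
  out <- replay_scenario(tiny_log(ev), spec = spec)
  expect_equal(score_total(out), 0)
  expect_true(is.na(score_task_efficacy(out)))
  expect_true(is.na(score_navigation_efficacy(out)))
  expect_equal(out$distance_walked_m + out$object_reach_m, 0)
  expect_equal(out$end_time_s, 90)
})

test_that("task efficacy matches hand counts and excludes waypoint clicks", {
  spec <- tiny_spec()
  # 3 relevant clicks + 1 irrelevant click + 5 waypoint clicks -> 0.75
  log <- tiny_log(make_events(
    t = c(1, 2, 3, 4, 5, 6, 8, 30, 41, 50),
    type = c("click_waypoint", "click_waypoint", "click_waypoint",
             "click_waypoint", "click_waypoint", "click_object",
             "click_object", "cue_onset", "click_object", "click_object"),
    object = c(NA, NA, NA, NA, NA, "oA1", "irrX", NA, "oB1", "oA3"),
    waypoint = c("wB", "wA", "wB", "wA", "wB", NA, NA, NA, NA, NA),
    cue = c(NA, NA, NA, NA, NA, NA, NA, "c1", NA, NA)))
  out <- replay_scenario(log, spec = spec)
  expect_equal(score_task_efficacy(out), 0.75)
  # redundant second click on an already-completed target is irrelevant
  log2 <- tiny_log(make_events(
    t = c(5, 6, 30), type = c("click_object", "click_object", "cue_onset"),
    object = c("oA1", "oA1", NA), cue = c(NA, NA, "c1")))
  expect_equal(score_task_efficacy(replay_scenario(log2, spec = spec)), 0.5)
  # only relevant actions -> 1
  log3 <- tiny_log(make_events(
    t = c(5, 30), type = c("click_object", "cue_onset"),
    object = c("oA1", NA), cue = c(NA, "c1")))
  expect_equal(score_task_efficacy(replay_scenario(log3, spec = spec)), 1)
})

test_that("navigation efficacy is scale covariant", {
  spec <- tiny_spec()
  out <- replay_scenario(hand_log(), spec = spec)
  v1 <- score_navigation_efficacy(out)
  doubled <- unclass(tiny_spec())
  doubled$floorplan$waypoints$x <- doubled$floorplan$waypoints$x * 2
  doubled$floorplan$waypoints$y <- doubled$floorplan$waypoints$y * 2
  doubled$floorplan$objects$x <- doubled$floorplan$objects$x * 2
  doubled$floorplan$objects$y <- doubled$floorplan$objects$y * 2
  doubled <- epelir:::as_task_spec(doubled)
  v2 <- score_navigation_efficacy(replay_scenario(hand_log(), spec = doubled))
  expect_equal(v2, v1 / 2)
})

test_that("TBPM window is inclusive at +/-10 s", {
  spec <- tiny_spec()
  for (case in list(c(30.0, 1), c(50.0, 1), c(50.1, 0), c(40.0, 1))) {
    log <- tiny_log(make_events(
      t = c(case[1L], 60), type = c("click_object", "cue_onset"),
      object = c("oB1", NA), cue = c(NA, "c1"), end = 90))
    out <- replay_scenario(log, spec = spec)
    expect_equal(score_tbpm(out, spec$scenarios[[1L]]), case[2L],
                 label = sprintf("completion at %.1f", case[1L]))
  }
})

test_that("EBPM window is inclusive and pre-cue completions do not count", {
  spec <- tiny_spec()
  for (case in list(c(40.0, 1), c(39.9, 1), c(40.1, 0), c(29.0, 0), c(30, 1))) {
    log <- tiny_log(make_events(
      t = c(30, case[1L])[order(c(30, case[1L]))],
      type = if (case[1L] >= 30) c("cue_onset", "click_object")
             else c("click_object", "cue_onset"),
      object = if (case[1L] >= 30) c(NA, "oA2") else c("oA2", NA),
      cue = if (case[1L] >= 30) c("c1", NA) else c(NA, "c1")))
    out <- replay_scenario(log, spec = spec)
    expect_equal(score_ebpm(out, spec$scenarios[[1L]]), case[2L],
                 label = sprintf("completion at %.1f", case[1L]))
  }
})

test_that("controller motion integrates geodesic angles, sign invariant", {
  spec <- tiny_spec()
  # constant orientation -> 0
  q0 <- matrix(rep(c(1, 0, 0, 0), each = 20L), 20L, 4L)
  expect_equal(score_controller_motion(tiny_log(orientation_events(q0))), 0)

  # 9 successive 10-degree rotations about a skew axis -> 90 degrees
  q <- quat_walk(c(1, 2, 3), rep(10, 9))
  expect_equal(score_controller_motion(tiny_log(orientation_events(q))), 90,
               tolerance = 1e-9)

  # flipping the sign of any sample leaves the measure unchanged
  qf <- q; qf[4L, ] <- -qf[4L, ]
  expect_equal(score_controller_motion(tiny_log(orientation_events(qf))), 90,
               tolerance = 1e-9)
})

test_that("total actions counts drum hits and instruction clicks, not waypoints", {
  spec <- tiny_spec()
  # 4 execution clicks + 2 drum hits + 1 instruction click + 3 waypoint clicks
  ev <- make_events(
    t = c(1, 2, 3, 4, 10, 11, 20, 21, 30),
    type = c("click_object", "click_object", "click_object", "click_object",
             "drum_hit", "drum_hit", "click_waypoint", "click_waypoint",
             "cue_onset"),
    object = c("oA1", "oA2", "oA3", "irrX", "oB1", "oB1", NA, NA, NA),
    waypoint = c(NA, NA, NA, NA, NA, NA, "wB", "wA", NA),
    cue = c(NA, NA, NA, NA, NA, NA, NA, NA, "c1"))
  instr_click <- ev[2L, ]
  instr_click$t_s <- 5; instr_click$phase <- "instruction"
  instr_click$type <- "click_object"; instr_click$object_id <- "irrX"
  ev <- rbind(ev[1L, ], instr_click, ev[-1L, ])
  ev <- ev[c(1, 2, 3, seq(4, nrow(ev))), ]
  wp3 <- ev[ev$type == "click_waypoint", ][1L, ]
  wp3$t_s <- 35; wp3$waypoint_id <- "wB"
  ev <- rbind(ev[-nrow(ev), ], wp3, ev[nrow(ev), ])
  ev <- ev[order(ev$t_s), ]
  log <- tiny_log(ev)
  expect_equal(count_total_actions(log), 7)
  # a clock check changes no other measure
  with_clock <- ev
  cc <- ev[nrow(ev) - 1L, ]; cc$t_s <- 50; cc$type <- "clock_check"
  cc$object_id <- NA; cc$waypoint_id <- NA
  with_clock <- rbind(ev[-nrow(ev), ], cc, ev[nrow(ev), ])
  s1 <- score_scenario(log, spec)
  s2 <- score_scenario(tiny_log(with_clock), spec)
  expect_equal(s2$clock_checks, s1$clock_checks + 1)
  for (m in setdiff(epelir:::MEASURES, "clock_checks")) {
    expect_equal(s2[[m]], s1[[m]], label = m)
  }
})

test_that("replay is deterministic and monotone under irrelevant perturbation", {
  spec <- default_task_spec()
  model <- default_population_model()
  coh <- sample_participants(model, 1L, 21L)
  tr <- epelir:::traits_from_row(coh$traits, 1L)
  sess <- simulate_session(tr, spec, assign_condition(0L, spec), 77L, model)
  log <- sess$scenario_logs[[1L]]

  s1 <- score_scenario(log, spec)
  s2 <- score_scenario(log, spec)
  expect_identical(s1, s2)

  # appending an irrelevant execution click: efficacy weakly decreases,
  # total actions increments, total score unchanged
  ev <- log$events
  extra <- ev[ev$type == "scenario_end", , drop = FALSE][1L, ]
  extra$type <- "click_object"
  extra$object_id <- "irr_kitchen_1"
  extra$t_s <- extra$t_s - 1e-6
  ev2 <- rbind(ev[-nrow(ev), ], extra, ev[nrow(ev), , drop = FALSE])
  log2 <- scenario_log(log$scenario_id, log$distractors_on, ev2)
  p1 <- score_scenario(log, spec)
  p2 <- score_scenario(log2, spec)
  expect_equal(p2$total_score, p1$total_score)
  expect_equal(p2$total_actions, p1$total_actions + 1)
  expect_lte(p2$task_efficacy, p1$task_efficacy)
})

test_that("every measure equals the naive recount oracle on simulated logs", {
  spec <- default_task_spec()
  model <- default_population_model()
  coh <- sample_participants(model, 2L, 31L)
  n_checked <- 0L
  for (i in 1:2) {
    tr <- epelir:::traits_from_row(coh$traits, i)
    sess <- simulate_session(tr, spec, assign_condition(i - 1L, spec),
                             seed = 300L + i, model)
    for (log in sess$scenario_logs) {
      got <- score_scenario(log, spec)
      want <- oracle_eight_measures(log, spec)
      for (m in epelir:::MEASURES) {
        expect_equal(got[[m]], want[[m]], tolerance = 1e-12,
                     label = sprintf("%s on %s", m, log$scenario_id))
      }
      n_checked <- n_checked + 1L
    }
  }
  expect_equal(n_checked, 26L)
})

test_that("session aggregation: ceiling, zeros, and additivity", {
  spec <- default_task_spec()
  # ideal agent reaches the ceiling
  sess <- simulate_session(ideal_traits(), spec, assign_condition(0L, spec),
                           seed = 1L)
  sc <- aggregate_session(sess, spec)
  expect_equal(sc$session$total_score, 70)
  expect_equal(sc$session$task_efficacy, 1.0)
  expect_equal(sc$session$tbpm, 13)
  expect_equal(sc$session$ebpm, 5)

  # count aggregates equal column sums of the per-scenario rows
  for (m in c("total_score", "total_actions", "tbpm", "ebpm", "clock_checks",
              "controller_motion_deg")) {
    expect_equal(sc$session[[m]], sum(sc$scenario[[m]]), label = m)
  }
  # ratio-of-sums efficacy equals summed numerators over summed denominators
  expect_equal(sc$session$task_efficacy,
               sum(sc$scenario$n_relevant) / sum(sc$scenario$n_actions_nonwp))

  # a no-op participant: zero counts, undefined efficacies
  none <- agent_traits(encode_p = 0, impulsivity_rate = 0, motor_level = 0,
                       motor_burst_deg = 0, monitor_rate = 0)
  sess0 <- simulate_session(none, spec, assign_condition(0L, spec), seed = 2L)
  sc0 <- aggregate_session(sess0, spec)
  expect_equal(sc0$session$total_score, 0)
  expect_true(is.na(sc0$session$task_efficacy))
  expect_true(is.na(sc0$session$navigation_efficacy))
})
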