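# Replay engine: deterministic re-execution of a scenario log against the
# task specification, producing subtask completions, action-relevance labels
# and the eight behavioral measures.
#
# Scoring semantics:
#  * a subtask completes at the event that finishes its required step
#    sequence; steps are matched in order within a subtask, subtasks complete
#    in any order, and completion is recognized regardless of timing (timing
#    accuracy is captured separately by the prospective-memory scores);
#  * a non-waypoint action (object click, pickup, drop, drum hit) is labeled
#    relevant iff it advances the next step of some not-yet-completed
#    subtask; redundant clicks after completion are irrelevant;
#  * waypoint clicks are excluded both from task efficacy (explicitly) and
#    from total actions (the measure counts interactions with objects);
#  * scoring windows are inclusive at their boundaries (+/-10 s, 10 s), so a
#    tie at the boundary credits the participant.

#' Replay a scenario log
#'
#' @param log An `epeli_scenario_log`.
#' @param scenario The matching scenario from the spec (or `NULL` to look it
#'   up by the log's `scenario_id`).
#' @param spec An `epeli_task_spec`.
#' @return An `epeli_scenario_outcome`: list with `completed` (named numeric,
#'   execution-clock completion time per completed subtask id), `end_time_s`,
#'   `relevance` (data frame: event row, execution time, relevant flag for
#'   every non-waypoint action in the execution phase), `distance_walked_m`,
#'   `object_reach_m`, and `cue_times` (execution-clock cue onsets).
#' @export
replay_scenario <- function(log, scenario = NULL, spec) {
  if (is.null(scenario)) scenario <- find_scenario(spec, log$scenario_id)
  if (is.null(scenario) || !identical(scenario$id, log$scenario_id)) {
    stop_epelir(sprintf("log scenario id '%s' does not match scenario '%s'",
                        log$scenario_id, scenario$id %||% "<none>"),
                "epelir_structure_error")
  }
  rt <- route_table(spec)
  ev <- log$events
  n <- nrow(ev)
  ie <- which(ev$type == "instruction_end")
  t0 <- if (length(ie)) ev$t_s[ie[1L]] else 0
  te <- ev$t_s - t0 # execution clock

  mach <- scenario_machine(spec, scenario)
  n_st <- mach$n_subtasks
  ptr <- rep(1L, n_st)                  # next micro-step per subtask
  n_micro <- mach$n_micro
  done_t <- rep(NA_real_, n_st)
  names(done_t) <- mach$subtask_ids
  cand_sub <- mach$cand_sub; cand_mic <- mach$cand_mic
  cand_op <- mach$cand_op; cand_obj <- mach$cand_obj
  cand_dest <- mach$cand_dest

  exec <- ev$phase == "execution"
  is_action <- exec & ev$type %in% ACTION_TYPES
  is_tp <- exec & ev$type == "click_waypoint"

  wp_row <- match(ev$waypoint_id, rt$ids)
  obj_row <- match(ev$object_id, rt$obj_ids)

  # distance walked: Euclidean hops between consecutive teleport destinations
  tp_rows <- wp_row[is_tp]
  entry_row <- match(spec$floorplan$entry_waypoint, rt$ids)
  seq_rows <- c(entry_row, tp_rows)
  dist_walked <- if (length(seq_rows) > 1L) {
    xy <- rt$wp_xy[seq_rows, , drop = FALSE]
    sum(sqrt(rowSums(diff(xy)^2)))
  } else 0

  # current waypoint at each event (for object reach)
  pos_idx <- cumsum(is_tp)                 # how many teleports happened so far
  cur_row <- seq_rows[pos_idx + 1L]

  reach <- 0
  action_idx <- which(is_action)
  relevant <- logical(length(action_idx))
  for (k in seq_along(action_idx)) {
    i <- action_idx[k]
    type <- ev$type[i]
    obj <- ev$object_id[i]
    if (!is.na(obj_row[i]) && type %in% c("click_object", "pickup", "drum_hit")) {
      dxy <- rt$obj_xy[obj_row[i], ] - rt$wp_xy[cur_row[i], ]
      reach <- reach + sqrt(sum(dxy^2))
    }
    op <- switch(type, click_object = "interact", drum_hit = "interact",
                 pickup = "pickup", drop = "drop")
    hit <- which(cand_obj == obj & cand_op == op &
                   is.na(done_t)[cand_sub] & cand_mic == ptr[cand_sub])
    if (op == "drop" && length(hit)) {
      hit <- hit[cand_dest[hit] == ev$waypoint_id[i]]
    }
    if (length(hit)) {
      si <- cand_sub[hit[1L]]            # first matching subtask in spec order
      ptr[si] <- ptr[si] + 1L
      relevant[k] <- TRUE
      if (ptr[si] > n_micro[si]) done_t[si] <- te[i]
    }
  }

  all_done <- !anyNA(done_t)
  end_time <- if (all_done && n_st > 0L) max(done_t) else spec$time_limit_s

  cue_rows <- which(ev$type == "cue_onset")
  cue_times <- te[cue_rows]
  names(cue_times) <- ev$cue_id[cue_rows]

  structure(list(
    scenario_id = scenario$id,
    completed = done_t[!is.na(done_t)],
    end_time_s = end_time,
    relevance = fast_df(list(event = action_idx, t_exec = te[action_idx],
                             relevant = relevant)),
    distance_walked_m = dist_walked,
    object_reach_m = reach,
    cue_times = cue_times,
    n_instruction_clicks = sum(!exec & ev$type %in% ACTION_TYPES)),
    class = "epeli_scenario_outcome")
}

# ---------------------------------------------------------------------------
# The eight measures

#' Total score: number of correctly performed subtasks
#' @param outcome An `epeli_scenario_outcome`.
#' @return Count of completed subtasks in the scenario.
#' @export
score_total <- function(outcome) length(outcome$completed)

#' Task efficacy: share of relevant actions
#'
#' Relevant non-waypoint actions divided by all non-waypoint actions during
#' the execution phase. Undefined (`NA`) when no non-waypoint action
#' occurred; such scenarios contribute only their (zero) denominator to the
#' session aggregate.
#'
#' @param outcome An `epeli_scenario_outcome`.
#' @return Proportion in `[0, 1]`, or `NA` when undefined.
#' @export
score_task_efficacy <- function(outcome) {
  n <- nrow(outcome$relevance)
  if (n == 0L) return(NA_real_)
  sum(outcome$relevance$relevant) / n
}

#' Navigation efficacy: completed subtasks per metre of movement
#'
#' Total score divided by the distance covered: teleport path length plus the
#' reach to each manipulated object. Undefined (`NA`) when no distance was
#' covered.
#'
#' @param outcome An `epeli_scenario_outcome`.
#' @return Subtasks per metre, or `NA`.
#' @export
score_navigation_efficacy <- function(outcome) {
  denom <- outcome$distance_walked_m + outcome$object_reach_m
  if (denom <= 0) return(NA_real_)
  score_total(outcome) / denom
}

#' Controller motion: cumulative angular displacement in degrees
#'
#' Sum over consecutive execution-phase orientation samples of the geodesic
#' rotation angle `2*acos(|<q_i, q_{i+1}>|)`, invariant to the quaternion
#' sign ambiguity.
#'
#' @param log An `epeli_scenario_log`.
#' @return Degrees (0 when fewer than two orientation samples are present).
#' @export
score_controller_motion <- function(log) {
  ev <- log$events
  keep <- ev$type == "orientation_sample" & ev$phase == "execution"
  quat_path_angle_deg(cbind(ev$qw[keep], ev$qx[keep], ev$qy[keep], ev$qz[keep]))
}

#' Total actions: all object interactions
#'
#' Execution-phase object clicks (including pickups and drops), drum hits,
#' and instruction-phase clicks. Waypoint clicks are excluded.
#'
#' @param log An `epeli_scenario_log`.
#' @return Count.
#' @export
count_total_actions <- function(log) {
  sum(log$events$type %in% ACTION_TYPES)
}

#' Time-based prospective memory: hits within the timing window
#'
#' Counts time-based subtasks completed within `tbpm_halfwidth_s` seconds
#' (inclusive) of their target time.
#'
#' @param outcome An `epeli_scenario_outcome`.
#' @param scenario The scenario definition.
#' @param halfwidth_s Window half-width in seconds (default 10).
#' @return Count.
#' @export
score_tbpm <- function(outcome, scenario, halfwidth_s = 10) {
  hits <- 0L
  for (st in scenario$subtasks) {
    if (st$kind != "time_based") next
    ct <- outcome$completed[st$id]
    if (!is.na(ct) && abs(ct - st$target_time_s) <= halfwidth_s) hits <- hits + 1L
  }
  hits
}

#' Event-based prospective memory: responses within the cue window
#'
#' Counts event-based subtasks completed between cue onset and
#' `window_s` seconds after it (inclusive). A completion before the cue does
#' not count.
#'
#' @param outcome An `epeli_scenario_outcome`.
#' @param scenario The scenario definition.
#' @param window_s Response window in seconds (default 10).
#' @return Count.
#' @export
score_ebpm <- function(outcome, scenario, window_s = 10) {
  hits <- 0L
  for (st in scenario$subtasks) {
    if (st$kind != "event_based") next
    ct <- outcome$completed[st$id]
    cue <- outcome$cue_times[st$cue_id]
    if (is.na(cue)) cue <- st$cue_time_s
    if (!is.na(ct) && ct >= cue && ct <= cue + window_s) hits <- hits + 1L
  }
  hits
}

#' Clock checks: time-monitoring events
#'
#' @param log An `epeli_scenario_log`.
#' @return Count of execution-phase `clock_check` events.
#' @export
count_clock_checks <- function(log) {
  sum(log$events$type == "clock_check" & log$events$phase == "execution")
}

#' All eight measures for one scenario log
#'
#' @param log An `epeli_scenario_log`.
#' @param spec An `epeli_task_spec`.
#' @return One-row data frame with the eight measures plus the bookkeeping
#'   columns used for ratio-of-sums session aggregation (`n_relevant`,
#'   `n_actions_nonwp`, `distance_m`).
#' @export
score_scenario <- function(log, spec) {
  fast_df(score_scenario_core(log, spec))
}

score_scenario_core <- function(log, spec) {
  scenario <- find_scenario(spec, log$scenario_id)
  out <- replay_scenario(log, scenario, spec)
  n_rel <- sum(out$relevance$relevant)
  n_act <- nrow(out$relevance)
  dist <- out$distance_walked_m + out$object_reach_m
  list(
    scenario_id = log$scenario_id,
    distractors_on = log$distractors_on,
    total_score = score_total(out),
    task_efficacy = score_task_efficacy(out),
    navigation_efficacy = score_navigation_efficacy(out),
    controller_motion_deg = score_controller_motion(log),
    total_actions = count_total_actions(log),
    tbpm = score_tbpm(out, scenario, spec$tbpm_halfwidth_s),
    clock_checks = count_clock_checks(log),
    ebpm = score_ebpm(out, scenario, spec$ebpm_window_s),
    end_time_s = out$end_time_s,
    n_relevant = n_rel,
    n_actions_nonwp = n_act,
    distance_m = dist)
}

MEASURES <- c("total_score", "task_efficacy", "navigation_efficacy",
              "controller_motion_deg", "total_actions", "tbpm",
              "clock_checks", "ebpm")

#' Score a full session: per-scenario rows plus session aggregates
#'
#' Count measures are summed over the scenarios; the two efficacies are
#' aggregated as ratio-of-sums by default (summed numerators over summed
#' denominators, so scenarios with an undefined per-scenario efficacy still
#' contribute their denominators), or as the mean of the defined per-scenario
#' ratios when `efficacy_aggregate = "mean_of_ratios"`.
#'
#' @param session An `epeli_session_log`.
#' @param spec An `epeli_task_spec`.
#' @param efficacy_aggregate `"ratio_of_sums"` (default) or
#'   `"mean_of_ratios"`.
#' @return An `epeli_scores`: list with `participant_id`, `scenario` (one row
#'   per scenario) and `session` (one aggregate row).
#' @export
aggregate_session <- function(session, spec,
                              efficacy_aggregate = c("ratio_of_sums",
                                                     "mean_of_ratios")) {
  efficacy_aggregate <- match.arg(efficacy_aggregate)
  n_scen <- length(spec$scenarios)
  if (length(session$scenario_logs) != n_scen) {
    stop_epelir(sprintf("session has %d scenario logs, spec defines %d",
                        length(session$scenario_logs), n_scen),
                "epelir_structure_error")
  }
  rows <- lapply(session$scenario_logs, score_scenario_core, spec = spec)
  cols <- lapply(names(rows[[1L]]), function(nm) {
    unlist(lapply(rows, `[[`, nm), use.names = FALSE)
  })
  names(cols) <- names(rows[[1L]])
  scen <- fast_df(cols)
  # per-scenario rows in canonical spec order for the item matrix
  scen <- scen[match(scenario_ids(spec), scen$scenario_id), , drop = FALSE]
  row.names(scen) <- NULL

  tot <- sum(scen$total_score)
  if (efficacy_aggregate == "ratio_of_sums") {
    task_eff <- if (sum(scen$n_actions_nonwp) > 0)
      sum(scen$n_relevant) / sum(scen$n_actions_nonwp) else NA_real_
    nav_eff <- if (sum(scen$distance_m) > 0)
      tot / sum(scen$distance_m) else NA_real_
  } else {
    task_eff <- if (all(is.na(scen$task_efficacy))) NA_real_
      else mean(scen$task_efficacy, na.rm = TRUE)
    nav_eff <- if (all(is.na(scen$navigation_efficacy))) NA_real_
      else mean(scen$navigation_efficacy, na.rm = TRUE)
  }
  sess <- fast_df(list(
    participant_id = session$participant_id,
    total_score = tot,
    task_efficacy = task_eff,
    navigation_efficacy = nav_eff,
    controller_motion_deg = sum(scen$controller_motion_deg),
    total_actions = sum(scen$total_actions),
    tbpm = sum(scen$tbpm),
    clock_checks = sum(scen$clock_checks),
    ebpm = sum(scen$ebpm)))
  structure(list(participant_id = session$participant_id,
                 scenario = scen, session = sess),
            class = "epeli_scores")
}

#' @export
print.epeli_scores <- function(x, ...) {
  cat(sprintf("Scores for participant %s\n", x$participant_id))
  s <- x$session
  cat(sprintf("  total score %d/70, task efficacy %s, navigation efficacy %s\n",
              s$total_score,
              formatC(s$task_efficacy, digits = 3, format = "f"),
              formatC(s$navigation_efficacy, digits = 4, format = "f")))
  cat(sprintf("  TBPM %d/13, EBPM %d/5, clock checks %d, total actions %d, controller motion %.0f deg\n",
              s$tbpm, s$ebpm, s$clock_checks, s$total_actions,
              s$controller_motion_deg))
  invisible(x)
}

#' Write per-scenario and per-session score tables as CSV
#'
#' @param scores_list List of `epeli_scores` (one per participant).
#' @param scenario_path,session_path Output CSV paths.
#' @param header_comment Optional comment line(s) written with a leading `#`.
#' @return Invisibly, a list with both data frames.
#' @export
write_scores_csv <- function(scores_list, scenario_path, session_path,
                             header_comment = NULL) {
  scen <- do.call(rbind, lapply(scores_list, function(s) {
    cbind(fast_df(list(participant_id = rep(s$participant_id, nrow(s$scenario)))),
          s$scenario)
  }))
  sess <- do.call(rbind, lapply(scores_list, `[[`, "session"))
  for (p in list(c(scenario_path), c(session_path))) {
    dir.create(dirname(p), showWarnings = FALSE, recursive = TRUE)
  }
  write_csv_with_comment(scen, scenario_path, header_comment)
  write_csv_with_comment(sess, session_path, header_comment)
  invisible(list(scenario = scen, session = sess))
}

write_csv_with_comment <- function(df, path, header_comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
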