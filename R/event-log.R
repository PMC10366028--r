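# Gameplay telemetry: event tables, JSON-Lines serialization, validation.
#
# One session = one participant playing all 13 scenarios. Events are
# timestamped from scenario onset; the instruction phase (oral instructions)
# precedes the execution phase, with the transition marked by a single
# instruction_end event. All scoring windows are measured on the execution
# clock (t_s minus the instruction_end time).

EVENT_TYPES <- c("scenario_start", "instruction_end", "click_object",
                 "click_waypoint", "pickup", "drop", "drum_hit", "clock_check",
                 "cue_onset", "orientation_sample", "scenario_end")
ACTION_TYPES <- c("click_object", "pickup", "drop", "drum_hit")

EVENT_COLS <- list(t_s = 0, phase = "", type = "",
                   object_id = NA_character_, waypoint_id = NA_character_,
                   cue_id = NA_character_, qw = NA_real_, qx = NA_real_,
                   qy = NA_real_, qz = NA_real_,
                   position_waypoint = NA_character_)

# Coerce a partial event table to the full column set, in canonical order.
normalize_events <- function(df) {
  n <- nrow(df)
  cols <- lapply(names(EVENT_COLS), function(nm) {
    if (nm %in% names(df)) {
      v <- df[[nm]]
      storage.mode(v) <- storage.mode(EVENT_COLS[[nm]])
      v
    } else {
      rep(EVENT_COLS[[nm]], n)
    }
  })
  names(cols) <- names(EVENT_COLS)
  fast_df(cols)
}

#' Construct a scenario log
#'
#' @param scenario_id Scenario id the log belongs to.
#' @param distractors_on Whether distractors were active in this gameplay.
#' @param events Event table (data frame with at least `t_s`, `phase`,
#'   `type`; missing optional columns are filled with `NA`).
#' @return An `epeli_scenario_log`.
#' @export
scenario_log <- function(scenario_id, distractors_on, events) {
  structure(list(scenario_id = scenario_id,
                 distractors_on = isTRUE(distractors_on),
                 events = normalize_events(events)),
            class = "epeli_scenario_log")
}

#' Construct a session log
#'
#' @param participant_id Participant identifier.
#' @param assignment An `epeli_assignment` (see [assign_condition()]).
#' @param scenario_logs List of `epeli_scenario_log`, in played order.
#' @param covariates Named list of participant covariates (may be empty).
#' @return An `epeli_session_log`.
#' @export
session_log <- function(participant_id, assignment, scenario_logs,
                        covariates = list()) {
  ids <- vapply(scenario_logs, `[[`, "", "scenario_id")
  if (!identical(unname(ids), unname(assignment$scenario_order[seq_along(ids)]))) {
    stop_epelir("scenario logs are not in the assignment's play order",
                "epelir_structure_error")
  }
  structure(list(participant_id = participant_id, assignment = assignment,
                 scenario_logs = scenario_logs, covariates = covariates),
            class = "epeli_session_log")
}

# ---------------------------------------------------------------------------
# Validation

find_scenario <- function(spec, scenario_id) {
  i <- match(scenario_id, scenario_ids(spec))
  if (is.na(i)) return(NULL)
  spec$scenarios[[i]]
}

#' Validate a scenario log against a task specification
#'
#' Checks the event-stream invariants: starts/ends with the scenario
#' start/end markers, timestamps non-negative and non-decreasing, a single
#' instruction-to-execution transition with consistent phase labels, unit
#' orientation quaternions (tolerance 1e-6), identifiers resolving against
#' the floor plan, cue onsets present for every event-based subtask, and the
#' scenario end respecting the execution time limit.
#'
#' Violations are returned, not thrown, so a caller can triage a corrupt log.
#'
#' @param log An `epeli_scenario_log`.
#' @param spec An `epeli_task_spec`.
#' @return A data frame with columns `index` (event row, NA for log-level
#'   rules), `rule` and `detail`; zero rows when the log is well formed.
#' @export
validate_log <- function(log, spec) {
  ev <- log$events
  n <- nrow(ev)
  idx <- integer()
  rule <- character()
  detail <- character()
  bad <- function(i, r, d) {
    idx <<- c(idx, i)
    rule <<- c(rule, r)
    detail <<- c(detail, d)
  }

  scen <- find_scenario(spec, log$scenario_id)
  if (is.null(scen)) {
    bad(NA_integer_, "unknown_scenario", sprintf("scenario '%s' not in spec", log$scenario_id))
    return(fast_df(list(index = idx, rule = rule, detail = detail)))
  }
  if (n == 0L) {
    bad(NA_integer_, "empty_log", "log has no events")
    return(fast_df(list(index = idx, rule = rule, detail = detail)))
  }
  if (ev$type[1L] != "scenario_start") {
    bad(1L, "starts_with_scenario_start", "first event must be scenario_start")
  }
  if (ev$type[n] != "scenario_end") {
    bad(n, "ends_with_scenario_end", "last event must be scenario_end")
  }
  if (any(ev$t_s < 0)) {
    bad(which(ev$t_s < 0)[1L], "nonnegative_time", "t_s < 0")
  }
  if (n > 1L && any(diff(ev$t_s) < 0)) {
    bad(which(diff(ev$t_s) < 0)[1L] + 1L, "monotone_time",
        "timestamps must be non-decreasing")
  }
  unknown_type <- !ev$type %in% EVENT_TYPES
  if (any(unknown_type)) {
    bad(which(unknown_type)[1L], "known_type",
        sprintf("unknown event type '%s'", ev$type[which(unknown_type)[1L]]))
  }

  ie <- which(ev$type == "instruction_end")
  if (length(ie) != 1L) {
    bad(if (length(ie)) ie[2L] else NA_integer_, "single_instruction_end",
        sprintf("expected exactly one instruction_end, found %d", length(ie)))
  } else {
    expect_phase <- rep("execution", n)
    expect_phase[seq_len(ie)] <- "instruction"
    mism <- which(ev$phase != expect_phase)
    if (length(mism)) {
      bad(mism[1L], "phase_consistency",
          "phase must be 'instruction' up to instruction_end, 'execution' after")
    }
    exec_end <- ev$t_s[n] - ev$t_s[ie]
    if (exec_end > spec$time_limit_s + 1e-6) {
      bad(n, "time_limit",
          sprintf("execution phase lasts %.3f s (> %g s limit)", exec_end,
                  spec$time_limit_s))
    }
  }

  q <- cbind(ev$qw, ev$qx, ev$qy, ev$qz)
  has_q <- ev$type == "orientation_sample"
  if (any(has_q)) {
    nrm <- sqrt(rowSums(q[has_q, , drop = FALSE]^2))
    off <- which(abs(nrm - 1) > 1e-6)
    if (length(off)) {
      bad(which(has_q)[off[1L]], "orientation_norm",
          sprintf("quaternion norm %.6f deviates from 1", nrm[off[1L]]))
    }
  }

  obj_ids <- spec$floorplan$objects$id
  wp_ids <- spec$floorplan$waypoints$id
  bad_obj <- which(!is.na(ev$object_id) & !ev$object_id %in% obj_ids)
  if (length(bad_obj)) {
    bad(bad_obj[1L], "unknown_object",
        sprintf("object '%s' not in floor plan", ev$object_id[bad_obj[1L]]))
  }
  bad_wp <- which(!is.na(ev$waypoint_id) & !ev$waypoint_id %in% wp_ids)
  if (length(bad_wp)) {
    bad(bad_wp[1L], "unknown_waypoint",
        sprintf("waypoint '%s' not in floor plan", ev$waypoint_id[bad_wp[1L]]))
  }
  cue_ids <- unlist(lapply(scen$subtasks, function(st) st$cue_id), use.names = FALSE)
  bad_cue <- which(!is.na(ev$cue_id) & !ev$cue_id %in% cue_ids)
  if (length(bad_cue)) {
    bad(bad_cue[1L], "unknown_cue",
        sprintf("cue '%s' not defined for scenario %s", ev$cue_id[bad_cue[1L]],
                log$scenario_id))
  }
  logged_cues <- ev$cue_id[ev$type == "cue_onset"]
  for (cid in cue_ids) {
    if (!cid %in% logged_cues) {
      bad(NA_integer_, "missing_cue",
          sprintf("no cue_onset logged for event-based cue '%s'", cid))
    }
  }

  fast_df(list(index = idx, rule = rule, detail = detail))
}

# ---------------------------------------------------------------------------
# JSON Lines serialization

json_str <- function(x) {
  # minimal JSON string escaping for identifiers and labels
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  paste0("\"", x, "\"")
}

events_to_jsonl <- function(ev) {
  n <- nrow(ev)
  if (n == 0L) return(character())
  parts <- sprintf('{"record":"event","t_s":%.9f,"phase":%s,"type":%s',
                   ev$t_s, json_str(ev$phase), json_str(ev$type))
  opt_chr <- function(parts, col, nm) {
    has <- !is.na(col)
    parts[has] <- paste0(parts[has], sprintf(',"%s":%s', nm, json_str(col[has])))
    parts
  }
  parts <- opt_chr(parts, ev$object_id, "object_id")
  parts <- opt_chr(parts, ev$waypoint_id, "waypoint_id")
  parts <- opt_chr(parts, ev$cue_id, "cue_id")
  parts <- opt_chr(parts, ev$position_waypoint, "position_waypoint")
  has_q <- !is.na(ev$qw)
  if (any(has_q)) {
    parts[has_q] <- paste0(parts[has_q], sprintf(
      ',"orientation":[%.9f,%.9f,%.9f,%.9f]',
      ev$qw[has_q], ev$qx[has_q], ev$qy[has_q], ev$qz[has_q]))
  }
  paste0(parts, "}")
}

#' Write a session log as JSON Lines
#'
#' One record per line: a session header (participant id, counterbalancing
#' assignment, covariates), then for each scenario a scenario header followed
#' by its events. Timestamps are written with nanosecond precision so that a
#' read/write round trip is lossless.
#'
#' @param session An `epeli_session_log`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(session, path) {
  a <- session$assignment
  header <- jsonlite::toJSON(list(
    record = "session",
    participant_id = session$participant_id,
    participant_index = a$participant_index,
    order = a$order,
    distractor_scenarios = a$distractor_scenarios,
    covariates = session$covariates), auto_unbox = TRUE, digits = NA, null = "null")
  lines <- vector("list", 1L + 2L * length(session$scenario_logs))
  lines[[1L]] <- as.character(header)
  k <- 1L
  for (sl in session$scenario_logs) {
    k <- k + 1L
    lines[[k]] <- sprintf('{"record":"scenario","scenario_id":%s,"distractors_on":%s}',
                          json_str(sl$scenario_id),
                          if (sl$distractors_on) "true" else "false")
    k <- k + 1L
    lines[[k]] <- events_to_jsonl(sl$events)
  }
  writeLines(unlist(lines), path, useBytes = TRUE)
  invisible(path)
}

parse_event_lines <- function(lines) {
  if (length(lines) == 0L) return(normalize_events(fast_df(list(t_s = numeric()))))
  df <- jsonlite::stream_in(textConnection(lines), verbose = FALSE,
                            simplifyDataFrame = TRUE, flatten = TRUE)
  if (!is.null(df$orientation)) {
    qm <- do.call(rbind, lapply(df$orientation, function(v) {
      if (is.null(v) || length(v) != 4L) rep(NA_real_, 4L) else v
    }))
    df$qw <- qm[, 1L]; df$qx <- qm[, 2L]; df$qy <- qm[, 3L]; df$qz <- qm[, 4L]
    df$orientation <- NULL
  }
  normalize_events(df)
}

#' Read a session log written by [write_session_log()]
#'
#' @param path Path to a JSON-Lines session log.
#' @param spec The `epeli_task_spec` the log was recorded against; every
#'   scenario log is validated against it and any violation raises an error.
#' @return An `epeli_session_log`.
#' @export
read_session_log <- function(path, spec) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    stop_epelir("empty session log file", "epelir_parse_error")
  }
  header <- jsonlite::fromJSON(lines[[1L]], simplifyVector = TRUE)
  if (!identical(header$record, "session")) {
    stop_epelir("first record must be the session header", "epelir_parse_error")
  }
  assignment <- assign_condition(header$participant_index, spec)
  if (!identical(assignment$order, header$order)) {
    stop_epelir("session header order does not match counterbalancing scheme",
                "epelir_parse_error")
  }
  is_scen <- startsWith(lines, '{"record":"scenario"')
  scen_at <- which(is_scen)
  if (length(scen_at) == 0L) {
    stop_epelir("no scenario records in session log", "epelir_parse_error")
  }
  bounds <- c(scen_at, length(lines) + 1L)
  logs <- vector("list", length(scen_at))
  for (i in seq_along(scen_at)) {
    sh <- jsonlite::fromJSON(lines[[scen_at[i]]])
    ev_lines <- lines[seq.int(scen_at[i] + 1L, bounds[i + 1L] - 1L)]
    ev_lines <- ev_lines[nzchar(ev_lines)]
    sl <- scenario_log(sh$scenario_id, sh$distractors_on, parse_event_lines(ev_lines))
    viol <- validate_log(sl, spec)
    if (nrow(viol)) {
      stop_epelir(paste(c(sprintf("invalid log for scenario %s:", sh$scenario_id),
                          sprintf("event %s: %s (%s)", viol$index, viol$rule,
                                  viol$detail)), collapse = "\n  "),
                  "epelir_log_error")
    }
    logs[[i]] <- sl
  }
  covs <- header$covariates
  session_log(header$participant_id, assignment, logs,
              if (is.null(covs)) list() else as.list(covs))
}

#' @export
print.epeli_scenario_log <- function(x, ...) {
  cat(sprintf("Scenario log %s: %d events, distractors %s\n", x$scenario_id,
              nrow(x$events), if (x$distractors_on) "on" else "off"))
  invisible(x)
}

#' @export
print.epeli_session_log <- function(x, ...) {
  cat(sprintf("Session log for participant %s: %d scenarios, %s order\n",
              x$participant_id, length(x$scenario_logs), x$assignment$order))
  invisible(x)
}
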