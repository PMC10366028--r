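# Independent oracles, deliberately coded apart from the package internals:
# a subtask-major naive rescoring of a scenario log, and a brute-force
# shortest-path search by simple-path enumeration.

oracle_eight_measures <- function(log, spec) {
  ev <- log$events
  scen <- NULL
  for (s in spec$scenarios) if (s$id == log$scenario_id) scen <- s
  fp <- spec$floorplan
  obj_x <- setNames(fp$objects$x, fp$objects$id)
  obj_y <- setNames(fp$objects$y, fp$objects$id)
  wp_x <- setNames(fp$waypoints$x, fp$waypoints$id)
  wp_y <- setNames(fp$waypoints$y, fp$waypoints$id)

  ie <- which(ev$type == "instruction_end")[1L]
  te <- ev$t_s - ev$t_s[ie]
  exec <- ev$phase == "execution"
  act_rows <- which(exec & ev$type %in% c("click_object", "pickup", "drop",
                                          "drum_hit"))

  # subtask-major completion scan; records which action rows were consumed
  consumed <- integer()
  completions <- list()
  for (st in scen$subtasks) {
    demands <- list()
    for (step in st$steps) {
      if (step$action == "interact") {
        demands[[length(demands) + 1L]] <- c("interact", step$object_id, NA)
      } else {
        demands[[length(demands) + 1L]] <- c("pickup", step$object_id, NA)
        demands[[length(demands) + 1L]] <- c("drop", step$object_id,
                                             step$destination_id)
      }
    }
    d <- 1L
    rows_used <- integer()
    for (i in act_rows) {
      if (d > length(demands)) break
      want <- demands[[d]]
      type <- ev$type[i]
      ok <- switch(want[1L],
        interact = type %in% c("click_object", "drum_hit") &&
          identical(ev$object_id[i], want[2L]),
        pickup = type == "pickup" && identical(ev$object_id[i], want[2L]),
        drop = type == "drop" && identical(ev$object_id[i], want[2L]) &&
          identical(ev$waypoint_id[i], want[3L]))
      if (isTRUE(ok)) {
        rows_used <- c(rows_used, i)
        d <- d + 1L
      }
    }
    if (d > length(demands)) {
      completions[[st$id]] <- te[rows_used[length(rows_used)]]
      consumed <- c(consumed, rows_used)
    }
  }

  total <- length(completions)
  n_act <- length(act_rows)
  n_rel <- sum(act_rows %in% consumed)
  eff <- if (n_act > 0) n_rel / n_act else NA_real_

  # distances
  tp_rows <- which(exec & ev$type == "click_waypoint")
  pos <- fp$entry_waypoint
  walked <- 0
  for (i in tp_rows) {
    w <- ev$waypoint_id[i]
    walked <- walked + sqrt((wp_x[w] - wp_x[pos])^2 + (wp_y[w] - wp_y[pos])^2)
    pos <- w
  }
  reach <- 0
  for (i in act_rows) {
    if (!ev$type[i] %in% c("click_object", "pickup", "drum_hit")) next
    before <- tp_rows[tp_rows < i]
    at <- if (length(before)) ev$waypoint_id[before[length(before)]] else
      fp$entry_waypoint
    ob <- ev$object_id[i]
    reach <- reach + sqrt((obj_x[ob] - wp_x[at])^2 + (obj_y[ob] - wp_y[at])^2)
  }
  nav <- if (walked + reach > 0) total / (walked + reach) else NA_real_

  # controller motion, scalar loop
  ori <- which(exec & ev$type == "orientation_sample")
  motion <- 0
  if (length(ori) > 1L) {
    for (j in seq_len(length(ori) - 1L)) {
      a <- c(ev$qw[ori[j]], ev$qx[ori[j]], ev$qy[ori[j]], ev$qz[ori[j]])
      b <- c(ev$qw[ori[j + 1L]], ev$qx[ori[j + 1L]], ev$qy[ori[j + 1L]],
             ev$qz[ori[j + 1L]])
      motion <- motion + 2 * acos(min(1, abs(sum(a * b)))) * 180 / pi
    }
  }

  actions <- sum(ev$type %in% c("click_object", "pickup", "drop", "drum_hit"))

  tbpm <- 0L
  ebpm <- 0L
  for (st in scen$subtasks) {
    ct <- completions[[st$id]]
    if (is.null(ct)) next
    if (st$kind == "time_based" && abs(ct - st$target_time_s) <= spec$tbpm_halfwidth_s) {
      tbpm <- tbpm + 1L
    }
    if (st$kind == "event_based") {
      cue_rows <- which(ev$type == "cue_onset" & ev$cue_id == st$cue_id)
      cue <- if (length(cue_rows)) te[cue_rows[1L]] else st$cue_time_s
      if (ct >= cue && ct <= cue + spec$ebpm_window_s) ebpm <- ebpm + 1L
    }
  }

  clocks <- sum(exec & ev$type == "clock_check")

  list(total_score = total, task_efficacy = unname(eff),
       navigation_efficacy = unname(nav),
       controller_motion_deg = unname(motion), total_actions = actions,
       tbpm = tbpm, clock_checks = clocks, ebpm = ebpm)
}

# brute-force shortest path by enumeration of all simple paths
brute_force_distance <- function(nodes, edges, w, a, b) {
  if (a == b) return(0)
  adj <- lapply(nodes, function(v) {
    c(edges$to[edges$from == v], edges$from[edges$to == v])
  })
  names(adj) <- nodes
  ew <- function(u, v) {
    hit <- (edges$from == u & edges$to == v) | (edges$from == v & edges$to == u)
    min(w[hit])
  }
  best <- Inf
  recurse <- function(v, visited, d) {
    if (d >= best) return()
    if (v == b) { best <<- d; return() }
    for (u in adj[[v]]) {
      if (!u %in% visited) recurse(u, c(visited, u), d + ew(v, u))
    }
  }
  recurse(a, a, 0)
  best
}
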