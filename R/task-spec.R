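# Task specification: scenarios, subtasks, floor plan, counterbalancing.
#
# The assessment is a virtual-apartment errand task: 13 short everyday
# scenarios, each a bundle of 4-6 subtasks given orally during an instruction
# phase and then executed under a 90 s limit. Subtasks are "anytime"
# (performable whenever), "time_based" (to be done at a stated clock time;
# scored as prospective-memory hits within +/-10 s) or "event_based"
# (triggered by a sound cue; scored within 10 s of cue onset).

.epelir_cache <- new.env(parent = emptyenv())

spec_token <- function(spec) {
  tok <- attr(spec, "epelir_token")
  if (is.null(tok)) {
    n <- (get0("token_counter", envir = .epelir_cache) %||% 0L) + 1L
    assign("token_counter", n, envir = .epelir_cache)
    tok <- paste0("spec", n)
  }
  tok
}

# Tag a hand-assembled spec list as an epeli_task_spec (fresh cache token).
as_task_spec <- function(x) {
  attr(x, "epelir_token") <- NULL
  class(x) <- "epeli_task_spec"
  attr(x, "epelir_token") <- spec_token(x)
  x
}

ROOMS <- c("living_room", "kitchen", "adult_bedroom", "childrens_room",
           "utility_room", "bathroom")

default_floorplan <- function() {
  rooms <- fast_df(list(
    name = c(ROOMS, "balcony"),
    reachable = c(rep(TRUE, 6L), FALSE)))
  waypoints <- fast_df(list(
    id = c("wp_liv_1", "wp_liv_2", "wp_liv_3", "wp_kit_1", "wp_kit_2",
           "wp_adb_1", "wp_adb_2", "wp_chr_1", "wp_chr_2", "wp_uti_1",
           "wp_bat_1"),
    room = c("living_room", "living_room", "living_room", "kitchen", "kitchen",
             "adult_bedroom", "adult_bedroom", "childrens_room",
             "childrens_room", "utility_room", "bathroom"),
    x = c(0, 3, 1.5, 6, 8, 0, 2, 6, 8, 11, 11),
    y = c(0, 0, 2.5, 0, 1.5, 5, 6.5, 5, 6.5, 1, 5)))
  # full connection within each room + one doorway edge per adjacent room pair
  edges <- rbind(
    c("wp_liv_1", "wp_liv_2"), c("wp_liv_1", "wp_liv_3"),
    c("wp_liv_2", "wp_liv_3"), c("wp_kit_1", "wp_kit_2"),
    c("wp_adb_1", "wp_adb_2"), c("wp_chr_1", "wp_chr_2"),
    c("wp_liv_2", "wp_kit_1"), c("wp_liv_1", "wp_adb_1"),
    c("wp_liv_3", "wp_chr_1"), c("wp_kit_2", "wp_uti_1"),
    c("wp_uti_1", "wp_bat_1"))
  teleport_edges <- fast_df(list(from = edges[, 1L], to = edges[, 2L]))
  list(rooms = rooms, waypoints = waypoints, teleport_edges = teleport_edges,
       objects = NULL, entry_waypoint = "wp_liv_1")
}

#' Construct the bundled default task specification
#'
#' Builds the default assessment structure entirely in code: 13 scenarios
#' holding 70 subtasks in total (52 any-time, 13 time-based, 5 event-based),
#' a 90 s execution limit per scenario, inclusive +/-10 s and 10 s
#' prospective-memory scoring windows, a 7/6 split of scenarios carrying
#' distractors in the forward and reverse play orders, and a six-room floor
#' plan with waypoint teleport navigation. The same structure is shipped as a
#' YAML document under `inst/extdata/default_task_spec.yaml`.
#'
#' @return An object of class `epeli_task_spec`.
#' @export
#' @examples
#' spec <- default_task_spec()
#' print(spec)
default_task_spec <- function() {
  n_sub <- c(6L, 5L, 6L, 5L, 6L, 5L, 6L, 5L, 6L, 5L, 6L, 5L, 4L)
  eb_scen <- c("s02", "s05", "s08", "s10", "s12")
  tb_target <- c(45, 60, 50, 70, 40, 65, 55, 75, 35, 60, 50, 70, 45)
  eb_cue <- c(s02 = 30, s05 = 40, s08 = 35, s10 = 50, s12 = 45)
  themes <- c(
    "getting ready for school", "coming home from school", "meal preparation",
    "tidying the living room", "pet care afternoon", "homework and play time",
    "laundry day", "setting the table", "birthday preparations",
    "evening wash-up", "packing for a trip", "helping with groceries",
    "bedtime routine")

  fp <- default_floorplan()
  room_cycle <- ROOMS
  obj_rows <- list()
  add_obj <- function(id, room, dx, dy, movable = FALSE, drum = FALSE,
                      clock_visible = FALSE, irrelevant = FALSE) {
    wp <- fp$waypoints[match(room, fp$waypoints$room), ]
    obj_rows[[length(obj_rows) + 1L]] <<- list(
      id = id, room = room, x = wp$x + dx, y = wp$y + dy, movable = movable,
      drum = drum, clock_visible = clock_visible, irrelevant = irrelevant)
    id
  }

  scenarios <- vector("list", 13L)
  oi <- 0L # running object counter, used to vary placement offsets
  for (s in seq_len(13L)) {
    sid <- sprintf("s%02d", s)
    n <- n_sub[s]
    tb_pos <- 3L
    eb_pos <- if (sid %in% eb_scen) n else NA_integer_
    subtasks <- vector("list", n)
    for (p in seq_len(n)) {
      stid <- sprintf("%s_t%d", sid, p)
      kind <- if (p == tb_pos) "time_based" else
        if (!is.na(eb_pos) && p == eb_pos) "event_based" else "anytime"
      oi <- oi + 1L
      room <- room_cycle[(oi - 1L) %% 6L + 1L]
      off <- 0.4 + 0.2 * ((oi - 1L) %% 5L)
      if (p == 2L) {
        # transport subtask: pick a movable object up and drop it at a
        # waypoint in a different room
        obj <- add_obj(sprintf("o_%s_%d", sid, p), room, off, 0.5, movable = TRUE)
        dest_room <- room_cycle[oi %% 6L + 1L]
        dest <- fp$waypoints$id[match(dest_room, fp$waypoints$room)]
        steps <- list(list(action = "transport", object_id = obj,
                           destination_id = dest))
        label <- sprintf("take the %s to the %s", obj, dest_room)
      } else if (sid == "s06" && p == 4L) {
        steps <- list(list(action = "interact", object_id = "o_drum"))
        label <- "play the drums in the children's room"
      } else if (p == 1L && n == 6L) {
        # two-step subtask, e.g. "turn off the tap and hang up the towel"
        obj1 <- add_obj(sprintf("o_%s_%da", sid, p), room, off, 0.3)
        oi <- oi + 1L
        room2 <- room_cycle[(oi - 1L) %% 6L + 1L]
        obj2 <- add_obj(sprintf("o_%s_%db", sid, p), room2, off, 0.9)
        steps <- list(list(action = "interact", object_id = obj1),
                      list(action = "interact", object_id = obj2))
        label <- sprintf("use the %s and then the %s", obj1, obj2)
      } else {
        obj <- add_obj(sprintf("o_%s_%d", sid, p), room, off, 0.6)
        steps <- list(list(action = "interact", object_id = obj))
        label <- switch(kind,
          time_based = sprintf("use the %s at the given time", obj),
          event_based = sprintf("use the %s when you hear the cue", obj),
          sprintf("use the %s", obj))
      }
      st <- list(id = stid, scenario_id = sid, kind = kind, position = p,
                 steps = steps, label = label)
      if (kind == "time_based") st$target_time_s <- tb_target[s]
      if (kind == "event_based") {
        st$cue_id <- paste0("cue_", sid)
        st$cue_time_s <- unname(eb_cue[sid])
      }
      subtasks[[p]] <- st
    }
    scenarios[[s]] <- list(id = sid, theme = themes[s],
                           instruction_duration_s = 4 + 2.5 * n,
                           subtasks = subtasks)
  }

  add_obj("o_drum", "childrens_room", 1.0, 0.2, drum = TRUE)
  add_obj("o_wallclock", "kitchen", 0.1, 1.0, clock_visible = TRUE)
  for (room in ROOMS) {
    add_obj(paste0("irr_", room, "_1"), room, 1.2, -0.3, irrelevant = TRUE)
    add_obj(paste0("irr_", room, "_2"), room, -0.5, 0.8, irrelevant = TRUE)
  }
  fp$objects <- fast_df(list(
    id = vapply(obj_rows, `[[`, "", "id"),
    room = vapply(obj_rows, `[[`, "", "room"),
    x = vapply(obj_rows, `[[`, 0, "x"),
    y = vapply(obj_rows, `[[`, 0, "y"),
    movable = vapply(obj_rows, `[[`, FALSE, "movable"),
    drum = vapply(obj_rows, `[[`, FALSE, "drum"),
    clock_visible = vapply(obj_rows, `[[`, FALSE, "clock_visible"),
    irrelevant = vapply(obj_rows, `[[`, FALSE, "irrelevant")))

  ids <- sprintf("s%02d", 1:13)
  spec <- structure(
    list(scenarios = scenarios,
         time_limit_s = 90,
         tbpm_halfwidth_s = 10,
         ebpm_window_s = 10,
         distractor_set_forward = ids[seq(1L, 13L, by = 2L)],
         distractor_set_reverse = ids[seq(2L, 12L, by = 2L)],
         floorplan = fp),
    class = "epeli_task_spec")
  attr(spec, "epelir_token") <- spec_token(spec)
  validate_task_spec(spec, strict = TRUE)
}

scenario_ids <- function(spec) vapply(spec$scenarios, `[[`, "", "id")

all_subtasks <- function(spec) {
  unlist(lapply(spec$scenarios, `[[`, "subtasks"), recursive = FALSE)
}

#' Validate a task specification
#'
#' Checks referential integrity (every object, waypoint and cue referenced by
#' a subtask exists in the floor plan), per-scenario structure (4-6 subtasks,
#' kind-conditional fields, timing targets inside the scenario limit) and, in
#' strict mode, the default task's printed totals: 13 scenarios, 70 subtasks
#' split 52/13/5 across kinds, a 90 s limit, 10 s scoring windows, and a 7 + 6
#' distractor partition of the scenarios.
#'
#' @param spec An `epeli_task_spec`.
#' @param strict Enforce the default structural totals (set `FALSE` to allow
#'   research variants with different counts).
#' @return The validated spec, invisibly. Errors of class
#'   `epelir_ref_error` / `epelir_structure_error` describe violations.
#' @export
validate_task_spec <- function(spec, strict = TRUE) {
  probs_ref <- character()
  probs_struct <- character()
  fp <- spec$floorplan
  wp_ids <- fp$waypoints$id
  obj_ids <- fp$objects$id
  reach_rooms <- fp$rooms$name[fp$rooms$reachable]

  if (any(!fp$waypoints$room %in% reach_rooms)) {
    probs_struct <- c(probs_struct, "waypoint placed in an unreachable room")
  }
  if (!spec$floorplan$entry_waypoint %in% wp_ids) {
    probs_ref <- c(probs_ref, "entry waypoint not in waypoint table")
  }
  bad_edge <- !(fp$teleport_edges$from %in% wp_ids) |
    !(fp$teleport_edges$to %in% wp_ids)
  if (any(bad_edge)) probs_ref <- c(probs_ref, "teleport edge references unknown waypoint")
  g <- igraph::graph_from_data_frame(fp$teleport_edges, directed = FALSE,
                                     vertices = fp$waypoints$id)
  if (!igraph::is_connected(g)) {
    probs_struct <- c(probs_struct, "teleport graph is not connected")
  }

  counts <- c(anytime = 0L, time_based = 0L, event_based = 0L)
  for (sc in spec$scenarios) {
    n <- length(sc$subtasks)
    if (n < 4L || n > 6L) {
      probs_struct <- c(probs_struct, sprintf(
        "scenario %s has %d subtasks (must be 4-6)", sc$id, n))
    }
    for (st in sc$subtasks) {
      counts[st$kind] <- counts[st$kind] + 1L
      if (!st$kind %in% c("anytime", "time_based", "event_based")) {
        probs_struct <- c(probs_struct, sprintf("subtask %s: unknown kind", st$id))
        next
      }
      if (length(st$steps) == 0L) {
        probs_struct <- c(probs_struct, sprintf("subtask %s: empty steps", st$id))
      }
      if (st$kind == "time_based") {
        if (is.null(st$target_time_s) ||
            st$target_time_s < 0 || st$target_time_s > spec$time_limit_s) {
          probs_struct <- c(probs_struct, sprintf(
            "subtask %s: time_based requires target_time_s in [0, %g]",
            st$id, spec$time_limit_s))
        }
      } else if (!is.null(st$target_time_s)) {
        probs_struct <- c(probs_struct, sprintf(
          "subtask %s: target_time_s only allowed for time_based", st$id))
      }
      if (st$kind == "event_based") {
        if (is.null(st$cue_id) || is.null(st$cue_time_s) ||
            st$cue_time_s >= spec$time_limit_s) {
          probs_ref <- c(probs_ref, sprintf(
            "subtask %s: event_based requires cue_id and cue_time_s < %g",
            st$id, spec$time_limit_s))
        }
      } else if (!is.null(st$cue_id) || !is.null(st$cue_time_s)) {
        probs_struct <- c(probs_struct, sprintf(
          "subtask %s: cue fields only allowed for event_based", st$id))
      }
      for (step in st$steps) {
        if (!step$action %in% c("interact", "transport")) {
          probs_struct <- c(probs_struct, sprintf(
            "subtask %s: unknown step action '%s'", st$id, step$action))
        }
        if (!step$object_id %in% obj_ids) {
          probs_ref <- c(probs_ref, sprintf(
            "subtask %s: unknown object '%s'", st$id, step$object_id))
        }
        if (identical(step$action, "transport") &&
            (is.null(step$destination_id) || !step$destination_id %in% wp_ids)) {
          probs_ref <- c(probs_ref, sprintf(
            "subtask %s: transport destination missing or unknown", st$id))
        }
      }
    }
  }

  if (strict) {
    ids <- scenario_ids(spec)
    if (length(ids) != 13L) {
      probs_struct <- c(probs_struct, sprintf("expected 13 scenarios, found %d", length(ids)))
    }
    total <- sum(counts)
    if (total != 70L || counts[["anytime"]] != 52L ||
        counts[["time_based"]] != 13L || counts[["event_based"]] != 5L) {
      probs_struct <- c(probs_struct, sprintf(
        "expected 70 subtasks as 52/13/5 anytime/time/event, found %d as %d/%d/%d",
        total, counts[["anytime"]], counts[["time_based"]], counts[["event_based"]]))
    }
    if (spec$time_limit_s != 90) {
      probs_struct <- c(probs_struct, "time_limit_s must be 90 in strict mode")
    }
    if (spec$tbpm_halfwidth_s != 10 || spec$ebpm_window_s != 10) {
      probs_struct <- c(probs_struct, "scoring windows must be 10 s in strict mode")
    }
    fwd <- spec$distractor_set_forward
    rev_ <- spec$distractor_set_reverse
    if (length(fwd) != 7L || length(rev_) != 6L ||
        length(intersect(fwd, rev_)) != 0L ||
        !setequal(union(fwd, rev_), ids)) {
      probs_struct <- c(probs_struct,
        "distractor sets must partition the 13 scenarios as 7 (forward) + 6 (reverse)")
    }
  }

  if (length(probs_ref)) {
    stop_epelir(paste(c("task spec referential errors:", probs_ref), collapse = "\n  "),
                "epelir_ref_error")
  }
  if (length(probs_struct)) {
    stop_epelir(paste(c("task spec structural violations:", probs_struct), collapse = "\n  "),
                "epelir_structure_error")
  }
  invisible(spec)
}

# ---------------------------------------------------------------------------
# YAML serialization

spec_to_list <- function(spec) {
  df_to_records <- function(df) {
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  list(
    time_limit_s = spec$time_limit_s,
    tbpm_halfwidth_s = spec$tbpm_halfwidth_s,
    ebpm_window_s = spec$ebpm_window_s,
    distractor_set_forward = as.list(spec$distractor_set_forward),
    distractor_set_reverse = as.list(spec$distractor_set_reverse),
    scenarios = spec$scenarios,
    floorplan = list(
      entry_waypoint = spec$floorplan$entry_waypoint,
      rooms = df_to_records(spec$floorplan$rooms),
      waypoints = df_to_records(spec$floorplan$waypoints),
      teleport_edges = df_to_records(spec$floorplan$teleport_edges),
      objects = df_to_records(spec$floorplan$objects)))
}

records_to_df <- function(recs, proto) {
  cols <- lapply(names(proto), function(nm) {
    vapply(recs, function(r) {
      v <- r[[nm]]
      if (is.null(v)) proto[[nm]] else v
    }, proto[[nm]])
  })
  names(cols) <- names(proto)
  fast_df(cols)
}

list_to_spec <- function(x) {
  scen <- lapply(x$scenarios, function(sc) {
    sc$instruction_duration_s <- as.numeric(sc$instruction_duration_s)
    sc$subtasks <- lapply(sc$subtasks, function(st) {
      st$position <- as.integer(st$position)
      if (!is.null(st$target_time_s)) st$target_time_s <- as.numeric(st$target_time_s)
      if (!is.null(st$cue_time_s)) st$cue_time_s <- as.numeric(st$cue_time_s)
      st$steps <- lapply(st$steps, function(step) step)
      st
    })
    sc
  })
  fp_in <- x$floorplan
  fp <- list(
    rooms = records_to_df(fp_in$rooms, list(name = "", reachable = TRUE)),
    waypoints = records_to_df(fp_in$waypoints,
                              list(id = "", room = "", x = 0, y = 0)),
    teleport_edges = records_to_df(fp_in$teleport_edges, list(from = "", to = "")),
    objects = records_to_df(fp_in$objects,
                            list(id = "", room = "", x = 0, y = 0, movable = FALSE,
                                 drum = FALSE, clock_visible = FALSE,
                                 irrelevant = FALSE)),
    entry_waypoint = fp_in$entry_waypoint)
  structure(list(scenarios = scen,
                 time_limit_s = as.numeric(x$time_limit_s),
                 tbpm_halfwidth_s = as.numeric(x$tbpm_halfwidth_s),
                 ebpm_window_s = as.numeric(x$ebpm_window_s),
                 distractor_set_forward = unlist(x$distractor_set_forward),
                 distractor_set_reverse = unlist(x$distractor_set_reverse),
                 floorplan = fp),
            class = "epeli_task_spec")
}

#' Read a task specification from YAML
#'
#' @param path Path to a YAML task-spec document. `NULL` loads the bundled
#'   default specification shipped with the package.
#' @param strict Enforce the default structural totals (see
#'   [validate_task_spec()]).
#' @return A validated `epeli_task_spec`.
#' @export
load_task_spec <- function(path = NULL, strict = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_task_spec.yaml", package = "epelir")
  }
  if (!file.exists(path)) {
    stop_epelir(sprintf("task spec file not found: %s", path), "epelir_parse_error")
  }
  x <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_epelir(sprintf("task spec parse failure: %s", conditionMessage(e)),
                "epelir_parse_error")
  })
  spec <- list_to_spec(x)
  attr(spec, "epelir_token") <- spec_token(spec)
  validate_task_spec(spec, strict = strict)
  spec
}

#' Write a task specification to YAML
#'
#' @param spec An `epeli_task_spec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_task_spec <- function(spec, path) {
  yaml::write_yaml(spec_to_list(spec), path, precision = 12L)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Counterbalancing

#' Counterbalancing assignment for one participant
#'
#' Participants alternate between the forward and the reverse scenario order
#' (even 0-based index: forward). The scenarios carrying distractors follow
#' the order, so that over any even number of consecutive participants every
#' scenario is played with distractors in exactly half of the gameplays.
#'
#' @param participant_index 0-based participant index.
#' @param spec An `epeli_task_spec`.
#' @return An `epeli_assignment`: list with `participant_index`, `order`
#'   (`"forward"` or `"reverse"`), `scenario_order` (ids in played order) and
#'   `distractor_scenarios`.
#' @export
#' @examples
#' spec <- default_task_spec()
#' assign_condition(0, spec)$order   # "forward"
#' assign_condition(1, spec)$order   # "reverse"
assign_condition <- function(participant_index, spec) {
  if (length(participant_index) != 1L || is.na(participant_index) ||
      participant_index < 0 || participant_index != floor(participant_index)) {
    stop_epelir("participant_index must be a single non-negative integer",
                "epelir_structure_error")
  }
  ids <- scenario_ids(spec)
  forward <- participant_index %% 2 == 0
  structure(list(
    participant_index = as.integer(participant_index),
    order = if (forward) "forward" else "reverse",
    scenario_order = if (forward) ids else rev(ids),
    distractor_scenarios = if (forward) spec$distractor_set_forward
                           else spec$distractor_set_reverse),
    class = "epeli_assignment")
}

# ---------------------------------------------------------------------------
# Navigation

fp_igraph <- function(floorplan) {
  wp <- floorplan$waypoints
  e <- floorplan$teleport_edges
  i <- match(e$from, wp$id)
  j <- match(e$to, wp$id)
  w <- sqrt((wp$x[i] - wp$x[j])^2 + (wp$y[i] - wp$y[j])^2)
  g <- igraph::graph_from_data_frame(
    fast_df(list(from = e$from, to = e$to, weight = w)),
    directed = FALSE, vertices = wp$id)
  g
}

#' Shortest teleport-path distance between two waypoints
#'
#' Length of the shortest path over the teleport graph with Euclidean edge
#' weights, in metres.
#'
#' @param floorplan A floor plan (component `floorplan` of an
#'   `epeli_task_spec`).
#' @param a,b Waypoint ids.
#' @return Distance in metres (0 when `a == b`).
#' @export
path_distance <- function(floorplan, a, b) {
  wp_ids <- floorplan$waypoints$id
  if (!a %in% wp_ids || !b %in% wp_ids) {
    stop_epelir(sprintf("unknown waypoint: %s",
                        paste(setdiff(c(a, b), wp_ids), collapse = ", ")),
                "epelir_ref_error")
  }
  if (a == b) return(0)
  d <- igraph::distances(fp_igraph(floorplan), v = a, to = b)[1L, 1L]
  if (!is.finite(d)) {
    stop_epelir(sprintf("waypoints %s and %s are not connected", a, b),
                "epelir_ref_error")
  }
  d
}

# Cached all-pairs routing for a spec: distance matrix plus next-step paths.
route_table <- function(spec) {
  tok <- attr(spec, "epelir_token") %||% "anon"
  key <- paste0("routes_", tok)
  rt <- get0(key, envir = .epelir_cache)
  if (!is.null(rt)) return(rt)
  g <- fp_igraph(spec$floorplan)
  ids <- spec$floorplan$waypoints$id
  dmat <- igraph::distances(g)
  paths <- vector("list", length(ids))
  names(paths) <- ids
  for (a in ids) {
    sp <- igraph::shortest_paths(g, from = a, to = ids, output = "vpath")$vpath
    paths[[a]] <- lapply(sp, function(v) names(v))
    names(paths[[a]]) <- ids
  }
  wp <- spec$floorplan$waypoints
  obj <- spec$floorplan$objects
  # each object is served from the nearest waypoint of its room
  obj_wp <- vapply(seq_len(nrow(obj)), function(k) {
    cand <- which(wp$room == obj$room[k])
    cand[which.min((wp$x[cand] - obj$x[k])^2 + (wp$y[cand] - obj$y[k])^2)]
  }, 1L)
  nbrs <- lapply(igraph::adjacent_vertices(g, ids), names)
  names(nbrs) <- ids
  rt <- list(ids = ids, dmat = dmat, paths = paths, nbrs = nbrs,
             wp_xy = cbind(wp$x, wp$y),
             obj_ids = obj$id, obj_xy = cbind(obj$x, obj$y),
             obj_wp = wp$id[obj_wp],
             irrelevant_objs = obj$id[obj$irrelevant],
             drum_objs = obj$id[obj$drum])
  assign(key, rt, envir = .epelir_cache)
  rt
}

# Expanded per-scenario completion machine: each subtask becomes an ordered
# list of micro-steps ("interact" | "pickup" | "drop").
scenario_micro_steps <- function(scenario) {
  lapply(scenario$subtasks, function(st) {
    micro <- list()
    for (step in st$steps) {
      if (step$action == "interact") {
        micro[[length(micro) + 1L]] <- list(op = "interact", object = step$object_id)
      } else {
        micro[[length(micro) + 1L]] <- list(op = "pickup", object = step$object_id)
        micro[[length(micro) + 1L]] <- list(op = "drop", object = step$object_id,
                                            dest = step$destination_id)
      }
    }
    list(id = st$id, kind = st$kind, micro = micro,
         target_time_s = st$target_time_s %||% NA_real_,
         cue_id = st$cue_id %||% NA_character_,
         cue_time_s = st$cue_time_s %||% NA_real_)
  })
}

# Flattened, cached completion machine for one scenario: micro-steps of all
# subtasks as parallel vectors for fast matching during replay.
scenario_machine <- function(spec, scenario) {
  tok <- attr(spec, "epelir_token") %||% "anon"
  key <- paste0("machine_", tok, "_", scenario$id)
  m <- get0(key, envir = .epelir_cache)
  if (!is.null(m)) return(m)
  sts <- scenario_micro_steps(scenario)
  cand_sub <- integer(); cand_mic <- integer(); cand_op <- character()
  cand_obj <- character(); cand_dest <- character()
  for (si in seq_along(sts)) {
    for (mi in seq_along(sts[[si]]$micro)) {
      mm <- sts[[si]]$micro[[mi]]
      cand_sub <- c(cand_sub, si); cand_mic <- c(cand_mic, mi)
      cand_op <- c(cand_op, mm$op); cand_obj <- c(cand_obj, mm$object)
      cand_dest <- c(cand_dest, mm$dest %||% NA_character_)
    }
  }
  m <- list(n_subtasks = length(sts),
            subtask_ids = vapply(sts, `[[`, "", "id"),
            n_micro = vapply(sts, function(s) length(s$micro), 1L),
            cand_sub = cand_sub, cand_mic = cand_mic, cand_op = cand_op,
            cand_obj = cand_obj, cand_dest = cand_dest)
  assign(key, m, envir = .epelir_cache)
  m
}

#' @export
print.epeli_task_spec <- function(x, ...) {
  sts <- all_subtasks(x)
  kind_vec <- vapply(sts, `[[`, "", "kind")
  cat(sprintf("Task specification: %d scenarios, %d subtasks (%d anytime, %d time-based, %d event-based)\n",
              length(x$scenarios), length(sts),
              sum(kind_vec == "anytime"), sum(kind_vec == "time_based"),
              sum(kind_vec == "event_based")))
  cat(sprintf("  execution limit %g s; TBPM window +/-%g s; EBPM window %g s\n",
              x$time_limit_s, x$tbpm_halfwidth_s, x$ebpm_window_s))
  cat(sprintf("  distractor scenarios: forward %d, reverse %d\n",
              length(x$distractor_set_forward), length(x$distractor_set_reverse)))
  cat(sprintf("  floor plan: %d rooms, %d waypoints, %d objects\n",
              sum(x$floorplan$rooms$reachable), nrow(x$floorplan$waypoints),
              nrow(x$floorplan$objects)))
  invisible(x)
}

#' @export
print.epeli_assignment <- function(x, ...) {
  cat(sprintf("Participant %d: %s order, distractors in %s\n",
              x$participant_index, x$order,
              paste(x$distractor_scenarios, collapse = ", ")))
  invisible(x)
}
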