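# Hand-built fixtures: a two-room mini task spec and event-table builders.
# The mini spec keeps the geometry trivial (one 3-4-5 edge) so expected
# distances and scores can be derived by hand.

tiny_spec <- function() {
  rooms <- data.frame(name = c("roomA", "roomB"), reachable = c(TRUE, TRUE))
  waypoints <- data.frame(id = c("wA", "wB"), room = c("roomA", "roomB"),
                          x = c(0, 3), y = c(0, 4))
  teleport_edges <- data.frame(from = "wA", to = "wB")
  objects <- data.frame(
    id = c("oA1", "oA2", "oA3", "oMov", "oB1", "irrX"),
    room = c("roomA", "roomA", "roomA", "roomA", "roomB", "roomA"),
    x = c(0, 0, 0, 1, 3, 0),
    y = c(1, 2, 3, 0, 5, 4),
    movable = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    drum = FALSE, clock_visible = FALSE,
    irrelevant = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  scen <- list(
    id = "t01", theme = "mini errands", instruction_duration_s = 10,
    subtasks = list(
      list(id = "t01_1", scenario_id = "t01", kind = "anytime", position = 1L,
           steps = list(list(action = "interact", object_id = "oA1")),
           label = "use oA1"),
      list(id = "t01_2", scenario_id = "t01", kind = "anytime", position = 2L,
           steps = list(list(action = "transport", object_id = "oMov",
                             destination_id = "wB")),
           label = "take oMov to roomB"),
      list(id = "t01_3", scenario_id = "t01", kind = "time_based",
           position = 3L,
           steps = list(list(action = "interact", object_id = "oB1")),
           target_time_s = 40, label = "use oB1 at the given time"),
      list(id = "t01_4", scenario_id = "t01", kind = "event_based",
           position = 4L,
           steps = list(list(action = "interact", object_id = "oA2")),
           cue_id = "c1", cue_time_s = 30, label = "use oA2 on cue"),
      list(id = "t01_5", scenario_id = "t01", kind = "anytime", position = 5L,
           steps = list(list(action = "interact", object_id = "oA3")),
           label = "use oA3")))
  spec <- list(scenarios = list(scen), time_limit_s = 90,
               tbpm_halfwidth_s = 10, ebpm_window_s = 10,
               distractor_set_forward = "t01",
               distractor_set_reverse = character(),
               floorplan = list(rooms = rooms, waypoints = waypoints,
                                teleport_edges = teleport_edges,
                                objects = objects, entry_waypoint = "wA"))
  spec <- epelir:::as_task_spec(spec)
  validate_task_spec(spec, strict = FALSE)
  spec
}

# Build an event table from compact arguments; t gives the execution clock
# for execution events, and scenario bracketing is added automatically.
make_events <- function(t, type, object = NA_character_,
                        waypoint = NA_character_, cue = NA_character_,
                        D = 10, end = 90) {
  n <- length(t)
  object <- rep_len(object, n); waypoint <- rep_len(waypoint, n)
  cue <- rep_len(cue, n)
  o <- order(t)
  data.frame(
    t_s = c(0, D, D + t[o], D + end),
    phase = c("instruction", "instruction", rep("execution", n), "execution"),
    type = c("scenario_start", "instruction_end", type[o], "scenario_end"),
    object_id = c(NA, NA, object[o], NA),
    waypoint_id = c(NA, NA, waypoint[o], NA),
    cue_id = c(NA, NA, cue[o], NA))
}

tiny_log <- function(events, distractors_on = FALSE) {
  scenario_log("t01", distractors_on, events)
}

# quaternion path along a given axis with per-step angles (degrees), built
# by explicit quaternion composition
quat_walk <- function(axis, step_deg) {
  q <- c(1, 0, 0, 0)
  out <- matrix(0, length(step_deg) + 1L, 4L)
  out[1L, ] <- q
  for (i in seq_along(step_deg)) {
    q <- epelir:::quat_mult(epelir:::quat_axis_angle(axis, step_deg[i]), q)
    out[i + 1L, ] <- q
  }
  out
}

orientation_events <- function(qmat, t0 = 1, dt = 0.05, D = 10, end = 90) {
  n <- nrow(qmat)
  t <- t0 + dt * (seq_len(n) - 1L)
  data.frame(
    t_s = c(0, D, D + t, D + end),
    phase = c("instruction", "instruction", rep("execution", n), "execution"),
    type = c("scenario_start", "instruction_end",
             rep("orientation_sample", n), "scenario_end"),
    qw = c(NA, NA, qmat[, 1L], NA), qx = c(NA, NA, qmat[, 2L], NA),
    qy = c(NA, NA, qmat[, 3L], NA), qz = c(NA, NA, qmat[, 4L], NA))
}

# exchangeable item matrix with inter-item correlation rho (population
# alpha = k*rho / (1 + (k-1)*rho) by the Spearman-Brown relation)
exchangeable_items <- function(n, k, rho) {
  f <- rnorm(n)
  sqrt(rho) * matrix(f, n, k) + sqrt(1 - rho) * matrix(rnorm(n * k), n, k)
}
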