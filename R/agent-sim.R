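# Agent-based gameplay simulator.
#
# Stands in for child participants: latent behavioral traits (instruction
# encoding, impulsivity, motor activity, navigation noise, time monitoring,
# timing precision, cue responsiveness, action speed) drive a generative
# model of full gameplay event logs, plus covariate-side proxies (an
# instruction-recall score and parent-rating scalars). Covariate effects on
# the traits are chosen for qualitative sign structure only — girls and older
# children encode more and act less impulsively — and are not estimates of
# any reported coefficients.

#' Agent trait vector
#'
#' @param encode_p Probability that a subtask instruction is encoded.
#' @param impulsivity_rate Irrelevant interactions per second of execution.
#' @param motor_level Baseline angular controller speed, degrees/second.
#' @param motor_burst_deg Extra angular burst per action, degrees.
#' @param nav_noise_p Probability of a suboptimal teleport detour per hop.
#' @param monitor_rate Spontaneous clock checks per minute.
#' @param timing_sd_s SD (seconds) of time-based execution error.
#' @param cue_response_p Probability of responding to a cue within the window.
#' @param action_latency_s Mean time per interaction, seconds.
#' @return An `epeli_traits` list.
#' @export
agent_traits <- function(encode_p = 0.7, impulsivity_rate = 0.08,
                         motor_level = 60, motor_burst_deg = 25,
                         nav_noise_p = 0.15, monitor_rate = 2.5,
                         timing_sd_s = 6, cue_response_p = 0.8,
                         action_latency_s = 2) {
  tr <- list(encode_p = encode_p, impulsivity_rate = impulsivity_rate,
             motor_level = motor_level, motor_burst_deg = motor_burst_deg,
             nav_noise_p = nav_noise_p, monitor_rate = monitor_rate,
             timing_sd_s = timing_sd_s, cue_response_p = cue_response_p,
             action_latency_s = action_latency_s)
  for (p in c("encode_p", "nav_noise_p", "cue_response_p")) {
    if (tr[[p]] < 0 || tr[[p]] > 1) {
      stop_epelir(sprintf("%s must lie in [0, 1]", p), "epelir_structure_error")
    }
  }
  for (p in setdiff(names(tr), c("encode_p", "nav_noise_p", "cue_response_p"))) {
    if (tr[[p]] < 0) stop_epelir(sprintf("%s must be >= 0", p), "epelir_structure_error")
  }
  structure(tr, class = "epeli_traits")
}

#' An error-free agent: encodes everything, acts only on task goals
#'
#' Useful as a scoring ceiling: replaying its sessions yields the maximum
#' total score (70), task efficacy 1, TBPM 13 and EBPM 5.
#' @return An `epeli_traits`.
#' @export
ideal_traits <- function() {
  agent_traits(encode_p = 1, impulsivity_rate = 0, motor_level = 30,
               motor_burst_deg = 10, nav_noise_p = 0, monitor_rate = 2,
               timing_sd_s = 0, cue_response_p = 1, action_latency_s = 2)
}

#' Default population model for synthetic cohorts
#'
#' Covariate distributions follow the study-cohort shape (ages uniform on
#' 9-13 years, roughly 40% girls, mostly regular gamers, two headset types),
#' and the covariate-to-trait linear maps plant the qualitative sign
#' structure expected of this population: girls and older children encode
#' instructions better (higher total scores and efficacies) and act less
#' impulsively (fewer total actions); timing precision improves with age;
#' girls check the clock less. Parent-rating analogs rise with impulsivity
#' (behavioral-regulation scale) and fall with encoding (metacognition
#' scale); their sum forms the global composite. All values here are
#' configuration, not estimates.
#'
#' @return An `epeli_population_model` list with components `covariates`,
#'   `traits` (per-trait `base`, `b_age` per year centered at 11,
#'   `b_girl`, `sd`, `range`), `ratings`, `recall`, and simulator timing
#'   constants.
#' @export
default_population_model <- function() {
  structure(list(
    covariates = list(age_range = c(9, 13), p_girl = 31 / 77,
                      p_gaming = 67 / 77, familiarity_mean = 4.9,
                      familiarity_sd = 1.05, p_hmd = 0.4),
    traits = list(
      encode_p        = list(base = 0.55, b_age = 0.040, b_girl = 0.08,  sd = 0.08, range = c(0.05, 0.98)),
      impulsivity_rate = list(base = 0.08, b_age = -0.012, b_girl = -0.03, sd = 0.03, range = c(0.005, 0.40)),
      motor_level     = list(base = 60,   b_age = -3,    b_girl = -10,   sd = 15,   range = c(10, 150)),
      motor_burst_deg = list(base = 25,   b_age = 0,     b_girl = 0,     sd = 5,    range = c(5, 60)),
      nav_noise_p     = list(base = 0.15, b_age = -0.02, b_girl = -0.04, sd = 0.05, range = c(0, 0.6)),
      monitor_rate    = list(base = 2.5,  b_age = 0,     b_girl = -0.5,  sd = 0.8,  range = c(0.2, 10)),
      timing_sd_s     = list(base = 6,    b_age = -0.8,  b_girl = -0.5,  sd = 2,    range = c(0.5, 20)),
      cue_response_p  = list(base = 0.80, b_age = 0.01,  b_girl = 0.03,  sd = 0.10, range = c(0.05, 1)),
      action_latency_s = list(base = 2,   b_age = 0,     b_girl = 0,     sd = 0.3,  range = c(0.8, 5))),
    ratings = list(
      bri = list(intercept = 18, b_impulsivity = 160, sd = 4, range = c(0, 56)),
      mi = list(intercept = 58, b_encode = -30, sd = 6, range = c(0, 88)),
      gec_range = c(0, 144)),
    recall = list(items = 30L, intercept = 0, slope = 1),
    distractor_multiplier = 1.5,
    teleport_latency_s = 0.5,
    eb_latency_mean_s = 3,
    orientation_hz = 20,
    instruction_click_rate_frac = 0.3),
    class = "epeli_population_model")
}

#' Sample a synthetic cohort of covariates and latent traits
#'
#' @param model An `epeli_population_model`.
#' @param n Number of participants.
#' @param seed Integer seed; the cohort is reproducible under it.
#' @return List with `covariates` (data frame: `participant_id`,
#'   `participant_index`, `age_years`, `gender` (girl = 1, boy = 0),
#'   `gaming_regular`, `familiarity` (1-7), `hmd_type`) and `traits`
#'   (data frame of the latent trait values).
#' @export
sample_participants <- function(model, n, seed) {
  if (n < 1L) stop_epelir("n must be >= 1", "epelir_structure_error")
  cv <- model$covariates
  with_seed(seed, {
    age <- stats::runif(n, cv$age_range[1L], cv$age_range[2L])
    girl <- as.integer(stats::runif(n) < cv$p_girl)
    gaming <- as.integer(stats::runif(n) < cv$p_gaming)
    familiarity <- as.integer(clip(round(stats::rnorm(n, cv$familiarity_mean,
                                                      cv$familiarity_sd)), 1, 7))
    hmd <- as.integer(stats::runif(n) < cv$p_hmd)
    traits <- lapply(model$traits, function(tr) {
      clip(tr$base + tr$b_age * (age - 11) + tr$b_girl * girl +
             stats::rnorm(n, 0, tr$sd), tr$range[1L], tr$range[2L])
    })
    pid <- sprintf("p%03d", seq_len(n) - 1L)
    list(covariates = fast_df(list(
           participant_id = pid, participant_index = seq_len(n) - 1L,
           age_years = age, gender = girl, gaming_regular = gaming,
           familiarity = familiarity, hmd_type = hmd)),
         traits = fast_df(c(list(participant_id = pid), traits)))
  })
}

traits_from_row <- function(traits_df, i) {
  do.call(agent_traits, as.list(traits_df[i, setdiff(names(traits_df),
                                                     "participant_id")]))
}

# Truncated exponential on [0, upper]
rtexp <- function(n, mean, upper) {
  u <- stats::runif(n)
  -mean * log(1 - u * (1 - exp(-upper / mean)))
}

# ---------------------------------------------------------------------------
# Scenario simulation (execution clock te in [0, 90])

simulate_scenario_events <- function(traits, scenario, spec, distractors_on,
                                     model, rt) {
  D <- scenario$instruction_duration_s
  lim <- spec$time_limit_s
  n_st <- length(scenario$subtasks)
  encoded <- stats::runif(n_st) < traits$encode_p

  # preallocated event buffers (generously sized, truncated at the end)
  cap <- 16L * n_st + 64L
  tele_t <- numeric(cap); tele_wp <- character(cap); n_tel <- 0L
  act_t <- numeric(cap); act_type <- character(cap)
  act_obj <- character(cap); act_wp <- character(cap); n_act <- 0L
  clock_t0 <- numeric(n_st); n_ck0 <- 0L
  comp <- rep(NA_real_, n_st)

  push_tel <- function(tt, ww) {
    k <- n_tel + seq_along(tt)
    tele_t[k] <<- tt
    tele_wp[k] <<- ww
    n_tel <<- n_tel + length(tt)
  }
  push_act <- function(tt, ty, ob, wp) {
    n_act <<- n_act + 1L
    act_t[n_act] <<- tt; act_type[n_act] <<- ty
    act_obj[n_act] <<- ob; act_wp[n_act] <<- wp
  }
  emit_hops <- function(from, to, t_start, dt) {
    path <- rt$paths[[from]][[to]]
    t <- t_start
    if (length(path) > 1L) {
      for (w in path[-1L]) {
        if (traits$nav_noise_p > 0 && stats::runif(1) < traits$nav_noise_p) {
          cur <- if (n_tel > 0L) tele_wp[n_tel] else from
          t <- t + dt
          push_tel(t, sample(rt$nbrs[[cur]], 1L))
        }
        t <- t + dt
        push_tel(t, w)
      }
    }
    t
  }

  # --- any-time subtasks, in instruction order, sequential agenda ----------
  cur <- spec$floorplan$entry_waypoint
  t <- 0.8
  dt_tp <- model$teleport_latency_s
  for (si in seq_len(n_st)) {
    st <- scenario$subtasks[[si]]
    if (st$kind != "anytime" || !encoded[si]) next
    for (step in st$steps) {
      ow <- rt$obj_wp[match(step$object_id, rt$obj_ids)]
      t <- emit_hops(cur, ow, t, dt_tp)
      cur <- ow
      t <- t + traits$action_latency_s
      if (step$action == "interact") {
        is_drum <- step$object_id %in% rt$drum_objs
        push_act(t, if (is_drum) "drum_hit" else "click_object",
                 step$object_id, NA_character_)
      } else { # transport: pickup, carry to destination, drop
        push_act(t, "pickup", step$object_id, NA_character_)
        t <- emit_hops(cur, step$destination_id, t, dt_tp)
        cur <- step$destination_id
        t <- t + traits$action_latency_s
        push_act(t, "drop", step$object_id, cur)
      }
    }
    comp[si] <- t
  }

  # --- time-based subtasks: executed at target + Gaussian timing error -----
  for (si in seq_len(n_st)) {
    st <- scenario$subtasks[[si]]
    if (st$kind != "time_based" || !encoded[si]) next
    texec <- clip(st$target_time_s + stats::rnorm(1, 0, traits$timing_sd_s),
                  1, lim - 1)
    n_ck0 <- n_ck0 + 1L
    clock_t0[n_ck0] <- texec - 0.25 # the gating glance at the watch
    ow <- rt$obj_wp[match(st$steps[[1L]]$object_id, rt$obj_ids)]
    path <- rt$paths[[cur]][[ow]]
    nh <- length(path) - 1L
    if (nh > 0L) push_tel(texec - 0.05 * (nh:1) - 0.05, path[-1L])
    for (k in rev(seq_along(st$steps))) {
      # steps end exactly at texec; earlier steps shortly before
      step <- st$steps[[k]]
      push_act(texec - 0.2 * (length(st$steps) - k), "click_object",
               step$object_id, NA_character_)
    }
    cur <- ow
    comp[si] <- texec
  }

  # --- event-based subtasks: cue onset, probabilistic in-window response ---
  cue_t <- numeric(); cue_id <- character()
  for (si in seq_len(n_st)) {
    st <- scenario$subtasks[[si]]
    if (st$kind != "event_based") next
    cue_t <- c(cue_t, st$cue_time_s); cue_id <- c(cue_id, st$cue_id)
    if (!encoded[si] || stats::runif(1) >= traits$cue_response_p) next
    tc <- st$cue_time_s + 0.5 +
      rtexp(1, model$eb_latency_mean_s, spec$ebpm_window_s - 1)
    ow <- rt$obj_wp[match(st$steps[[1L]]$object_id, rt$obj_ids)]
    path <- rt$paths[[cur]][[ow]]
    nh <- length(path) - 1L
    if (nh > 0L) push_tel(tc - 0.05 * (nh:1) - 0.05, path[-1L])
    push_act(tc, "click_object", st$steps[[1L]]$object_id, NA_character_)
    cur <- ow
    comp[si] <- tc
  }
  tele_t <- tele_t[seq_len(n_tel)]; tele_wp <- tele_wp[seq_len(n_tel)]
  act_t <- act_t[seq_len(n_act)]; act_type <- act_type[seq_len(n_act)]
  act_obj <- act_obj[seq_len(n_act)]; act_wp <- act_wp[seq_len(n_act)]
  clock_t <- clock_t0[seq_len(n_ck0)]

  # --- truncate at the time limit and determine the scenario end ----------
  comp[!is.na(comp) & comp > lim] <- NA_real_
  end <- if (!anyNA(comp) && n_st > 0L) max(comp) else lim

  keep_a <- act_t <= lim
  act_t <- act_t[keep_a]; act_type <- act_type[keep_a]
  act_obj <- act_obj[keep_a]; act_wp <- act_wp[keep_a]
  keep_t <- tele_t <= lim
  tele_t <- tele_t[keep_t]; tele_wp <- tele_wp[keep_t]

  # --- background streams on [0, end] --------------------------------------
  lambda <- traits$impulsivity_rate *
    (if (distractors_on) model$distractor_multiplier else 1)
  n_irr <- stats::rpois(1, lambda * end)
  irr_t <- sort(stats::runif(n_irr, 0, end))
  irr_obj <- sample(rt$irrelevant_objs, n_irr, replace = TRUE)

  n_clk <- stats::rpois(1, traits$monitor_rate / 60 * end)
  clock_t <- c(clock_t, stats::runif(n_clk, 0, end))
  clock_t <- clock_t[clock_t >= 0 & clock_t <= end]

  hz <- model$orientation_hz
  ori_t <- seq(0, end, by = 1 / hz)
  n_ori <- length(ori_t)
  step_deg <- rep(traits$motor_level / hz, n_ori)
  step_deg[1L] <- 0
  all_act_t <- c(act_t, irr_t)
  if (length(all_act_t) && n_ori > 1L) {
    at <- pmin(pmax(round(all_act_t * hz) + 1L, 2L), n_ori)
    burst <- tabulate(at, nbins = n_ori) * traits$motor_burst_deg
    step_deg <- step_deg + burst
  }
  theta <- cumsum(step_deg) # degrees, rotation about a fixed axis
  half <- theta * pi / 360
  q <- cbind(cos(half), 0, 0, sin(half))

  # --- instruction phase ----------------------------------------------------
  n_ins <- stats::rpois(1, traits$impulsivity_rate *
                          model$instruction_click_rate_frac * D)
  ins_t <- sort(stats::runif(n_ins, 0, D))
  ins_obj <- sample(rt$irrelevant_objs, n_ins, replace = TRUE)

  # --- assemble, shift to scenario clock, sort ------------------------------
  nE <- function(n, v = NA_character_) rep(v, n)
  t_all <- c(0, ins_t, D,
             D + tele_t, D + act_t, D + irr_t, D + clock_t, D + cue_t,
             D + ori_t, D + end)
  type_all <- c("scenario_start", nE(n_ins, "click_object"), "instruction_end",
                nE(length(tele_t), "click_waypoint"), act_type,
                nE(length(irr_t), "click_object"),
                nE(length(clock_t), "clock_check"),
                nE(length(cue_t), "cue_onset"),
                nE(n_ori, "orientation_sample"), "scenario_end")
  phase_all <- c("instruction", nE(n_ins, "instruction"), "instruction",
                 nE(length(t_all) - n_ins - 3L, "execution"), "execution")
  obj_all <- c(NA, ins_obj, NA, nE(length(tele_t)), act_obj,
               irr_obj, nE(length(clock_t)), nE(length(cue_t)),
               nE(n_ori), NA)
  wp_all <- c(NA, nE(n_ins), NA, tele_wp, act_wp, nE(length(irr_t)),
              nE(length(clock_t)), nE(length(cue_t)), nE(n_ori), NA)
  cue_all <- c(NA, nE(n_ins), NA, nE(length(tele_t)), nE(length(act_t)),
               nE(length(irr_t)), nE(length(clock_t)), cue_id, nE(n_ori), NA)
  qw <- c(rep(NA_real_, n_ins + 2L),
          rep(NA_real_, length(tele_t) + length(act_t) + length(irr_t) +
                length(clock_t) + length(cue_t)),
          q[, 1L], NA_real_)
  qx <- c(rep(NA_real_, length(qw) - n_ori - 1L), q[, 2L], NA_real_)
  qy <- c(rep(NA_real_, length(qw) - n_ori - 1L), q[, 3L], NA_real_)
  qz <- c(rep(NA_real_, length(qw) - n_ori - 1L), q[, 4L], NA_real_)

  prio <- c(0, rep(1, n_ins), 2, rep(3, length(t_all) - n_ins - 3L), 9)
  o <- order(t_all, prio)
  fast_df(list(t_s = t_all[o], phase = phase_all[o], type = type_all[o],
               object_id = obj_all[o], waypoint_id = wp_all[o],
               cue_id = cue_all[o], qw = qw[o], qx = qx[o], qy = qy[o],
               qz = qz[o], position_waypoint = nE(length(o))))
}

#' Simulate a full gameplay session for one agent
#'
#' Generates the 13 scenario logs in the participant's counterbalanced play
#' order. Encoded any-time subtasks are executed in instruction order via
#' shortest-path teleports (corrupted by `nav_noise_p` detours); encoded
#' time-based subtasks are executed at their target time plus Gaussian error
#' preceded by a clock check; encoded event-based subtasks are answered after
#' the cue with probability `cue_response_p` and a truncated-exponential
#' latency; irrelevant clicks form a Poisson stream at `impulsivity_rate`,
#' boosted by the distractor multiplier when the scenario carries
#' distractors; controller orientation integrates `motor_level` with
#' per-action bursts at the configured sampling rate; the scenario truncates
#' at the 90 s limit.
#'
#' @param traits An `epeli_traits`.
#' @param spec An `epeli_task_spec`.
#' @param assignment An `epeli_assignment`.
#' @param seed Integer seed; identical inputs give a bit-identical session.
#' @param model An `epeli_population_model` (supplies simulator timing
#'   constants and the distractor multiplier).
#' @param participant_id Participant identifier stored in the log.
#' @param covariates Optional named list stored in the session header.
#' @return An `epeli_session_log`.
#' @export
simulate_session <- function(traits, spec, assignment, seed,
                             model = default_population_model(),
                             participant_id = sprintf("p%03d", assignment$participant_index),
                             covariates = list()) {
  rt <- route_table(spec)
  logs <- vector("list", length(assignment$scenario_order))
  for (k in seq_along(assignment$scenario_order)) {
    sid <- assignment$scenario_order[k]
    scenario <- find_scenario(spec, sid)
    d_on <- sid %in% assignment$distractor_scenarios
    ev <- with_seed(derive_seed(seed, k),
                    simulate_scenario_events(traits, scenario, spec, d_on,
                                             model, rt))
    logs[[k]] <- scenario_log(sid, d_on, ev)
  }
  session_log(participant_id, assignment, logs, covariates)
}

#' Simulate the instruction-recall covariate task
#'
#' A verbal task in which the participant repeats instruction lists like the
#' ones used in the scenarios; modeled as a binomial draw whose success
#' probability increases with the encoding trait, so the score correlates
#' positively with the simulated total score across a cohort.
#'
#' @param traits An `epeli_traits`.
#' @param seed Integer seed.
#' @param model An `epeli_population_model`.
#' @return Integer score in `[0, items]`.
#' @export
simulate_recall_score <- function(traits, seed,
                                  model = default_population_model()) {
  rc <- model$recall
  p <- clip(rc$intercept + rc$slope * traits$encode_p, 0, 1)
  with_seed(seed, stats::rbinom(1L, rc$items, p))
}

#' Simulate parent-rating scalars (executive-function problem scales)
#'
#' The behavioral-regulation analog (BRI) increases with the impulsivity
#' trait; the metacognition analog (MI) decreases with the encoding trait;
#' the global composite (GEC) is their sum. Gaussian noise is added and the
#' results are clipped to the configured ranges.
#'
#' @param traits An `epeli_traits`.
#' @param seed Integer seed.
#' @param model An `epeli_population_model`.
#' @return Named numeric vector `c(gec, bri, mi)`.
#' @export
simulate_ratings <- function(traits, seed, model = default_population_model()) {
  rr <- model$ratings
  with_seed(seed, {
    bri <- clip(rr$bri$intercept + rr$bri$b_impulsivity * traits$impulsivity_rate +
                  stats::rnorm(1, 0, rr$bri$sd), rr$bri$range[1L], rr$bri$range[2L])
    mi <- clip(rr$mi$intercept + rr$mi$b_encode * traits$encode_p +
                 stats::rnorm(1, 0, rr$mi$sd), rr$mi$range[1L], rr$mi$range[2L])
    gec <- clip(bri + mi, rr$gec_range[1L], rr$gec_range[2L])
    c(gec = gec, bri = bri, mi = mi)
  })
}

#' Simulate a cohort and keep the full session logs
#'
#' @param model An `epeli_population_model`.
#' @param n Cohort size.
#' @param seed Master seed; per-participant and per-scenario child seeds are
#'   derived deterministically from it.
#' @param spec An `epeli_task_spec`.
#' @return List with `sessions` (list of `epeli_session_log`), `covariates`
#'   (including `recall_score`, `gec`, `bri`, `mi`) and `traits`.
#' @export
simulate_cohort <- function(model, n, seed, spec = default_task_spec()) {
  coh <- sample_participants(model, n, derive_seed(seed, 0L))
  cv <- coh$covariates
  sessions <- vector("list", n)
  recall <- integer(n)
  gec <- numeric(n); bri <- numeric(n); mi <- numeric(n)
  for (i in seq_len(n)) {
    tr <- traits_from_row(coh$traits, i)
    asg <- assign_condition(cv$participant_index[i], spec)
    sessions[[i]] <- simulate_session(tr, spec, asg, derive_seed(seed, i, 1L),
                                      model, participant_id = cv$participant_id[i])
    recall[i] <- simulate_recall_score(tr, derive_seed(seed, i, 2L), model)
    r <- simulate_ratings(tr, derive_seed(seed, i, 3L), model)
    gec[i] <- r[["gec"]]; bri[i] <- r[["bri"]]; mi[i] <- r[["mi"]]
  }
  cv$recall_score <- recall
  cv$gec <- gec; cv$bri <- bri; cv$mi <- mi
  list(sessions = sessions, covariates = cv, traits = coh$traits)
}

#' Simulate a cohort and score it in one pass
#'
#' Memory-friendly variant of [simulate_cohort()]: each session is scored
#' with [aggregate_session()] immediately and its raw log discarded. This is
#' the workhorse behind replication studies.
#'
#' @inheritParams simulate_cohort
#' @param efficacy_aggregate Passed to [aggregate_session()].
#' @return List with `session_scores` (one row per participant, eight
#'   measures), `scenario_scores` (participant x scenario rows), `covariates`
#'   and `traits`.
#' @export
simulate_and_score_cohort <- function(model, n, seed, spec = default_task_spec(),
                                      efficacy_aggregate = "ratio_of_sums") {
  coh <- sample_participants(model, n, derive_seed(seed, 0L))
  cv <- coh$covariates
  sess_rows <- vector("list", n)
  scen_rows <- vector("list", n)
  recall <- integer(n)
  gec <- numeric(n); bri <- numeric(n); mi <- numeric(n)
  for (i in seq_len(n)) {
    tr <- traits_from_row(coh$traits, i)
    asg <- assign_condition(cv$participant_index[i], spec)
    sess <- simulate_session(tr, spec, asg, derive_seed(seed, i, 1L), model,
                             participant_id = cv$participant_id[i])
    sc <- aggregate_session(sess, spec, efficacy_aggregate)
    sess_rows[[i]] <- sc$session
    scen_i <- sc$scenario
    scen_i$participant_id <- rep(cv$participant_id[i], nrow(scen_i))
    scen_rows[[i]] <- scen_i
    recall[i] <- simulate_recall_score(tr, derive_seed(seed, i, 2L), model)
    r <- simulate_ratings(tr, derive_seed(seed, i, 3L), model)
    gec[i] <- r[["gec"]]; bri[i] <- r[["bri"]]; mi[i] <- r[["mi"]]
  }
  cv$recall_score <- recall
  cv$gec <- gec; cv$bri <- bri; cv$mi <- mi
  list(session_scores = do.call(rbind, sess_rows),
       scenario_scores = do.call(rbind, scen_rows),
       covariates = cv, traits = coh$traits)
}
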