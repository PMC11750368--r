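#' Scenario configuration
#'
#' Bundles world, gait, controller and budget settings for one experiment.
#' Every scenario is fully deterministic given its seed. Scenario-specific
#' defaults (documented in the package vignette) can be overridden through
#' `...`; unknown fields are an error.
#'
#' @param scenario one of `"path_integration"`, `"visual_beacon"`,
#'   `"visual_compass"`, `"trail_following"`, `"plume_tracking"`,
#'   `"locomotion_demo"`.
#' @param seed integer RNG seed (mandatory).
#' @param ... scenario field overrides.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("path_integration", "visual_beacon",
                                         "visual_compass", "trail_following",
                                         "plume_tracking", "locomotion_demo"),
                            seed, ...) {
  scenario <- match.arg(scenario)
  if (missing(seed) || !is.finite(seed)) {
    stop("scenario_config: seed is mandatory", call. = FALSE)
  }
  common <- list(Sn = 5, Sh = 15, gait_type = "tripod", goal_radius = 4,
                 out_dir = NULL)
  defaults <- switch(scenario,
    path_integration = list(n_outbound = 60, turn_noise = 0.15,
                            outbound_Sl = 15, kPI = 10, cx_gain = 0.0025,
                            cx_k_speed = 0.5, cycles = 200),
    visual_beacon = list(mode = "binocular", beacon = list(), threshold = 18,
                         kvb = 0.25, init_theta = NULL, cycles = 120),
    visual_compass = list(n_landmarks = 7, world_seed = 11,
                          rotation_mode = "incremental", rotation_rate = 1,
                          jump_angle = 90, jump_cycle = 10, cycles = 120,
                          settle_cycles = 40),
    trail_following = list(width = 2, curvature = 0.4, trail_length = 14,
                           trail_seed = NULL, antenna_mode = "moving",
                           sweep_amplitude = 30, sweep_period = 20,
                           cycles = 80, goal_radius = 2.5),
    plume_tracking = list(plume = list(), plume_burn_in = 800,
                          start = c(25, 1), start_heading = pi,
                          decisions = 100, goal_radius = 3),
    locomotion_demo = list(Sl = 15, theta = 0, n_cycles = 10))
  cfg <- utils::modifyList(utils::modifyList(common, defaults), list(...))
  extra <- setdiff(names(list(...)), c(names(common), names(defaults)))
  if (length(extra)) {
    stop("unknown scenario_config field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  cfg$scenario <- scenario
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "scenario_config")
}

clip_theta <- function(theta) max(-1, min(1, theta))

# run one full gait cycle from tick0; on_tick(pose, tick) is called after
# every tick (used for within-cycle sensor sampling)
run_gait_cycle <- function(model, sched, params, pose, carry, tick0,
                           on_tick = NULL) {
  for (t in seq_len(sched$cycle_len)) {
    step <- embodied_tick(model, sched, tick0 + t - 1L, params, "FK",
                          pose, carry)
    pose <- step$pose
    carry <- step$carry
    if (!is.null(on_tick)) on_tick(pose, tick0 + t - 1L)
  }
  list(pose = pose, carry = carry, tick = tick0 + sched$cycle_len)
}

new_scenario_result <- function(log, metrics, config) {
  structure(list(log = log, metrics = metrics, config = config),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>", x$config$scenario, "seed", x$config$seed, "\n")
  str(x$metrics, give.head = FALSE)
  invisible(x)
}

#' Run a navigation scenario
#'
#' Wires the closed sensorimotor loop — sense, controller, (theta, Sl) gait
#' commands, gait stepping, leg forward kinematics, stance odometry — for
#' the configured experiment and logs the trajectory once per gait cycle.
#' If `out_dir` is set, writes `trajectory.csv` and `metrics.json` there.
#'
#' @param config a [scenario_config()].
#' @return a `scenario_result` with `log` (per-cycle tibble), `metrics`
#'   (named list) and `config`.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  res <- switch(config$scenario,
    path_integration = scenario_path_integration(config),
    visual_beacon = scenario_visual_beacon(config),
    visual_compass = scenario_visual_compass(config),
    trail_following = scenario_trail_following(config),
    plume_tracking = scenario_plume_tracking(config),
    locomotion_demo = scenario_locomotion_demo(config))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$log, file.path(config$out_dir, "trajectory.csv"),
                     row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(res$metrics,
                           file.path(config$out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  res
}

scenario_locomotion_demo <- function(cfg) {
  model <- build_ant_model()
  log <- run_locomotion(model, fk_gait_params(Sl = cfg$Sl, Sh = cfg$Sh,
                                              theta = cfg$theta, Sn = cfg$Sn),
                        n_cycles = cfg$n_cycles, gait_type = cfg$gait_type)
  s <- attr(log, "summary")
  new_scenario_result(log, list(mean_speed = s$mean_speed,
                                net_turn_per_cycle =
                                  s$net_heading_change_per_cycle), cfg)
}

scenario_path_integration <- function(cfg) {
  model <- build_ant_model()
  sched <- make_gait_schedule(cfg$gait_type, cfg$Sn)
  route <- make_foraging_route(cfg$n_outbound, cfg$turn_noise, cfg$seed)
  pose <- body_pose(0, 0, attr(route, "h0"))
  cx <- cx_state(gain = cfg$cx_gain, k_speed = cfg$cx_k_speed, kPI = cfg$kPI)
  carry <- NULL; tick <- 0L
  rows <- list(); prev_xy <- c(pose$x, pose$y)
  run_one <- function(theta, Sl) {
    params <- fk_gait_params(Sl = Sl, Sh = cfg$Sh, theta = theta,
                             Sn = cfg$Sn)
    out <- run_gait_cycle(model, sched, params, pose, carry, tick)
    pose <<- out$pose; carry <<- out$carry; tick <<- out$tick
  }
  for (i in seq_len(cfg$n_outbound)) {
    th <- route$theta_cmd[i]
    run_one(th, cfg$outbound_Sl)
    v <- sqrt(sum((c(pose$x, pose$y) - prev_xy)^2)); prev_xy <- c(pose$x, pose$y)
    cx_out <- cx_pi_step(cx, pose$h, v)
    cx <- cx_out$state
    rows[[length(rows) + 1]] <- c(i, tick, pose$x, pose$y, pose$h, th,
                                  cfg$outbound_Sl, 0)
  }
  turn_xy <- c(pose$x, pose$y)
  decoded_at_turn <- decode_home_vector(cx)
  min_dist <- sqrt(sum(turn_xy^2))
  homing_cycles <- 0L
  budget <- if (min_dist <= cfg$goal_radius) 0L else cfg$cycles
  for (i in seq_len(budget)) {
    cx_out <- cx_pi_step(cx, pose$h,
                         sqrt(sum((c(pose$x, pose$y) - prev_xy)^2)))
    cx <- cx_out$state
    th <- clip_theta(cx_out$theta)
    prev_xy <- c(pose$x, pose$y)
    run_one(th, cx_out$Sl)
    d <- sqrt(pose$x^2 + pose$y^2)
    min_dist <- min(min_dist, d)
    homing_cycles <- i
    rows[[length(rows) + 1]] <- c(cfg$n_outbound + i, tick, pose$x, pose$y,
                                  pose$h, th, cx_out$Sl, 1)
    if (d <= cfg$goal_radius) break
  }
  log <- as_cycle_log(rows, c("cycle", "tick", "x", "y", "h", "theta_cmd",
                              "sl_cmd", "homing"))
  out_pts <- log[log$homing == 0, c("x", "y")]
  route_len <- sum(sqrt(diff(c(0, out_pts$x))^2 + diff(c(0, out_pts$y))^2))
  true_home_bearing <- atan2(-turn_xy[2], -turn_xy[1])
  metrics <- list(
    route_length = route_len,
    turn_point_distance = sqrt(sum(turn_xy^2)),
    decoded_bearing = decoded_at_turn$bearing,
    true_home_bearing = true_home_bearing,
    bearing_error_deg = abs(rad2deg(wrap_angle(
      decoded_at_turn$bearing - true_home_bearing))),
    min_homing_distance = min_dist,
    final_distance = sqrt(pose$x^2 + pose$y^2),
    homing_cycles = homing_cycles,
    success = min_dist <= 0.1 * route_len)
  new_scenario_result(log, metrics, cfg)
}

as_cycle_log <- function(rows, names) {
  m <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0, length(names))
  colnames(m) <- names
  tibble::as_tibble(as.data.frame(m))
}

scenario_visual_beacon <- function(cfg) {
  model <- build_ant_model()
  sched <- make_gait_schedule(cfg$gait_type, cfg$Sn)
  world <- make_landmark_world(list(beacon = cfg$beacon), cfg$seed)
  beacon <- attr(world, "beacon")
  h0 <- switch(cfg$mode,
               left = stats::runif(1, 0, pi / 2),
               right = stats::runif(1, pi / 2, pi),
               binocular = stats::runif(1, pi / 4, 3 * pi / 4))
  pose <- body_pose(0, 0, h0)
  # until first detection the agent turns in a random direction; any fixed
  # choice would bias the mono modes differently
  theta <- cfg$init_theta %||% (0.5 * sample(c(-1, 1), 1))
  carry <- NULL; tick <- 0L
  rows <- list()
  reach <- cfg$goal_radius + (cfg$beacon$radius %||% 1.5)
  success <- FALSE; cycles_to_goal <- NA_integer_
  for (i in seq_len(cfg$cycles)) {
    need_left <- cfg$mode %in% c("left", "binocular")
    need_right <- cfg$mode %in% c("right", "binocular")
    mask_l <- if (need_left) {
      binarize_image(render_binocular(world, pose, "left", model),
                     cfg$threshold)
    } else NULL
    mask_r <- if (need_right) {
      binarize_image(render_binocular(world, pose, "right", model),
                     cfg$threshold)
    } else NULL
    bd <- beacon_desired_shift(mask_l, mask_r, cfg$mode)
    if (bd$detected) {
      cur <- heading_encoding(pose$h)
      des <- shift_encoding(cur, bd$sign * bd$shift)
      theta <- steering_from_desired(cur, des, cfg$kvb)
    }
    th <- clip_theta(theta)
    Sl <- speed_modulation(th)
    params <- fk_gait_params(Sl = Sl, Sh = cfg$Sh, theta = th, Sn = cfg$Sn)
    out <- run_gait_cycle(model, sched, params, pose, carry, tick)
    pose <- out$pose; carry <- out$carry; tick <- out$tick
    d <- sqrt((pose$x - beacon[1])^2 + (pose$y - beacon[2])^2)
    rows[[length(rows) + 1]] <- c(i, tick, pose$x, pose$y, pose$h, th, Sl,
                                  as.integer(bd$detected), d)
    if (d <= reach) { success <- TRUE; cycles_to_goal <- i; break }
  }
  log <- as_cycle_log(rows, c("cycle", "tick", "x", "y", "h", "theta_cmd",
                              "sl_cmd", "detected", "dist_to_beacon"))
  # signed lateral offset w.r.t. the start->beacon axis (left positive)
  axis <- beacon / sqrt(sum(beacon^2))
  lat <- -axis[2] * log$x + axis[1] * log$y
  approach <- log$dist_to_beacon <= 12
  metrics <- list(success = success, cycles_to_goal = cycles_to_goal,
                  initial_heading = h0,
                  final_distance = log$dist_to_beacon[nrow(log)],
                  mean_lateral_offset = if (any(approach))
                    mean(lat[approach]) else NA_real_)
  new_scenario_result(log, metrics, cfg)
}

scenario_visual_compass <- function(cfg) {
  model <- build_ant_model()
  sched <- make_gait_schedule(cfg$gait_type, cfg$Sn)
  world <- make_landmark_world(list(n_distractors = cfg$n_landmarks,
                                    beacon = list(distance = 20)),
                               cfg$world_seed)
  h0 <- stats::runif(1, -pi, pi)
  pose <- body_pose(0, 0, h0)
  mem <- compass_memory(render_panorama(world, pose))
  carry <- NULL; tick <- 0L
  rows <- list()
  for (i in seq_len(cfg$cycles)) {
    rot <- if (cfg$rotation_mode == "incremental") {
      deg2rad(cfg$rotation_rate) * i
    } else {
      if (i >= cfg$jump_cycle) deg2rad(cfg$jump_angle) else 0
    }
    world$rotation <- rot
    out_c <- visual_compass_step(render_panorama(world, pose), mem)
    mem <- out_c$memory
    Sl_deg <- min(rad2deg(out_c$Sl), 25)
    params <- fk_gait_params(Sl = Sl_deg, Sh = cfg$Sh,
                             theta = clip_theta(out_c$theta), Sn = cfg$Sn)
    out <- run_gait_cycle(model, sched, params, pose, carry, tick)
    pose <- out$pose; carry <- out$carry; tick <- out$tick
    err <- wrap_angle(pose$h - (h0 + rot))
    rows[[length(rows) + 1]] <- c(i, tick, pose$x, pose$y, pose$h,
                                  out_c$theta, Sl_deg, rot, err)
  }
  log <- as_cycle_log(rows, c("cycle", "tick", "x", "y", "h", "theta_cmd",
                              "sl_cmd", "world_rotation", "heading_error"))
  settled <- log$cycle > cfg$settle_cycles
  metrics <- list(
    max_abs_error_deg = max(abs(rad2deg(log$heading_error))),
    settled_max_abs_error_deg = if (any(settled))
      max(abs(rad2deg(log$heading_error[settled]))) else NA_real_,
    final_error_deg = rad2deg(log$heading_error[nrow(log)]))
  new_scenario_result(log, metrics, cfg)
}

scenario_trail_following <- function(cfg) {
  model <- build_ant_model()
  sched <- make_gait_schedule(cfg$gait_type, cfg$Sn)
  trail <- make_trail_map(width = cfg$width, curvature = cfg$curvature,
                          length = cfg$trail_length,
                          seed = cfg$trail_seed %||% cfg$seed)
  set.seed(cfg$seed)   # agent RNG (trail generation used its own seed)
  ant <- antenna_state(cfg$antenna_mode, cfg$sweep_amplitude,
                       cfg$sweep_period)
  pose <- body_pose(5, 0, pi)
  goal <- trail$goal
  carry <- NULL; tick <- 0L
  rows <- list()
  success <- FALSE; cycles_to_goal <- NA_integer_
  # within-cycle sensing: the antennae sweep while the body advances, so
  # each side's reading is the maximum over samples taken during the cycle
  sense_env <- new.env()
  sensor <- function(pose_t, tick_t) {
    if (tick_t %% 2L == 0L) {
      tips <- antenna_tips_world(model, pose_t, ant, tick_t)
      sense_env$Ol <- max(sense_env$Ol, trail_sensor_read(trail, tips$AL))
      sense_env$Or <- max(sense_env$Or, trail_sensor_read(trail, tips$AR))
    }
  }
  Ol <- 0; Or <- 0
  tips0 <- antenna_tips_world(model, pose, ant, 0L)
  Ol <- trail_sensor_read(trail, tips0$AL)
  Or <- trail_sensor_read(trail, tips0$AR)
  for (i in seq_len(cfg$cycles)) {
    cmd <- trail_follow_step(Ol, Or)
    th <- clip_theta(cmd$theta)
    params <- fk_gait_params(Sl = cmd$Sl, Sh = cfg$Sh, theta = th,
                             Sn = cfg$Sn)
    sense_env$Ol <- 0; sense_env$Or <- 0
    out <- run_gait_cycle(model, sched, params, pose, carry, tick,
                          on_tick = sensor)
    pose <- out$pose; carry <- out$carry; tick <- out$tick
    Ol <- sense_env$Ol; Or <- sense_env$Or
    d <- sqrt((pose$x - goal[1])^2 + (pose$y - goal[2])^2)
    rows[[length(rows) + 1]] <- c(i, tick, pose$x, pose$y, pose$h, th,
                                  cmd$Sl, Ol, Or, d)
    if (d <= cfg$goal_radius) { success <- TRUE; cycles_to_goal <- i; break }
  }
  log <- as_cycle_log(rows, c("cycle", "tick", "x", "y", "h", "theta_cmd",
                              "sl_cmd", "Ol", "Or", "dist_to_goal"))
  metrics <- list(success = success, cycles_to_goal = cycles_to_goal,
                  final_distance = log$dist_to_goal[nrow(log)],
                  frac_cycles_sensing = mean(pmax(log$Ol, log$Or) >= 900))
  new_scenario_result(log, metrics, cfg)
}

scenario_plume_tracking <- function(cfg) {
  model <- build_ant_model()
  sched <- make_gait_schedule(cfg$gait_type, cfg$Sn)
  pp <- do.call(plume_params, cfg$plume)
  plume <- plume_init(pp, cfg$seed + 1000L)
  burn_steps <- ceiling(cfg$plume_burn_in / sched$cycle_len)
  for (i in seq_len(burn_steps)) plume <- plume_step(plume, sched$cycle_len)
  ant <- antenna_state("fixed")
  tracker <- plume_tracker_state()
  pose <- body_pose(cfg$start[1], cfg$start[2], cfg$start_heading)
  src <- pp$source[1:2]
  carry <- NULL; tick <- 0L
  rows <- list()
  success <- FALSE; decisions_to_goal <- NA_integer_
  min_d <- sqrt(sum((cfg$start - src)^2))
  run_cycle_cmd <- function(theta, Sl) {
    params <- fk_gait_params(Sl = Sl, Sh = cfg$Sh, theta = theta, Sn = cfg$Sn)
    out <- run_gait_cycle(model, sched, params, pose, carry, tick)
    pose <<- out$pose; carry <<- out$carry; tick <<- out$tick
    plume <<- plume_step(plume, sched$cycle_len)
    min_d <<- min(min_d, sqrt((pose$x - src[1])^2 + (pose$y - src[2])^2))
  }
  for (i in seq_len(cfg$decisions)) {
    tips <- antenna_tips_world(model, pose, ant, tick)
    Ol <- concentration_at(plume, tips$AL)
    Or <- concentration_at(plume, tips$AR)
    Wl <- wind_at(plume, tips$AL)
    Wr <- wind_at(plume, tips$AR)
    cmd <- plume_track_step(tracker, Ol, Or, Wl, Wr, pose$h)
    tracker <- cmd$state
    run_cycle_cmd(clip_theta(cmd$theta), cmd$Sl)
    d <- sqrt((pose$x - src[1])^2 + (pose$y - src[2])^2)
    rows[[length(rows) + 1]] <- c(i, tick, pose$x, pose$y, pose$h,
                                  cmd$theta, cmd$Sl, Ol, Or, d,
                                  cmd$surge_loops)
    if (d <= cfg$goal_radius) { success <- TRUE; decisions_to_goal <- i }
    if (success) break
    if (cmd$surge_loops > 0) {
      for (s in seq_len(cmd$surge_loops)) {
        run_cycle_cmd(0, 15)
        d <- sqrt((pose$x - src[1])^2 + (pose$y - src[2])^2)
        if (d <= cfg$goal_radius) { success <- TRUE; decisions_to_goal <- i }
        if (success) break
      }
    }
    if (success) break
  }
  log <- as_cycle_log(rows, c("decision", "tick", "x", "y", "h", "theta_cmd",
                              "sl_cmd", "Ol", "Or", "dist_to_source",
                              "surge_loops"))
  metrics <- list(success = success, decisions_to_goal = decisions_to_goal,
                  final_distance = sqrt((pose$x - src[1])^2 +
                                          (pose$y - src[2])^2),
                  min_distance = min_d,
                  frac_decisions_sensing =
                    mean(pmax(log$Ol, log$Or) > tracker$Top))
  new_scenario_result(log, metrics, cfg)
}

#' One-row summary of a scenario result
#'
#' @param x a `scenario_result`.
#' @param ... unused.
#' @return a one-row tibble of the scalar metrics plus scenario and seed.
#' @export
glance.scenario_result <- function(x, ...) {
  m <- x$metrics[vapply(x$metrics, function(v) length(v) == 1, logical(1))]
  tibble::as_tibble(c(list(scenario = x$config$scenario,
                           seed = x$config$seed), m))
}

#' @export
glance <- function(x, ...) UseMethod("glance")
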