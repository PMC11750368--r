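#' Gait parameter sets
#'
#' `fk_gait_params()` parameterises the forward-kinematic gait: joint angles
#' are generated directly from the hip swing `Sl` (protraction amplitude,
#' degrees), lift swing `Sh` (degrees), moving direction `d` (+1 forward,
#' -1 backward), rotation configuration `theta` (dimensionless steering
#' command, effective over [-1, 1]) and the half-swing step count `Sn`
#' (ticks to lift the leg to its highest point). `ik_gait_params()`
#' parameterises the inverse-kinematic gait by the Cartesian step length `L`
#' and step height `H` (model units); tip targets are converted to joint
#' angles by [leg_inverse_kinematics()].
#'
#' @param Sl hip swing amplitude, degrees (>= 0).
#' @param Sh lift swing amplitude, degrees (>= 0).
#' @param d moving direction, -1 or +1.
#' @param theta rotation configuration; values outside [-1, 1] are clipped
#'   (with a warning) where the yaw-control table is evaluated.
#' @param Sn half-swing step count (ticks, >= 1).
#' @param alpha0,beta0,gamma0 initial (rest) angles of the ThCz, CTr and FTi
#'   joints in degrees; defaults are the default morphology's rest pose.
#' @return a parameter object of class `fk_gait_params` / `ik_gait_params`.
#' @export
fk_gait_params <- function(Sl = 15, Sh = 15, d = 1, theta = 0, Sn = 10,
                           alpha0 = 0, beta0 = 30, gamma0 = -75) {
  stopifnot(Sl >= 0, Sh >= 0, d %in% c(-1, 1), Sn >= 1)
  structure(list(Sl = Sl, Sh = Sh, d = d, theta = theta, Sn = as.integer(Sn),
                 alpha0 = alpha0, beta0 = beta0, gamma0 = gamma0),
            class = "fk_gait_params")
}

#' @rdname fk_gait_params
#' @param L step length, model units (>= 0).
#' @param H step height, model units (>= 0).
#' @export
ik_gait_params <- function(L = 0.6, H = 0.3, theta = 0, Sn = 10) {
  stopifnot(L >= 0, H >= 0, Sn >= 1)
  structure(list(L = L, H = H, theta = theta, Sn = as.integer(Sn)),
            class = "ik_gait_params")
}

#' ThCz joint range for yaw control
#'
#' The steering command theta asymmetrises the left/right stride amplitude:
#' for theta >= 0, left legs get `R = Sl * d * (2 theta - 1)` while right
#' legs keep the full stride `R = Sl * d`; for theta < 0 the roles mirror
#' (left legs keep `R = -Sl * d`, right legs get `R = Sl * d * (2 theta +
#' 1)`), so that negating theta mirrors the gait left/right. At theta = 0
#' both sides stride forward (the opposite signs reflect the mirrored
#' right-handed leg-base frames: positive ThCz rotation protracts a right
#' leg but retracts a left leg); theta = +1/-1 spins the body in place
#' CCW/CW. theta outside [-1, 1] is clipped with a warning.
#'
#' @param theta rotation configuration.
#' @param side `"left"` or `"right"`.
#' @param d moving direction, -1 or +1.
#' @param Sl hip swing amplitude, degrees.
#' @return joint range R in degrees.
#' @export
thc_joint_range <- function(theta, side = c("left", "right"), d = 1, Sl = 15) {
  side <- match.arg(side)
  if (abs(theta) > 1) {
    warning("rotation configuration ", signif(theta, 4),
            " outside [-1, 1]; clipped", call. = FALSE)
    theta <- sign(theta)
  }
  if (theta >= 0) {
    if (side == "left") Sl * d * (2 * theta - 1) else Sl * d
  } else {
    if (side == "left") -Sl * d else Sl * d * (2 * theta + 1)
  }
}

#' Per-leg FK joint angles within one gait phase
#'
#' Evaluates the piecewise-linear swing/stance angle profiles. In the first
#' swing half the leg lifts while protracting from the rearmost position; in
#' the second half it lowers while reaching the frontmost position; in
#' stance the hip angle sweeps back while the lift joints hold the rest
#' pose. The profiles are continuous at every phase boundary and close the
#' cycle.
#'
#' @param phase `"swing1"`, `"swing2"` or `"stance"`.
#' @param k step index within the phase: 0..Sn for the swing halves,
#'   0..`stance_steps` for stance.
#' @param R ThCz joint range for this leg (degrees, from
#'   [thc_joint_range()]).
#' @param params an [fk_gait_params()] object.
#' @param stance_steps stance duration in ticks (default `2 * Sn`,
#'   the tripod value; ripple and wave use longer stances).
#' @return named numeric `c(alpha, beta, gamma)` in degrees.
#' @export
fk_leg_angles <- function(phase = c("swing1", "swing2", "stance"), k, R,
                          params, stance_steps = 2L * params$Sn) {
  phase <- match.arg(phase)
  Sn <- params$Sn
  kmax <- if (phase == "stance") stance_steps else Sn
  if (k < 0 || k > kmax) {
    stop(sprintf("step index k = %s out of range [0, %d] for phase %s",
                 format(k), kmax, phase), call. = FALSE)
  }
  a0 <- params$alpha0; b0 <- params$beta0; g0 <- params$gamma0
  Sh <- params$Sh
  switch(phase,
    swing1 = c(alpha = -R + a0 + R * k / Sn,
               beta  = b0 + Sh * k / Sn,
               gamma = g0 + Sh * k / Sn),
    swing2 = c(alpha = a0 + R * k / Sn,
               beta  = b0 + Sh - Sh * k / Sn,
               gamma = g0 + Sh - Sh * k / Sn),
    stance = c(alpha = a0 + R - 2 * R * k / stance_steps,
               beta  = b0,
               gamma = g0))
}

#' Per-leg IK tip-pose targets within one gait phase
#'
#' Returns the tip pose (Euler rotation triple, translation triple) relative
#' to the leg's rest tip. During swing the tip travels from the frontmost
#' position (`L/2`) backward over the step while descending by `H` (the
#' monotone-descent profile is literal; set `lift = TRUE` for a
#' lift-then-lower triangular profile); during stance it sweeps from the
#' rearmost to the frontmost position on the ground while the yaw rotation
#' accrues from 0 to theta.
#'
#' @param phase `"swing"` or `"stance"`.
#' @param k step index in 0..`stance_steps` (stance) or 0..Sn (swing).
#' @param params an [ik_gait_params()] object.
#' @param stance_steps stance duration in ticks (default `Sn`).
#' @param lift if TRUE, the swing z-profile lifts to `+H` mid-swing and
#'   returns to 0 instead of descending monotonically to `-H`.
#' @return list with elements `rotation` (radians, about x/y/z) and
#'   `translation` (model units).
#' @export
ik_leg_targets <- function(phase = c("swing", "stance"), k, params,
                           stance_steps = params$Sn, lift = FALSE) {
  phase <- match.arg(phase)
  Sn <- params$Sn
  kmax <- if (phase == "stance") stance_steps else Sn
  if (k < 0 || k > kmax) {
    stop(sprintf("step index k = %s out of range [0, %d] for phase %s",
                 format(k), kmax, phase), call. = FALSE)
  }
  L <- params$L; H <- params$H; th <- params$theta
  if (phase == "swing") {
    z <- if (lift) -H * (1 - abs(2 * k / Sn - 1)) * (-1) else -H * k / Sn
    list(rotation = c(0, 0, th - th * k / Sn),
         translation = c(L / 2 - L * k / Sn, 0, z))
  } else {
    list(rotation = c(0, 0, th * k / stance_steps),
         translation = c(-L / 2 + L * k / stance_steps, 0, 0))
  }
}

#' Gait coordination schedules
#'
#' Builds the per-leg phase schedule for the three hexapod coordination
#' patterns. With half-swing count `Sn`, every leg's swing lasts `2 Sn`
#' ticks; the stance is stretched so that the duty cycle matches the
#' pattern: tripod (two antiphase groups of three legs, cycle `4 Sn`,
#' exactly 3 legs in swing at all times), ripple (three antiphase pairs,
#' cycle `6 Sn`, exactly 2 legs swinging) and wave (one leg at a time in
#' back-to-front order, cycle `12 Sn`, exactly 1 leg swinging).
#'
#' @param gait_type `"tripod"`, `"ripple"` or `"wave"`.
#' @param Sn half-swing step count.
#' @return a `gait_schedule` object: tibble of per-leg tick offsets plus
#'   `cycle_len`, `stance_steps` and `Sn` attributes.
#' @export
make_gait_schedule <- function(gait_type = c("tripod", "ripple", "wave"),
                               Sn = 10) {
  gait_type <- match.arg(gait_type)
  Sn <- as.integer(Sn)
  sched <- switch(gait_type,
    tripod = tibble::tibble(
      leg = c("FR", "ML", "HL", "FL", "MR", "HR"),
      offset = c(0L, 0L, 0L, 2L * Sn, 2L * Sn, 2L * Sn)),
    ripple = tibble::tibble(
      leg = c("FL", "MR", "FR", "HL", "ML", "HR"),
      offset = rep(c(0L, 2L, 4L) * Sn, each = 2)),
    wave = tibble::tibble(
      leg = c("HL", "ML", "FL", "HR", "MR", "FR"),
      offset = c(0L, 2L, 4L, 6L, 8L, 10L) * Sn))
  cycle_len <- switch(gait_type, tripod = 4L, ripple = 6L, wave = 12L) * Sn
  structure(list(gait_type = gait_type, schedule = sched,
                 offsets = stats::setNames(sched$offset, sched$leg),
                 cycle_len = cycle_len, Sn = Sn,
                 stance_steps = cycle_len - 2L * Sn),
            class = "gait_schedule")
}

schedule_phase <- function(schedule, leg, tick) {
  Sn <- schedule$Sn
  local <- (tick - schedule$offsets[[leg]]) %% schedule$cycle_len
  if (local < Sn) {
    list(phase = "swing1", k = local)
  } else if (local < 2L * Sn) {
    list(phase = "swing2", k = local - Sn)
  } else {
    list(phase = "stance", k = local - 2L * Sn)
  }
}

# Fast internal per-tick evaluation: 6x3 angle matrix (rows in LEG_IDS
# order), stance flags and phase labels, without tibble allocation.
gait_angles_at <- function(model, sched, tick, params, mode) {
  ang <- matrix(0, 6, 3, dimnames = list(LEG_IDS, c("alpha", "beta", "gamma")))
  stance <- logical(6)
  phases <- character(6)
  for (i in seq_along(LEG_IDS)) {
    leg <- LEG_IDS[i]
    ph <- schedule_phase(sched, leg, tick)
    phases[i] <- ph$phase
    stance[i] <- ph$phase == "stance"
    if (mode == "FK") {
      R <- thc_joint_range(params$theta, leg_side(leg), params$d, params$Sl)
      ang[i, ] <- fk_leg_angles(ph$phase, ph$k, R, params,
                                stance_steps = sched$stance_steps)
    } else {
      ikph <- if (ph$phase == "stance") "stance" else "swing"
      kk <- if (ikph == "swing") {
        (if (ph$phase == "swing1") ph$k else ph$k + sched$Sn) / 2
      } else ph$k
      tgt <- ik_leg_targets(ikph, kk, params, stance_steps = sched$stance_steps)
      # tip-pose x axis points rearward; yaw negated so theta > 0 turns the
      # body CCW, matching the FK yaw-control convention
      b <- model$legs[[leg]]
      trans_base <- drop(rot_z(-b$base_yaw) %*%
                           (tgt$translation * c(-1, 1, 1)))
      ang[i, ] <- leg_inverse_kinematics(model, leg, b$rest_tip + trans_base,
                                         yaw = -tgt$rotation[3])
    }
  }
  list(angles = ang, stance = stance, phases = phases)
}

#' Initialise a gait state
#'
#' @param model an [build_ant_model()] result (needed for IK mode).
#' @param gait_type `"tripod"`, `"ripple"` or `"wave"`.
#' @param mode `"FK"` or `"IK"`.
#' @param Sn half-swing step count per phase.
#' @return a `gait_state` object tracking the schedule and tick counter.
#' @export
gait_state <- function(model, gait_type = "tripod", mode = c("FK", "IK"),
                       Sn = 10) {
  mode <- match.arg(mode)
  structure(list(model = model,
                 schedule = make_gait_schedule(gait_type, Sn),
                 mode = mode, tick = 0L),
            class = "gait_state")
}

#' Advance the gait one tick
#'
#' Pure state transition: evaluates every leg's phase from the schedule and
#' dispatches to [fk_leg_angles()] (FK mode) or [ik_leg_targets()] +
#' [leg_inverse_kinematics()] (IK mode), then increments the tick counter.
#' Steering (`theta`) and stride parameters should only change at cycle
#' boundaries (`state$tick %% state$schedule$cycle_len == 0`).
#'
#' @param state a [gait_state()] object.
#' @param params an [fk_gait_params()] (FK mode) or [ik_gait_params()]
#'   (IK mode) object.
#' @return list with the advanced `state` and `angles`, a tibble with one
#'   row per leg: `leg`, `phase`, `alpha`, `beta`, `gamma`, `in_stance`.
#' @export
gait_step <- function(state, params) {
  if (state$mode == "FK" && !inherits(params, "fk_gait_params")) {
    stop("FK-mode gait_step requires fk_gait_params", call. = FALSE)
  }
  if (state$mode == "IK" && !inherits(params, "ik_gait_params")) {
    stop("IK-mode gait_step requires ik_gait_params", call. = FALSE)
  }
  res <- gait_angles_at(state$model, state$schedule, state$tick, params,
                        state$mode)
  state$tick <- state$tick + 1L
  list(state = state,
       angles = tibble::tibble(leg = LEG_IDS, phase = res$phases,
                               alpha = unname(res$angles[, "alpha"]),
                               beta = unname(res$angles[, "beta"]),
                               gamma = unname(res$angles[, "gamma"]),
                               in_stance = res$stance))
}

#' Generate a joint-angle time series for a gait
#'
#' Convenience wrapper running [gait_step()] for `n_ticks` ticks with fixed
#' parameters; useful for inspecting or exporting gait profiles.
#'
#' @inheritParams gait_state
#' @param params gait parameter object matching `mode`.
#' @param n_ticks number of ticks (default one full cycle).
#' @return tibble `(tick, leg, phase, alpha, beta, gamma, in_stance)`.
#' @export
gait_angle_series <- function(model, params, gait_type = "tripod",
                              mode = if (inherits(params, "ik_gait_params"))
                                "IK" else "FK",
                              n_ticks = NULL) {
  st <- gait_state(model, gait_type, mode, Sn = params$Sn)
  if (is.null(n_ticks)) n_ticks <- st$schedule$cycle_len
  purrr::map_dfr(seq_len(n_ticks), function(t) {
    out <- gait_step(st, params)
    st <<- out$state
    dplyr::mutate(out$angles, tick = t - 1L, .before = 1)
  })
}
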