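#' Planar body pose
#'
#' Position and heading of the ant body in the world frame. Heading is
#' measured CCW from world +x in radians and kept wrapped to (-pi, pi].
#'
#' @param x,y planar position (model units).
#' @param h heading (radians).
#' @return a `body_pose` object.
#' @export
body_pose <- function(x = 0, y = 0, h = 0) {
  stopifnot(is.finite(x), is.finite(y), is.finite(h))
  structure(list(x = x, y = y, h = wrap_angle(h)), class = "body_pose")
}

#' @export
print.body_pose <- function(x, ...) {
  cat(sprintf("<body_pose> x=%.3f y=%.3f h=%.1f deg\n",
              x$x, x$y, rad2deg(x$h)))
  invisible(x)
}

# Least-squares planar rigid fit (2-D Kabsch): rotation angle and
# translation mapping point set `from` onto `to` (2 x n matrices).
rigid_fit_2d <- function(from, to) {
  c_from <- rowMeans(from)
  c_to <- rowMeans(to)
  A <- from - c_from
  B <- to - c_to
  S <- B %*% t(A)                      # 2x2 cross-covariance
  ang <- atan2(S[2, 1] - S[1, 2], S[1, 1] + S[2, 2])
  Rm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  list(angle = ang, translation = c_to - drop(Rm %*% c_from))
}

#' Stance-foot odometry update
#'
#' Kinematic replacement for rigid-body ground contact: the stance feet are
#' assumed anchored to the ground, so the rigid planar motion that best
#' explains their apparent displacement in the body frame (least-squares
#' rigid fit) is applied inversely to the body. With a single stance leg
#' only the translation is recoverable (rotation is set to 0); with no
#' stance legs the pose is returned unchanged with a warning.
#'
#' @param pose a [body_pose()].
#' @param tips_before,tips_after 2-row matrices (x; y, body frame) of the
#'   stance-foot positions at the previous and current tick, columns in the
#'   same leg order.
#' @return the updated `body_pose`.
#' @export
stance_odometry_update <- function(pose, tips_before, tips_after) {
  if (is.null(tips_before) || ncol(tips_before) == 0) {
    warning("no stance legs: pose unchanged", call. = FALSE)
    return(pose)
  }
  stopifnot(ncol(tips_before) == ncol(tips_after))
  if (ncol(tips_before) == 1) {
    dh <- 0
    dp <- drop(tips_before - tips_after)
  } else {
    # world-anchored feet: R(dh) b_after + dp = b_before
    fit <- rigid_fit_2d(tips_after, tips_before)
    dh <- fit$angle
    dp <- fit$translation
  }
  ch <- cos(pose$h); sh <- sin(pose$h)
  body_pose(pose$x + ch * dp[1] - sh * dp[2],
            pose$y + sh * dp[1] + ch * dp[2],
            pose$h + dh)
}

# body-frame (x, y) tip positions for a 6x3 angle matrix in LEG_IDS order
leg_tips_xy <- function(model, ang_mat) {
  out <- matrix(0, 2, 6)
  for (i in 1:6) {
    leg <- LEG_IDS[i]
    tip <- leg_forward_kinematics(model, leg, ang_mat[i, ],
                                  check_limits = FALSE)
    b <- model$legs[[leg]]
    out[, i] <- b$base_pos[1:2] +
      drop(rot_z(b$base_yaw) %*% tip)[1:2]
  }
  out
}

# One embodied tick: evaluate the gait, advance the pose from the feet that
# stayed in stance across the tick. Shared by run_locomotion and the
# scenario runners. `carry` holds prev tips/stance between calls.
embodied_tick <- function(model, sched, tick, params, mode, pose, carry) {
  res <- gait_angles_at(model, sched, tick, params, mode)
  tips <- leg_tips_xy(model, res$angles)
  if (!is.null(carry)) {
    keep <- carry$stance & res$stance
    if (any(keep)) {
      pose <- stance_odometry_update(pose, carry$tips[, keep, drop = FALSE],
                                     tips[, keep, drop = FALSE])
    }
  }
  list(pose = pose, carry = list(tips = tips, stance = res$stance))
}

#' Run open-loop locomotion
#'
#' Composes [gait_step()], leg forward kinematics and
#' [stance_odometry_update()] tick by tick, optionally changing the steering
#' command at each cycle boundary, and logs the trajectory.
#'
#' @param model an [build_ant_model()] result.
#' @param params [fk_gait_params()] or [ik_gait_params()].
#' @param n_cycles number of full gait cycles to run.
#' @param gait_type `"tripod"`, `"ripple"` or `"wave"`.
#' @param theta_schedule optional function `(cycle_index) -> theta` applied
#'   at each cycle boundary (overrides `params$theta`).
#' @param pose initial [body_pose()].
#' @return a `trajectory_log`: tibble `(tick, x, y, h, theta_cmd, sl_cmd)`
#'   with attributes `summary` (mean forward speed per tick, net heading
#'   change per cycle) and `cycle_len`.
#' @export
run_locomotion <- function(model, params, n_cycles = 10,
                           gait_type = "tripod", theta_schedule = NULL,
                           pose = body_pose()) {
  mode <- if (inherits(params, "ik_gait_params")) "IK" else "FK"
  sched <- make_gait_schedule(gait_type, params$Sn)
  cycle_len <- sched$cycle_len
  n_ticks <- n_cycles * cycle_len

  stride <- if (mode == "IK") params$L else params$Sl
  rec <- matrix(0, n_ticks, 6)
  carry <- NULL
  for (t in seq_len(n_ticks)) {
    if (!is.null(theta_schedule) && (t - 1) %% cycle_len == 0) {
      params$theta <- theta_schedule((t - 1) %/% cycle_len)
    }
    step <- embodied_tick(model, sched, t - 1L, params, mode, pose, carry)
    pose <- step$pose
    carry <- step$carry
    rec[t, ] <- c(t - 1, pose$x, pose$y, pose$h, params$theta, stride)
  }

  log <- tibble::tibble(tick = rec[, 1], x = rec[, 2], y = rec[, 3],
                        h = rec[, 4], theta_cmd = rec[, 5], sl_cmd = rec[, 6])
  h_series <- log$h
  net_turn <- sum(wrap_angle(diff(h_series)))
  path_len <- sum(sqrt(diff(log$x)^2 + diff(log$y)^2))
  attr(log, "summary") <- list(
    mean_speed = path_len / (n_ticks - 1),
    net_heading_change_per_cycle = net_turn / n_cycles)
  attr(log, "cycle_len") <- cycle_len
  class(log) <- c("trajectory_log", class(log))
  log
}
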