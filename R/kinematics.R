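#' Leg forward kinematics
#'
#' Composes the per-joint transforms along the coxa-femur-tibia-tarsus chain
#' of one leg and returns the tip position in the leg-base frame (x pointing
#' outward along the leg's rest direction, z up). The active joints are
#' alpha (ThCz, yaw about z), beta (CTr) and gamma (FTi); the two pitch
#' joints rotate about -y so that positive angles lift the tip. ThCx and
#' TiTa are evaluated at their fixed morphology angles.
#'
#' @param model an [build_ant_model()] result.
#' @param leg leg id, one of `"FL","ML","HL","FR","MR","HR"`.
#' @param angles numeric length 3 `c(alpha, beta, gamma)` in degrees.
#' @param check_limits error if an angle is outside its joint limit
#'   (default TRUE).
#' @return numeric length-3 tip position in the leg-base frame (model units).
#' @export
leg_forward_kinematics <- function(model, leg, angles, check_limits = TRUE) {
  leg <- match.arg(leg, LEG_IDS)
  stopifnot(length(angles) == 3, all(is.finite(angles)))
  if (check_limits) {
    lim <- model$morphology$joint_limits
    nm <- c("alpha", "beta", "gamma")
    jn <- c("ThCz", "CTr", "FTi")
    for (i in 1:3) {
      l <- lim[[nm[i]]]
      if (angles[i] < l[1] || angles[i] > l[2]) {
        stop(sprintf("joint %s_%s angle %.2f outside limits [%g, %g]",
                     leg, jn[i], angles[i], l[1], l[2]), call. = FALSE)
      }
    }
  }
  seg <- model$legs[[leg]]$segments
  a <- deg2rad(angles[1]); b <- deg2rad(angles[2]); g <- deg2rad(angles[3])
  thcx <- deg2rad(model$morphology$fixed_thcx)
  tita <- deg2rad(model$morphology$fixed_tita)

  if (thcx == 0) {
    # chain stays in the vertical plane at azimuth alpha: closed form
    e1 <- b; e2 <- b + g; e3 <- b + g + tita
    r <- seg[[1]] + seg[[2]] * cos(e1) + seg[[3]] * cos(e2) + seg[[4]] * cos(e3)
    z <- seg[[2]] * sin(e1) + seg[[3]] * sin(e2) + seg[[4]] * sin(e3)
    return(unname(c(r * cos(a), r * sin(a), z)))
  }

  R1 <- rot_z(a) %*% rot_x(thcx)
  p <- drop(R1 %*% c(seg[["coxa"]], 0, 0))
  R2 <- R1 %*% rot_y(-b)
  p <- p + drop(R2 %*% c(seg[["femur"]], 0, 0))
  R3 <- R2 %*% rot_y(-g)
  p <- p + drop(R3 %*% c(seg[["tibia"]], 0, 0))
  R4 <- R3 %*% rot_y(-tita)
  unname(p + drop(R4 %*% c(seg[["tarsus"]], 0, 0)))
}

#' Leg tip at the rest pose
#' @inheritParams leg_forward_kinematics
#' @return tip position (leg-base frame) at the morphology's rest angles.
#' @export
leg_rest_tip <- function(model, leg) {
  cached <- model$legs[[leg]]$rest_tip
  if (!is.null(cached)) return(cached)
  leg_forward_kinematics(model, leg, model$morphology$rest_angles)
}

#' Leg tip position in the body frame
#' @inheritParams leg_forward_kinematics
#' @return tip position in the body frame (+x forward, +y left, +z up).
#' @export
leg_tip_body <- function(model, leg, angles) {
  leg <- match.arg(leg, LEG_IDS)
  tip <- leg_forward_kinematics(model, leg, angles)
  b <- model$legs[[leg]]
  b$base_pos + drop(rot_z(b$base_yaw) %*% tip)
}

#' Leg inverse kinematics
#'
#' Closed-form inverse kinematics for the three active joints of one leg:
#' the target is first rotated by `yaw` about the leg-base z axis (the pose's
#' yaw component, absorbed by ThCz), alpha then points the leg's vertical
#' plane at the target and the two pitch joints are solved in that plane by
#' the law of cosines (elbow-up branch). Requires the fixed ThCx and TiTa
#' angles to be zero (the default morphology), which makes tibia + tarsus a
#' straight effective segment.
#'
#' @inheritParams leg_forward_kinematics
#' @param target numeric length-3 tip position in the leg-base frame.
#' @param yaw additional yaw about the leg-base z axis (radians) applied to
#'   the target before solving; assigned to ThCz.
#' @return named numeric `c(alpha, beta, gamma)` in degrees, satisfying
#'   `leg_forward_kinematics(model, leg, .)` = target (after yaw) to 1e-9.
#' @export
leg_inverse_kinematics <- function(model, leg, target, yaw = 0) {
  leg <- match.arg(leg, LEG_IDS)
  stopifnot(length(target) == 3, all(is.finite(target)))
  if (model$morphology$fixed_thcx != 0 || model$morphology$fixed_tita != 0) {
    stop("closed-form IK requires fixed ThCx and TiTa angles of 0",
         call. = FALSE)
  }
  seg <- model$legs[[leg]]$segments
  p <- if (yaw != 0) drop(rot_z(yaw) %*% target) else target

  alpha <- atan2(p[2], p[1])
  r <- sqrt(p[1]^2 + p[2]^2) - seg[["coxa"]]
  z <- p[3]
  d <- sqrt(r^2 + z^2)
  fe <- seg[["femur"]]
  le <- seg[["tibia"]] + seg[["tarsus"]]
  if (d > fe + le + 1e-12 || d < abs(fe - le) - 1e-12) {
    stop(sprintf(
      "target unreachable for leg %s: planar distance %.4f outside [%.4f, %.4f]",
      leg, d, abs(fe - le), fe + le), call. = FALSE)
  }
  clamp1 <- function(x) min(1, max(-1, x))
  beta <- atan2(z, r) + acos(clamp1((fe^2 + d^2 - le^2) / (2 * fe * d)))
  gamma <- acos(clamp1((fe^2 + le^2 - d^2) / (2 * fe * le))) - pi
  c(alpha = rad2deg(alpha), beta = rad2deg(beta), gamma = rad2deg(gamma))
}
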