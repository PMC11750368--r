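LEG_IDS <- c("FL", "ML", "HL", "FR", "MR", "HR")
LEFT_LEGS <- c("FL", "ML", "HL")
RIGHT_LEGS <- c("FR", "MR", "HR")

leg_group <- function(leg) {
  switch(substr(leg, 1, 1), F = "front", M = "middle", H = "hind",
         stop("unknown leg id: ", leg, call. = FALSE))
}

leg_side <- function(leg) if (substr(leg, 2, 2) == "L") "left" else "right"

#' Build the ant's kinematic model
#'
#' Constructs the full joint tree: five joints per leg (ThCx, ThCz, CTr,
#' FTi, TiTa, named segment-pair + rotation axis), three per antenna, two in
#' the neck and two in the abdomen — 40 joints in total. The six leg tips
#' and two antenna tips are the eight tactile end-effector points. ThCx and
#' TiTa are held at fixed angles; the active triple per leg is
#' (alpha = ThCz, beta = CTr, gamma = FTi).
#'
#' @param morphology an [ant_morphology()] object.
#' @return an object of class `ant_model` with elements `morphology`,
#'   `joints` (one row per joint: joint, limb, axis, fixed, fixed_angle,
#'   lower, upper) and `legs` (per-leg scaled segment lengths and base
#'   transforms).
#' @examples
#' model <- build_ant_model(ant_morphology())
#' nrow(model$joints)   # 40
#' @export
build_ant_model <- function(morphology = ant_morphology()) {
  validate_morphology(morphology)
  s <- morphology$scale
  lim <- morphology$joint_limits

  leg_rows <- purrr::map(LEG_IDS, function(leg) {
    tibble::tibble(
      joint = paste0(leg, "_", c("ThCx", "ThCz", "CTr", "FTi", "TiTa")),
      limb = leg,
      axis = c("x", "z", "-y", "-y", "-y"),
      fixed = c(TRUE, FALSE, FALSE, FALSE, TRUE),
      fixed_angle = c(morphology$fixed_thcx, NA, NA, NA, morphology$fixed_tita),
      lower = c(NA, lim$alpha[1], lim$beta[1], lim$gamma[1], NA),
      upper = c(NA, lim$alpha[2], lim$beta[2], lim$gamma[2], NA))
  })
  ant_rows <- purrr::map(c("AL", "AR"), function(a) {
    tibble::tibble(
      joint = paste0(a, "_", c("ScPz", "ScPy", "PdFy")),
      limb = a, axis = c("z", "-y", "-y"),
      fixed = FALSE, fixed_angle = NA_real_,
      lower = -180, upper = 180)
  })
  body_rows <- tibble::tibble(
    joint = c("Neck_y", "Neck_z", "Abd_y", "Abd_z"),
    limb = c("neck", "neck", "abdomen", "abdomen"),
    axis = c("y", "z", "y", "z"),
    fixed = FALSE, fixed_angle = NA_real_, lower = -90, upper = 90)

  joints <- dplyr::bind_rows(c(leg_rows, ant_rows, list(body_rows)))

  legs <- purrr::map(LEG_IDS, function(leg) {
    g <- leg_group(leg)
    base_xy <- morphology$leg_base_xy[[g]] * s
    yaw <- morphology$leg_base_yaw[[g]]
    if (leg_side(leg) == "right") {
      base_xy[2] <- -base_xy[2]
      yaw <- -yaw
    }
    list(leg = leg,
         segments = morphology$leg_segments[[g]] * s,
         base_pos = c(base_xy, 0),
         base_yaw = deg2rad(yaw))
  })
  names(legs) <- LEG_IDS

  antennae <- purrr::map(c("AL", "AR"), function(a) {
    base <- morphology$antenna_base_xyz * s
    rest_yaw <- 25
    if (a == "AR") {
      base[2] <- -base[2]
      rest_yaw <- -rest_yaw
    }
    list(antenna = a, segments = morphology$antenna_segments * s,
         base_pos = base, rest_angles = c(yaw = rest_yaw, pitch = -10, flex = 0))
  })
  names(antennae) <- c("AL", "AR")

  model <- structure(list(morphology = morphology, joints = joints,
                          legs = legs, antennae = antennae),
                     class = "ant_model")
  for (leg in LEG_IDS) {
    model$legs[[leg]]$rest_tip <-
      leg_forward_kinematics(model, leg, morphology$rest_angles)
  }
  model
}

#' @export
print.ant_model <- function(x, ...) {
  cat("<ant_model>", nrow(x$joints), "joints,",
      length(x$legs), "legs,", length(end_effectors(x)), "end effectors\n")
  invisible(x)
}

#' Number of joints in the model
#' @param model an `ant_model`.
#' @return integer joint count (40 for the default build).
#' @export
n_joints <- function(model) nrow(model$joints)

#' Degrees of freedom of one leg
#' @param model an `ant_model`.
#' @param leg a leg id (`"FL"`, `"ML"`, `"HL"`, `"FR"`, `"MR"`, `"HR"`).
#' @return integer d.f. count (fixed joints included; 5 per leg).
#' @export
leg_dof <- function(model, leg) {
  sum(model$joints$limb == match.arg(leg, LEG_IDS))
}

#' End-effector (tactile) points of the model
#'
#' @param model an `ant_model`.
#' @return character vector of the eight tactile tips: six leg tips and two
#'   antenna tips.
#' @export
end_effectors <- function(model) {
  c(paste0(LEG_IDS, "_tip"), "AL_tip", "AR_tip")
}
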