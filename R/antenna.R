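#' Antennal state and active sweeping
#'
#' Each antenna has three joints (yaw at the scape base, pitch at the scape
#' base, flex between scape and funiculus). In `fixed` mode the antennae
#' hold their rest angles; in `moving` mode the lateral (yaw) joints
#' oscillate sinusoidally around rest with the configured amplitude and
#' period, left and right in antiphase, emulating active antennal sweeping.
#' Sweep kinematics are not constrained by measured data; amplitude and
#' period are configuration values.
#'
#' @param mode `"fixed"` or `"moving"`.
#' @param amplitude sweep amplitude (degrees, >= 0).
#' @param period sweep period (ticks, >= 2).
#' @param phase phase offset (ticks).
#' @return an `antenna_state` object.
#' @export
antenna_state <- function(mode = c("fixed", "moving"), amplitude = 30,
                          period = 20, phase = 0) {
  mode <- match.arg(mode)
  stopifnot(amplitude >= 0, period >= 2)
  structure(list(mode = mode, amplitude = amplitude, period = period,
                 phase = phase), class = "antenna_state")
}

#' Antenna joint angles at a tick
#'
#' @param state an [antenna_state()].
#' @param tick integer tick.
#' @param model an `ant_model` (for the rest angles).
#' @return named list `AL`, `AR` of `c(yaw, pitch, flex)` in degrees.
#' @export
antenna_sweep <- function(state, tick, model = NULL) {
  rest <- if (is.null(model)) {
    list(AL = c(yaw = 25, pitch = -10, flex = 0),
         AR = c(yaw = -25, pitch = -10, flex = 0))
  } else {
    list(AL = model$antennae$AL$rest_angles,
         AR = model$antennae$AR$rest_angles)
  }
  if (state$mode == "fixed") return(rest)
  osc <- state$amplitude * sin(2 * pi * (tick + state$phase) / state$period)
  rest$AL[1] <- rest$AL[1] + osc
  rest$AR[1] <- rest$AR[1] - osc   # antiphase in the signed joint angle
  rest
}

# world positions (3-vectors) of both antenna tips for a body pose
antenna_tips_world <- function(model, pose, state, tick) {
  ang <- antenna_sweep(state, tick, model)
  ch <- cos(pose$h); sh <- sin(pose$h)
  out <- list()
  for (a in c("AL", "AR")) {
    ant <- model$antennae[[a]]
    yaw <- deg2rad(ang[[a]][1]); pitch <- deg2rad(ang[[a]][2])
    flex <- deg2rad(ang[[a]][3])
    R1 <- rot_z(yaw) %*% rot_y(-pitch)
    p <- ant$base_pos + drop(R1 %*% c(ant$segments[[1]], 0, 0))
    R2 <- R1 %*% rot_y(-flex)
    p <- p + drop(R2 %*% c(ant$segments[[2]] + ant$segments[[3]], 0, 0))
    out[[a]] <- c(pose$x + ch * p[1] - sh * p[2],
                  pose$y + sh * p[1] + ch * p[2],
                  p[3])
  }
  out
}
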