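#' One odour-trail-following step
#'
#' Bilateral comparison of the antennal trail-sensor readings. Odour is
#' sensed when either reading reaches the on-trail threshold `To`; the
#' left-right difference `Od = Ol - Or` then steers the agent: a small
#' difference (|Od| < Td) means the trail lies ahead, so walk straight and
#' fast; a large difference turns the agent toward the stronger side
#' (`theta = Od / kd`); with no odour the agent casts randomly (`theta`
#' drawn from {-1, +1}) at a short step length. Thresholds `Td = 5`,
#' `To = 900` and the scale `kd = 400` follow the trail sensor's 0-1000
#' calibration.
#'
#' Uses the session RNG for the random cast; seed the caller for
#' reproducibility.
#'
#' @param Ol,Or left/right trail-sensor readings in [0, 1000].
#' @param To on-trail threshold.
#' @param Td left-right difference deadband.
#' @param kd steering scale divisor.
#' @return list `theta` (rotation configuration; may exceed [-1, 1] and is
#'   clipped at the gait), `Sl` (hip swing, degrees) and `sensed`
#'   (logical).
#' @export
trail_follow_step <- function(Ol, Or, To = 900, Td = 5, kd = 400) {
  stopifnot(Ol >= 0, Or >= 0)
  sensed <- max(Ol, Or) >= To
  Od <- Ol - Or
  if (sensed && abs(Od) < Td) {
    list(theta = 0, Sl = 8, sensed = TRUE)
  } else if (sensed) {
    list(theta = Od / kd, Sl = 4, sensed = TRUE)
  } else {
    list(theta = sample(c(-1, 1), 1), Sl = 3, sensed = FALSE)
  }
}

#' Plume-tracker state
#'
#' Tracks the cast/surge behavioural mode of the plume-tracking controller.
#'
#' @param Top odour detection threshold on the concentration.
#' @return a `plume_tracker_state` with `mode` (`"search"`, `"orient"` or
#'   `"surge"`) and a surge counter in {0, 1, 2}.
#' @export
plume_tracker_state <- function(Top = 1e-6) {
  structure(list(mode = "search", surge = 0L, Top = Top),
            class = "plume_tracker_state")
}

#' One plume-tracking step
#'
#' With no odour above threshold the agent searches locally: `theta` is
#' drawn from {-1, +1} and the hip swing is a small 5 degrees. When odour
#' is detected, the wind is read on the higher-concentration side, the
#' upwind bearing `m = atan2(-wy, -wx)` (two-argument arctangent of the
#' negated wind) is compared with the heading, and the agent orients with
#' `theta = sign(m - h)` and `Sl = min(5 + |(m - h) mod 5|, 15)` (the
#' difference wrapped to (-180, 180] degrees first). After the orienting
#' gait loop the directive prescribes two straight surge loops (`Sl = 15`,
#' `theta = 0`) before re-sensing.
#'
#' @param state a [plume_tracker_state()].
#' @param Ol,Or odour concentrations at the left/right antenna tips.
#' @param Wl,Wr wind vectors `c(wx, wy)` at the left/right antenna tips.
#' @param h current heading (radians).
#' @return list with the updated `state`, `theta`, `Sl` (degrees) for the
#'   next gait loop, and `surge_loops` (0 in search mode, 2 after an
#'   orienting step) to execute at `Sl = 15`, `theta = 0`.
#' @export
plume_track_step <- function(state, Ol, Or, Wl, Wr, h) {
  if (max(Ol, Or) <= state$Top) {
    state$mode <- "search"
    state$surge <- 0L
    return(list(state = state, theta = sample(c(-1, 1), 1), Sl = 5,
                surge_loops = 0L))
  }
  wind <- if (Ol >= Or) Wl else Wr
  m <- atan2(-wind[2], -wind[1])
  delta <- wrap_angle(m - h)
  delta_deg <- rad2deg(delta)
  theta <- sign(delta)
  Sl <- min(5 + abs(delta_deg) %% 5, 15)
  state$mode <- "orient"
  state$surge <- 2L
  list(state = state, theta = theta, Sl = Sl, surge_loops = 2L)
}
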