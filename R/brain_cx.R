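#' Central-complex path integration state
#'
#' A rate-based, noise-free central-complex (CX) circuit for path
#' integration: two TN2 speed cells with preferred axes at +/-45 degrees to
#' the body axis, an 8-column TB1 heading ring (sinusoidal encoding of the
#' current heading), 16 CPU4 memory cells (two banks of 8 columns) that
#' integrate speed gated by the inverted heading signal — together storing
#' the home vector — and 16 CPU1 steering cells comparing the memory
#' against the heading ring with a one-column offset. The summed
#' left-minus-right CPU1 difference, scaled by the motor gain `kPI`, is the
#' rotation configuration fed to the gait controller; the hip swing follows
#' the speed-modulation rule `Sl = Sl0 + Slf * (1 - min(|theta|, 1))`,
#' confining the step length to [Sl0, Sl0 + Slf] = [5, 25] degrees.
#'
#' All activities are clamped to [0, 1]; CPU4 starts at a uniform 0.5
#' baseline.
#'
#' @param gain CPU4 integration gain per unit speed input.
#' @param decay uniform CPU4 decay per step (0 = pure integrator).
#' @param k_speed scaling from speed (model units per controller step) to
#'   TN2 drive; chosen so typical stride speeds stay well inside the clamp.
#' @param kPI motor scale from the CPU1 difference to theta.
#' @param Sl0 basis step length, degrees.
#' @param Slf step-length scale factor, degrees.
#' @return a `cx_state` object.
#' @export
cx_state <- function(gain = 0.0025, decay = 0, k_speed = 0.5, kPI = 10,
                     Sl0 = 5, Slf = 20) {
  structure(list(tn2 = c(0, 0),
                 tb1 = rep(0, 8),
                 cpu4 = rep(0.5, 16),
                 cpu1 = rep(0, 16),
                 gain = gain, decay = decay, k_speed = k_speed, kPI = kPI,
                 Sl0 = Sl0, Slf = Slf),
            class = "cx_state")
}

CX_COL_DIRS <- 2 * pi * (0:7) / 8

#' Speed modulation of the hip swing by the steering command
#'
#' The step length shrinks as the steering demand grows:
#' `Sl = Sl0 + Slf * (1 - min(|theta|, 1))`, so the hip swing is confined
#' to `[Sl0, Sl0 + Slf]` = [5, 25] degrees at the defaults — full stride
#' when walking straight, minimum stride when turning hard.
#'
#' @param theta rotation configuration (any finite value; vectorised).
#' @param Sl0 basis step length, degrees.
#' @param Slf scale factor, degrees.
#' @return hip swing Sl in degrees.
#' @export
speed_modulation <- function(theta, Sl0 = 5, Slf = 20) {
  Sl0 + Slf * (1 - pmin(abs(theta), 1))
}

#' Sinusoidal 8-column heading encoding
#'
#' TB1-style encoding: column i (preferred direction `2 pi i / 8`,
#' i = 0..7) takes activity `(1 + cos(h - dir_i)) / 2`.
#'
#' @param h heading (radians).
#' @return numeric length-8 activity vector in [0, 1].
#' @export
heading_encoding <- function(h) (1 + cos(h - CX_COL_DIRS)) / 2

clamp01 <- function(x) pmin(1, pmax(0, x))

# CPU1-style comparison: the desired encoding, shifted one column backward
# (left bank) or forward (right bank), excites each steering cell while the
# current heading encoding gates (inhibits) it. For sinusoidal encodings
# the summed left-minus-right difference is proportional to
# sin(desired - current): zero when aligned or opposed, maximal near
# +/-90 degrees, positive when the desired heading lies CCW of the
# current one.
cpu1_compare <- function(current, desired) {
  left <- clamp01(desired[c(8, 1:7)] * (1 - current))
  right <- clamp01(desired[c(2:8, 1)] * (1 - current))
  c(left, right)
}

#' One path-integration step
#'
#' Updates the CX state from the current heading and speed and returns the
#' motor commands. Speed is the distance advanced since the previous
#' controller step (one gait cycle in the embodied loop).
#'
#' @param state a [cx_state()].
#' @param h current heading (radians).
#' @param v speed (model units per controller step, >= 0).
#' @return list with the updated `state`, `theta` (rotation configuration)
#'   and `Sl` (hip swing, degrees, in [Sl0, Sl0 + Slf]).
#' @export
cx_pi_step <- function(state, h, v) {
  stopifnot(is.finite(h), v >= 0)
  state$tn2 <- clamp01(rep(state$k_speed * v * cos(pi / 4), 2))
  state$tb1 <- heading_encoding(h)
  gate <- 1 - state$tb1
  state$cpu4 <- clamp01(
    state$cpu4 + state$gain * rep(state$tn2, each = 8) * c(gate, gate) -
      state$decay)
  state$cpu1 <- cpu1_compare(state$tb1,
                             (state$cpu4[1:8] + state$cpu4[9:16]) / 2)
  theta <- state$kPI * (sum(state$cpu1[1:8]) - sum(state$cpu1[9:16]))
  list(state = state, theta = theta,
       Sl = speed_modulation(theta, state$Sl0, state$Slf))
}

#' Decode the stored home vector
#'
#' Folds the 16 CPU4 cells into one 8-column sinusoid (bank average),
#' removes the common baseline and extracts the phase (home bearing, world
#' frame) and amplitude (proportional to home distance) by projection onto
#' the column directions.
#'
#' @param state a [cx_state()].
#' @param eps amplitude below which the bearing is flagged undefined.
#' @return list `bearing` (radians; `NA` if undefined), `magnitude`
#'   (arbitrary units) and `defined` (logical).
#' @export
decode_home_vector <- function(state, eps = 1e-6) {
  folded <- (state$cpu4[1:8] + state$cpu4[9:16]) / 2
  z <- sum((folded - mean(folded)) * exp(1i * CX_COL_DIRS))
  mag <- Mod(z)
  if (mag < eps) {
    list(bearing = NA_real_, magnitude = 0, defined = FALSE)
  } else {
    list(bearing = Arg(z), magnitude = mag, defined = TRUE)
  }
}

#' Steering command from a desired heading encoding
#'
#' CPU1-style comparison of a desired 8-column heading encoding against the
#' current one: theta is zero when they agree, positive when the desired
#' heading lies CCW (left) of the current one, and largest in magnitude
#' near +/-90 degree offsets.
#'
#' @param current,desired length-8 sinusoidal heading encodings (see
#'   [heading_encoding()]).
#' @param k motor scale.
#' @return scalar theta.
#' @export
steering_from_desired <- function(current, desired, k = 1) {
  stopifnot(length(current) == 8, length(desired) == 8)
  cpu1 <- cpu1_compare(current, desired)
  k * (sum(cpu1[1:8]) - sum(cpu1[9:16]))
}
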