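#' Generate a landmark world
#'
#' Builds a scene with one beacon landmark plus optional distractor shapes
#' at seeded positions. The beacon defaults to a dark cylinder at bearing
#' pi/2 (the convention shared by the visual-beacon trials, whose initial
#' headings are sampled around that bearing).
#'
#' @param spec list with optional entries `beacon` (list `bearing`
#'   (radians), `distance`, `radius`, `height`, `type`, `intensity`),
#'   `n_distractors`, `distractor_range` (`c(rmin, rmax)` radial placement
#'   band), `distractor_size` (`c(min, max)` radius band).
#' @param seed integer seed for distractor placement.
#' @return a [scene()] whose first primitive is the beacon; the beacon
#'   centre is stored in the `beacon` attribute.
#' @export
make_landmark_world <- function(spec = list(), seed = 1) {
  # default beacon proportions follow classic ant landmark-approach arenas:
  # a dark cylinder subtending roughly 17 degrees from the start point
  b <- utils::modifyList(
    list(bearing = pi / 2, distance = 20, radius = 3, height = 12,
         type = "cylinder", intensity = 0),
    spec$beacon %||% list())
  beacon_center <- c(b$distance * cos(b$bearing), b$distance * sin(b$bearing))
  prims <- list(list(type = b$type,
                     center = c(beacon_center, 0),
                     radius = b$radius, height = b$height,
                     intensity = b$intensity))
  n_d <- spec$n_distractors %||% 0
  if (n_d > 0) {
    rng_band <- spec$distractor_range %||% c(15, 30)
    size_band <- spec$distractor_size %||% c(1, 3)
    set.seed(seed)
    types <- c("cylinder", "sphere", "cone")
    for (i in seq_len(n_d)) {
      ang <- stats::runif(1, 0, 2 * pi)
      r <- stats::runif(1, rng_band[1], rng_band[2])
      sz <- stats::runif(1, size_band[1], size_band[2])
      ty <- types[(i - 1) %% 3 + 1]
      ctr <- c(r * cos(ang), r * sin(ang), if (ty == "sphere") sz else 0)
      prims[[length(prims) + 1]] <-
        list(type = ty, center = ctr, radius = sz,
             height = if (ty == "sphere") NULL else stats::runif(1, 3, 8),
             intensity = 0)
    }
  }
  # reject specs whose primitives overlap in the ground plane
  if (length(prims) > 1) {
    ctrs <- t(vapply(prims, function(p) p$center[1:2], numeric(2)))
    rads <- vapply(prims, function(p) p$radius, numeric(1))
    for (i in seq_len(length(prims) - 1)) {
      for (j in seq(i + 1, length(prims))) {
        if (sqrt(sum((ctrs[i, ] - ctrs[j, ])^2)) < rads[i] + rads[j]) {
          stop("landmark world spec has overlapping primitives (", i,
               ", ", j, ")", call. = FALSE)
        }
      }
    }
  }
  sc <- scene(prims)
  attr(sc, "beacon") <- beacon_center
  sc
}

#' Generate a correlated random-walk foraging route
#'
#' Command series for an outbound foraging trip: the start is fixed at the
#' origin, the initial heading is uniform on [0, 2 pi), and per-step
#' heading increments are zero-mean Gaussian with standard deviation
#' `turn_noise` (radians), smoothed over three steps for a correlated walk.
#' The returned tibble carries both the abstract series (heading `h`, unit
#' speed `v`) for disembodied path-integration studies and a scaled
#' steering command `theta_cmd` for the embodied runner.
#'
#' @param n_ticks number of route steps (>= 1).
#' @param turn_noise heading-increment standard deviation (radians/step).
#' @param seed integer seed.
#' @return tibble `(step, dh, h, v, theta_cmd)` with attribute `h0` (the
#'   initial heading).
#' @export
make_foraging_route <- function(n_ticks = 200, turn_noise = 0.15, seed = 1) {
  stopifnot(n_ticks >= 0)
  set.seed(seed)
  h0 <- stats::runif(1, 0, 2 * pi)
  if (n_ticks == 0) {
    out <- tibble::tibble(step = integer(), dh = numeric(), h = numeric(),
                          v = numeric(), theta_cmd = numeric())
    attr(out, "h0") <- h0
    return(out)
  }
  dh <- stats::rnorm(n_ticks, 0, turn_noise)
  if (n_ticks >= 3) {
    dh <- stats::filter(dh, rep(1 / 3, 3), sides = 1)
    dh[is.na(dh)] <- 0
    dh <- as.numeric(dh)
  }
  if (n_ticks >= 1) dh[1] <- 0
  h <- wrap_angle(h0 + cumsum(dh))
  out <- tibble::tibble(step = seq_len(n_ticks), dh = dh, h = h, v = 1,
                        theta_cmd = pmax(-1, pmin(1, dh / deg2rad(40))))
  attr(out, "h0") <- h0
  out
}
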