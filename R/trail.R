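#' Odour trail maps
#'
#' The odour trail is simulated optically, as a high-intensity band painted
#' on the floor; the antennal trail sensor reads the floor reflectance under
#' the antenna tip. A `trail_map` is a grayscale raster (0-255) with an
#' invertible world-to-pixel transform: pixel (row, col) covers the world
#' point `origin + res * (col - 1, row - 1)` (row index along +y).
#'
#' @param raster numeric matrix of intensities in [0, 255]; rows index y,
#'   columns index x.
#' @param origin world coordinates `c(x, y)` of the center of pixel (1, 1).
#' @param res world size of one pixel (model units, > 0).
#' @param centerline optional 2-column matrix of the trail centerline.
#' @param goal optional world `c(x, y)` of the trail end.
#' @return a `trail_map` object.
#' @export
trail_map <- function(raster, origin = c(0, 0), res = 0.1,
                      centerline = NULL, goal = NULL) {
  stopifnot(is.matrix(raster), res > 0, length(origin) == 2)
  structure(list(raster = raster, origin = origin, res = res,
                 centerline = centerline, goal = goal),
            class = "trail_map")
}

#' @export
print.trail_map <- function(x, ...) {
  cat(sprintf("<trail_map> %d x %d px, res %.3f, origin (%.1f, %.1f)\n",
              nrow(x$raster), ncol(x$raster), x$res, x$origin[1],
              x$origin[2]))
  invisible(x)
}

#' Read the trail sensor at a world position
#'
#' Models the antennal infra-red reflectance sensor as a linear 0-1000
#' reading: 1000 times the bilinearly interpolated, normalised trail
#' intensity under the given point. On-trail interior points read at the
#' full trail intensity (1000 for a 255-valued band, comfortably above the
#' trail-following controller's on-trail threshold of 900); points off the
#' raster or over background read 0.
#'
#' @param trail a [trail_map()].
#' @param pos world position; only the first two components (x, y) are
#'   used, so an antenna-tip 3-D position can be passed directly.
#' @return scalar reading in [0, 1000].
#' @export
trail_sensor_read <- function(trail, pos) {
  px <- (pos[1] - trail$origin[1]) / trail$res + 1
  py <- (pos[2] - trail$origin[2]) / trail$res + 1
  r <- trail$raster
  if (px < 1 || py < 1 || px > ncol(r) || py > nrow(r)) return(0)
  x0 <- floor(px); y0 <- floor(py)
  x1 <- min(x0 + 1, ncol(r)); y1 <- min(y0 + 1, nrow(r))
  fx <- px - x0; fy <- py - y0
  v <- r[y0, x0] * (1 - fx) * (1 - fy) + r[y0, x1] * fx * (1 - fy) +
    r[y1, x0] * (1 - fx) * fy + r[y1, x1] * fx * fy
  1000 * v / 255
}

#' Generate a curved trail map
#'
#' Draws a single connected band of the requested width following a seeded
#' smooth curve. The centerline starts at `start` with heading `heading0`
#' and accumulates smoothed Gaussian heading noise (`curvature`, radians per
#' unit length); the band is stamped as overlapping discs of diameter
#' `width` along the centerline. The curve's end point is stored as the
#' trail goal.
#'
#' @param width trail band width (model units, > 0).
#' @param curvature standard deviation of the heading increments (radians
#'   per unit arc length); 0 gives a straight trail.
#' @param length trail arc length (model units).
#' @param seed integer RNG seed.
#' @param res raster resolution (model units per pixel).
#' @param start,heading0 start point and initial heading of the centerline.
#' @param margin raster margin around the trail's bounding box.
#' @return a [trail_map()] with `centerline` and `goal` set.
#' @export
make_trail_map <- function(width = 2, curvature = 0.1, length = 14,
                           seed = 1, res = 0.1, start = c(5, 0),
                           heading0 = pi, margin = NULL) {
  stopifnot(width > 0, length > 0, res > 0)
  if (length / res < 2) stop("degenerate trail: length too short for res",
                             call. = FALSE)
  set.seed(seed)
  n <- ceiling(length / res)
  dh <- stats::rnorm(n, 0, curvature * sqrt(res))
  dh <- stats::filter(dh, rep(1 / 5, 5), sides = 2)
  dh[is.na(dh)] <- 0
  h <- heading0 + cumsum(dh)
  pts <- cbind(start[1] + cumsum(c(0, cos(h[-n]) * res)),
               start[2] + cumsum(c(0, sin(h[-n]) * res)))
  if (is.null(margin)) margin <- width / 2 + 1
  x0 <- min(pts[, 1]) - margin; x1 <- max(pts[, 1]) + margin
  y0 <- min(pts[, 2]) - margin; y1 <- max(pts[, 2]) + margin
  ncol_ <- ceiling((x1 - x0) / res) + 1
  nrow_ <- ceiling((y1 - y0) / res) + 1
  raster <- matrix(0, nrow_, ncol_)
  rad <- width / 2 / res
  irad <- ceiling(rad)
  off <- expand.grid(dx = -irad:irad, dy = -irad:irad)
  off <- off[off$dx^2 + off$dy^2 <= rad^2, ]
  for (i in seq_len(n)) {
    cx <- round((pts[i, 1] - x0) / res) + 1
    cy <- round((pts[i, 2] - y0) / res) + 1
    xs <- cx + off$dx; ys <- cy + off$dy
    ok <- xs >= 1 & xs <= ncol_ & ys >= 1 & ys <= nrow_
    raster[cbind(ys[ok], xs[ok])] <- 255
  }
  trail_map(raster, origin = c(x0, y0), res = res, centerline = pts,
            goal = pts[n, ])
}

#' Write / read a trail map as a grayscale PNG
#'
#' The raster is stored as PNG; the transform (origin, res) goes in a YAML
#' sidecar next to it. Requires the `png` package.
#'
#' @param trail a [trail_map()].
#' @param path PNG file path; the sidecar is `<path>.yml`.
#' @return `write_trail_png` the path, invisibly; `read_trail_png` a
#'   [trail_map()].
#' @export
write_trail_png <- function(trail, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("writing PNG trail maps requires the 'png' package", call. = FALSE)
  }
  png::writePNG(trail$raster[nrow(trail$raster):1, , drop = FALSE] / 255,
                path)
  yaml::write_yaml(list(origin = as.numeric(trail$origin), res = trail$res,
                        goal = as.numeric(trail$goal)),
                   paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_trail_png
#' @param path PNG file path written by [write_trail_png()].
#' @export
read_trail_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("reading PNG trail maps requires the 'png' package", call. = FALSE)
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  trail_map(img[nrow(img):1, , drop = FALSE] * 255,
            origin = meta$origin, res = meta$res, goal = meta$goal)
}
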