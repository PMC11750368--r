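#' Synthetic visual scenes
#'
#' A scene is a list of landmark primitives (spheres, vertical cylinders and
#' cones) on an infinite bright ground/sky background. Landmarks are dark by
#' default (intensity 0 on a background of 255), matching the
#' dark-silhouette assumption of the visual controllers. Rendering is
#' analytic silhouette ray-casting: each pixel's ray is intersected with
#' every primitive and takes the nearest hit's intensity.
#'
#' @param primitives list of primitive lists, each with `type`
#'   (`"sphere"`, `"cylinder"`, `"cone"`), `center` (`c(x, y, z)`; base
#'   center for cylinder/cone, sphere center for spheres), `radius`, and for
#'   cylinder/cone `height`; optional `intensity` (default 0).
#' @param background background intensity in [0, 255].
#' @param trail_map optional [trail_map()] attached to the scene floor.
#' @param rotation world rotation angle (radians) about the world origin,
#'   applied to all primitives at render time; used by the visual-compass
#'   experiments to rotate the world around the agent.
#' @return a `scene` object.
#' @export
scene <- function(primitives = list(), background = 255, trail_map = NULL,
                  rotation = 0) {
  for (p in primitives) {
    if (!p$type %in% c("sphere", "cylinder", "cone")) {
      stop("unknown primitive type: ", p$type, call. = FALSE)
    }
    if (p$radius <= 0) stop("primitive radius must be positive", call. = FALSE)
    if (p$type != "sphere" && (is.null(p$height) || p$height <= 0)) {
      stop("cylinder/cone primitives need a positive height", call. = FALSE)
    }
    intens <- p$intensity %||% 0
    if (intens < 0 || intens > 255) {
      stop("primitive intensity must be in [0, 255]", call. = FALSE)
    }
  }
  if (background < 0 || background > 255) {
    stop("background intensity must be in [0, 255]", call. = FALSE)
  }
  structure(list(primitives = primitives, background = background,
                 trail_map = trail_map, rotation = rotation),
            class = "scene")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cast unit rays from a common origin; dirs is 3 x n. Returns intensities.
ray_cast <- function(sc, origin, dirs) {
  n <- ncol(dirs)
  best_t <- rep(Inf, n)
  intens <- rep(sc$background, n)
  rot <- sc$rotation
  for (p in sc$primitives) {
    ctr <- p$center
    if (rot != 0) {
      ctr <- c(cos(rot) * p$center[1] - sin(rot) * p$center[2],
               sin(rot) * p$center[1] + cos(rot) * p$center[2], p$center[3])
    }
    o <- origin - c(ctr[1], ctr[2], 0)   # xy relative to axis/center
    t_hit <- rep(Inf, n)
    if (p$type == "sphere") {
      oc <- origin - ctr
      b <- 2 * (dirs[1, ] * oc[1] + dirs[2, ] * oc[2] + dirs[3, ] * oc[3])
      cc <- sum(oc^2) - p$radius^2
      disc <- b^2 - 4 * cc
      ok <- disc >= 0
      t1 <- (-b[ok] - sqrt(disc[ok])) / 2
      t1[t1 <= 0] <- Inf
      t_hit[ok] <- t1
    } else {
      # vertical quadric: cylinder r(z) = R; cone r(z) = R (1 - (z-zb)/h)
      zb <- ctr[3]; h <- p$height; R <- p$radius
      if (p$type == "cylinder") {
        a <- dirs[1, ]^2 + dirs[2, ]^2
        b <- 2 * (dirs[1, ] * o[1] + dirs[2, ] * o[2])
        cc <- o[1]^2 + o[2]^2 - R^2
      } else {
        k <- R / h
        w0 <- zb + h - origin[3]          # apex z minus origin z
        a <- dirs[1, ]^2 + dirs[2, ]^2 - k^2 * dirs[3, ]^2
        b <- 2 * (dirs[1, ] * o[1] + dirs[2, ] * o[2] + k^2 * dirs[3, ] * w0)
        cc <- o[1]^2 + o[2]^2 - k^2 * w0^2
      }
      disc <- b^2 - 4 * a * cc
      ok <- disc >= 0 & abs(a) > 1e-12
      if (any(ok)) {
        sq <- sqrt(disc[ok])
        ta <- (-b[ok] - sq) / (2 * a[ok])
        tb <- (-b[ok] + sq) / (2 * a[ok])
        z_a <- origin[3] + dirs[3, ok] * ta
        z_b <- origin[3] + dirs[3, ok] * tb
        ta[ta <= 0 | z_a < zb | z_a > zb + h] <- Inf
        tb[tb <= 0 | z_b < zb | z_b > zb + h] <- Inf
        t_hit[ok] <- pmin(ta, tb)
      }
    }
    better <- t_hit < best_t
    if (any(better)) {
      best_t[better] <- t_hit[better]
      intens[better] <- p$intensity %||% 0
    }
  }
  intens
}

#' Render the panoramic view
#'
#' Spherical projection: columns sample azimuth uniformly over the full
#' circle (column 1 looks along the heading, azimuth decreasing — i.e.
#' turning clockwise in the world — across the image), rows sample elevation
#' from the zenith (row 1) to the nadir. Increasing the agent's yaw by
#' `delta` circularly shifts the image columns by `width * delta / (2 pi)`.
#'
#' @param sc a [scene()].
#' @param pose a [body_pose()].
#' @param eye_height camera height above the ground (model units).
#' @param width,height image resolution (default 72 x 72).
#' @return a `panoramic_image`: `height x width` intensity matrix with a
#'   `background` attribute.
#' @export
render_panorama <- function(sc, pose, eye_height = 1, width = 72,
                            height = 72) {
  az <- pose$h - 2 * pi * (seq_len(width) - 1) / width
  el <- pi / 2 - pi * (seq_len(height) - 0.5) / height
  A <- matrix(rep(az, each = height), height, width)
  E <- matrix(rep(el, width), height, width)
  dirs <- rbind(as.vector(cos(E) * cos(A)),
                as.vector(cos(E) * sin(A)),
                as.vector(sin(E)))
  img <- matrix(ray_cast(sc, c(pose$x, pose$y, eye_height), dirs),
                height, width)
  structure(img, background = sc$background, class = "panoramic_image")
}

#' Render one eye's planar (pinhole) view
#'
#' Pinhole projection with a 2 rad horizontal and 0.5 rad vertical field of
#' view at 74 x 19 resolution by default. The optical axis points along the
#' body heading; the eyes sit at the head sides separated by the
#' morphology's eye separation (zero toe-in). A landmark at horizontal angle
#' `phi` to the image-right of the axis projects to column
#' `width/2 + f * tan(phi)` with `f = (width/2) / tan(fov_h/2)`.
#'
#' @param sc a [scene()].
#' @param pose a [body_pose()].
#' @param eye `"left"` or `"right"`.
#' @param model optional `ant_model` supplying head/eye geometry; default
#'   uses the default morphology.
#' @param width,height image resolution.
#' @param fov_h,fov_v horizontal/vertical field of view (radians).
#' @param aa anti-aliasing factor: each pixel averages `aa x aa` sub-rays,
#'   giving continuous-valued silhouette edges as a real camera would;
#'   `aa = 1` disables it.
#' @return an `eye_image`: `height x width` intensity matrix with a
#'   `background` attribute.
#' @export
render_binocular <- function(sc, pose, eye = c("left", "right"),
                             model = NULL, width = 74, height = 19,
                             fov_h = 2, fov_v = 0.5, aa = 2) {
  eye <- match.arg(eye)
  morph <- if (is.null(model)) ant_morphology() else model$morphology
  head <- morph$head_xyz * morph$scale
  sep <- morph$eye_sep * morph$scale
  ey <- if (eye == "left") sep / 2 else -sep / 2
  ch <- cos(pose$h); sh <- sin(pose$h)
  origin <- c(pose$x + ch * head[1] - sh * ey,
              pose$y + sh * head[1] + ch * ey,
              head[3])
  axis <- c(ch, sh, 0)
  right <- c(sh, -ch, 0)
  f <- (width / 2) / tan(fov_h / 2)
  fv <- (height / 2) / tan(fov_v / 2)
  aa <- max(1L, as.integer(aa))
  sub <- (seq_len(aa) - 0.5) / aa
  img <- matrix(0, height, width)
  for (sx in sub) {
    for (sy in sub) {
      xn <- (seq_len(width) - 1 + sx - width / 2) / f
      yn <- (seq_len(height) - 1 + sy - height / 2) / fv
      XN <- matrix(rep(xn, each = height), height, width)
      YN <- matrix(rep(yn, width), height, width)
      dx <- axis[1] + XN * right[1]
      dy <- axis[2] + XN * right[2]
      dz <- -YN
      nrm <- sqrt(dx^2 + dy^2 + dz^2)
      dirs <- rbind(as.vector(dx / nrm), as.vector(dy / nrm),
                    as.vector(dz / nrm))
      img <- img + matrix(ray_cast(sc, origin, dirs), height, width)
    }
  }
  img <- img / aa^2
  structure(img, background = sc$background, class = "eye_image")
}

#' Binarise a rendered image
#'
#' Marks pixels whose intensity differs from the background by more than the
#' threshold (dark-landmark pixels for the default scenes).
#'
#' @param img an intensity matrix (`panoramic_image` or `eye_image`).
#' @param threshold intensity threshold in [0, 255]; the visual-beacon
#'   controller's default is 18, the midpoint of the empirically useful
#'   range.
#' @param background background intensity; taken from the image attribute
#'   if present.
#' @return logical mask of the same dimensions.
#' @export
binarize_image <- function(img, threshold = 18,
                           background = attr(img, "background") %||% 255) {
  stopifnot(threshold >= 0, threshold <= 255)
  abs(unclass(img) - background) > threshold
}
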