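#' Ant morphology
#'
#' Segment geometry of the simulated desert ant. All lengths are stored at
#' real-ant scale (metres) and multiplied by `scale` (default 100, i.e. the
#' model ant is one hundred times larger than the animal, which keeps the
#' simulated world at a convenient size). Hind legs are longer than middle
#' legs, which are longer than front legs, the characteristic desert-ant
#' leg proportion; left and right legs are mirror images about the sagittal
#' plane.
#'
#' The default segment lengths are declared here once and nowhere else;
#' replace them via the arguments (or a YAML morphology config, see
#' [read_morphology_config()]) to use measured values.
#'
#' @param scale dimensionless multiplier applied to every length (default 100).
#' @param leg_segments named list with entries `front`, `middle`, `hind`,
#'   each a numeric vector `c(coxa, femur, tibia, tarsus)` in metres at
#'   real-ant scale. Left/right pairs share these values (mirror symmetry).
#' @param leg_base_xy named list `front`, `middle`, `hind` of `c(x, y)`
#'   left-side leg-base positions in the body frame (+x forward, +y left);
#'   right bases are the y-mirror.
#' @param leg_base_yaw named numeric `front`, `middle`, `hind`: yaw of the
#'   left leg-base frame's outward x-axis, degrees CCW from body +x; right
#'   sides are negated.
#' @param antenna_segments numeric length 3 `c(scape, pedicel, flagellum)`
#'   in metres; both antennae identical.
#' @param antenna_base_xyz `c(x, y, z)` of the left antenna base in the body
#'   frame (metres at ant scale); right is the y-mirror.
#' @param eye_sep lateral separation of the two eye cameras (metres).
#' @param head_xyz `c(x, y, z)` of the eye midpoint / panoramic camera
#'   location in the body frame (metres at ant scale).
#' @param fixed_thcx,fixed_tita fixed angles (degrees) of the thorax-coxa
#'   x-axis joint and tibia-tarsus joint; held constant by the gait
#'   controllers. The closed-form leg IK assumes both are 0.
#' @param rest_angles `c(alpha, beta, gamma)` rest pose of the three active
#'   leg joints (ThCz, CTr, FTi), degrees.
#' @param joint_limits named list `alpha`, `beta`, `gamma` of `c(lower,
#'   upper)` limits in degrees for the active joints.
#' @return an object of class `ant_morphology`.
#' @export
ant_morphology <- function(scale = 100,
                           leg_segments = list(
                             front  = c(coxa = 0.0040, femur = 0.0100,
                                        tibia = 0.0090, tarsus = 0.0050),
                             middle = c(coxa = 0.0044, femur = 0.0110,
                                        tibia = 0.0099, tarsus = 0.0055),
                             hind   = c(coxa = 0.0052, femur = 0.0130,
                                        tibia = 0.0117, tarsus = 0.0065)),
                           leg_base_xy = list(front  = c(0.0100, 0.0045),
                                              middle = c(0.0000, 0.0050),
                                              hind   = c(-0.0100, 0.0045)),
                           leg_base_yaw = c(front = 60, middle = 90, hind = 120),
                           antenna_segments = c(scape = 0.0050,
                                                pedicel = 0.0030,
                                                flagellum = 0.0070),
                           antenna_base_xyz = c(0.0160, 0.0015, 0.0080),
                           eye_sep = 0.0040,
                           head_xyz = c(0.0150, 0, 0.0100),
                           fixed_thcx = 0,
                           fixed_tita = 0,
                           rest_angles = c(alpha = 0, beta = 30, gamma = -75),
                           joint_limits = list(alpha = c(-100, 100),
                                               beta  = c(-45, 135),
                                               gamma = c(-170, 20))) {
  m <- structure(
    list(scale = scale,
         leg_segments = leg_segments,
         leg_base_xy = leg_base_xy,
         leg_base_yaw = leg_base_yaw,
         antenna_segments = antenna_segments,
         antenna_base_xyz = antenna_base_xyz,
         eye_sep = eye_sep,
         head_xyz = head_xyz,
         fixed_thcx = fixed_thcx,
         fixed_tita = fixed_tita,
         rest_angles = rest_angles,
         joint_limits = joint_limits),
    class = "ant_morphology")
  validate_morphology(m)
  m
}

#' @export
print.ant_morphology <- function(x, ...) {
  cat("<ant_morphology> scale =", x$scale, "\n")
  for (g in names(x$leg_segments)) {
    cat(sprintf("  %-6s leg segments (model units): %s  total %.2f\n", g,
                paste(sprintf("%.2f", x$leg_segments[[g]] * x$scale),
                      collapse = " "),
                sum(x$leg_segments[[g]]) * x$scale))
  }
  invisible(x)
}

validate_morphology <- function(m) {
  for (g in c("front", "middle", "hind")) {
    seg <- m$leg_segments[[g]]
    if (length(seg) != 4 || any(!is.finite(seg)) || any(seg <= 0)) {
      stop("invalid morphology: leg_segments$", g,
           " must be 4 strictly positive lengths", call. = FALSE)
    }
  }
  if (sum(m$leg_segments$hind) <= sum(m$leg_segments$front)) {
    stop("invalid morphology: hind-leg total length must exceed ",
         "front-leg total length (leg_segments)", call. = FALSE)
  }
  if (length(m$antenna_segments) != 3 || any(m$antenna_segments <= 0)) {
    stop("invalid morphology: antenna_segments must be 3 positive lengths",
         call. = FALSE)
  }
  if (m$scale <= 0) stop("invalid morphology: scale must be positive",
                         call. = FALSE)
  for (nm in c("alpha", "beta", "gamma")) {
    lim <- m$joint_limits[[nm]]
    if (is.null(lim) || lim[1] >= lim[2]) {
      stop("invalid morphology: joint_limits$", nm, call. = FALSE)
    }
  }
  invisible(m)
}

#' Read a morphology configuration from YAML
#'
#' The YAML file may specify any subset of [ant_morphology()]'s arguments;
#' unspecified fields keep their defaults.
#'
#' @param path path to a YAML file.
#' @return an `ant_morphology` object.
#' @export
read_morphology_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- cfg[intersect(names(cfg), names(formals(ant_morphology)))]
  cfg <- lapply(cfg, function(x) if (is.list(x)) lapply(x, unlist) else unlist(x))
  do.call(ant_morphology, cfg)
}
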