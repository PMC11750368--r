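#' Desired-heading shift from binarised eye images
#'
#' Copy-and-shift visual beaconing: the horizontal offset `delta` between
#' the image centre and the mean column of the dark-landmark pixels
#' determines how many 45-degree columns the current heading encoding is
#' shifted to form the desired heading. `delta` is positive when the
#' landmark lies left of centre; the shift magnitude is
#' `ceiling(|6 delta / W|)` with the sign of `delta`. The default `delta`
#' uses the image centre (`W/2 - Pl`); `form = "width"` selects the literal
#' width-based variant (`W - Pl`).
#'
#' @param left_mask,right_mask logical masks from [binarize_image()] (only
#'   the mask(s) required by `mode` are used; the other may be `NULL`).
#' @param mode `"left"`, `"right"` (monocular) or `"binocular"`.
#' @param form `"center"` (default) or `"width"` reference for `delta`.
#' @return list `detected` (logical), `shift` (non-negative integer),
#'   `sign` (-1, 0, 1) and `delta` (pixels). With no landmark pixels in the
#'   mode's mask(s), `detected` is FALSE and the caller should keep its
#'   previous command.
#' @export
beacon_desired_shift <- function(left_mask = NULL, right_mask = NULL,
                                 mode = c("binocular", "left", "right"),
                                 form = c("center", "width")) {
  mode <- match.arg(mode)
  form <- match.arg(form)
  eye_delta <- function(mask) {
    if (is.null(mask) || !any(mask)) return(NULL)
    W <- ncol(mask)
    cols <- col(mask)[mask] - 0.5          # pixel centres in [0, W]
    Pl <- mean(cols)
    if (form == "center") W / 2 - Pl else W - Pl
  }
  deltas <- switch(mode,
    left = list(eye_delta(left_mask)),
    right = list(eye_delta(right_mask)),
    binocular = Filter(Negate(is.null),
                       list(eye_delta(left_mask), eye_delta(right_mask))))
  deltas <- Filter(Negate(is.null), deltas)
  if (length(deltas) == 0) {
    return(list(detected = FALSE, shift = 0L, sign = 0, delta = NA_real_))
  }
  delta <- mean(unlist(deltas))
  W <- ncol(if (!is.null(left_mask)) left_mask else right_mask)
  list(detected = TRUE,
       shift = as.integer(ceiling(abs(6 * delta / W))),
       sign = sign(delta),
       delta = delta)
}

#' Shift a heading encoding by whole columns
#'
#' Copy-and-shift: shifting by `+s` columns yields the encoding of a
#' heading `s * 45` degrees CCW of the encoded one.
#'
#' @param enc length-8 heading encoding.
#' @param s signed integer column shift.
#' @return shifted encoding.
#' @export
shift_encoding <- function(enc, s) {
  s <- ((s %% 8) + 8) %% 8
  if (s == 0) return(enc)
  enc[((seq_len(8) - 1 - s) %% 8) + 1]
}

zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  out <- 0
  for (s in 0:((n - m) / 2)) {
    out <- out + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) *
         factorial((n - m) / 2 - s)) * rho^(n - 2 * s)
  }
  out
}

#' Zernike moment of a panoramic image
#'
#' Maps the panorama onto the unit disk — column c becomes polar angle
#' `2 pi (c - 1) / W`, row r becomes radius `(r - 0.5) / H` (zenith at the
#' centre) — and computes the complex Zernike coefficient of order `n` and
#' repetition `m` with the `(n + 1) / pi` normalisation over the discrete
#' polar grid. Circularly shifting the image by `s` columns multiplies the
#' coefficient by `exp(-i m s 2 pi / W)`: the phase is a rotational
#' signature of the view, which the visual compass exploits.
#'
#' @param img intensity matrix (rows = elevation from the zenith,
#'   columns = azimuth), e.g. a [render_panorama()] result.
#' @param n order (>= 0).
#' @param m repetition; `n - |m|` must be even and non-negative.
#' @return complex coefficient.
#' @export
zernike_moment <- function(img, n = 7, m = 1) {
  if (n < abs(m) || (n - abs(m)) %% 2 != 0) {
    stop("invalid Zernike order/repetition: need n >= |m| and n - |m| even",
         call. = FALSE)
  }
  H <- nrow(img); W <- ncol(img)
  rho <- (seq_len(H) - 0.5) / H
  theta <- 2 * pi * (seq_len(W) - 1) / W
  radial <- zernike_radial(n, m, rho) * rho        # includes area factor rho
  ang <- exp(-1i * m * theta)
  # separable double sum: sum_r sum_c f[r,c] R(rho_r) rho_r e^{-i m theta_c}
  s <- sum(drop(radial %*% unclass(img)) * ang)
  (n + 1) / pi * s * (1 / H) * (2 * pi / W) / 255
}

#' Visual-compass memory
#'
#' Stores the Zernike phase of the first panoramic view as the desired
#' rotational signature.
#'
#' @param img the initial panoramic image.
#' @param n,m Zernike order and repetition (defaults 7 and 1).
#' @return a `compass_memory` object.
#' @export
compass_memory <- function(img, n = 7, m = 1) {
  z <- zernike_moment(img, n, m)
  structure(list(phi0 = Arg(z), n = n, m = m,
                 prev = list(theta = 0, Sl = 0)),
            class = "compass_memory")
}

#' One visual-compass step
#'
#' Compares the current view's Zernike phase with the stored one; the
#' wrapped difference sets the turn direction (`theta = sign(delta)`, with
#' `sign(0) = 0`) and the hip swing `Sl = |delta / 5|` (radians of phase;
#' the scenario runner converts to degrees at the gait boundary). A
#' featureless panorama (coefficient magnitude below `eps`) holds the
#' previous command and flags low confidence.
#'
#' @param img current panoramic image.
#' @param memory a [compass_memory()].
#' @param eps minimum coefficient magnitude for a confident phase.
#' @return list `theta`, `Sl`, `delta` (wrapped phase difference, radians),
#'   `low_confidence` and the updated `memory`.
#' @export
visual_compass_step <- function(img, memory, eps = 1e-9) {
  z <- zernike_moment(img, memory$n, memory$m)
  if (Mod(z) < eps) {
    return(list(theta = memory$prev$theta, Sl = memory$prev$Sl,
                delta = NA_real_, low_confidence = TRUE, memory = memory))
  }
  delta <- wrap_angle(Arg(z) - memory$phi0)
  theta <- sign(delta)
  Sl <- abs(delta / 5)
  memory$prev <- list(theta = theta, Sl = Sl)
  list(theta = theta, Sl = Sl, delta = delta, low_confidence = FALSE,
       memory = memory)
}
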