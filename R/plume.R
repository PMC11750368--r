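#' Filament-based odour plume parameters
#'
#' The plume is a set of Gaussian puffs released at the source and advected
#' by a noisy wind field, mimicking the short-timescale filament structure
#' and long-timescale meander of a turbulent plume. The wind is a mean
#' vector plus a first-order autoregressive (coloured-noise) perturbation;
#' each puff additionally receives its own centerline-dispersion noise and
#' its squared radius grows linearly in time. Concentration at a point is
#' the superposition of normalised 3-D Gaussian kernels,
#' `sum_j q * (2 pi s_j)^(-3/2) * exp(-|x - p_j|^2 / (2 s_j))`.
#'
#' No upstream parameter values constrain this model; the defaults produce
#' an intermittent but trackable plume at the package's world scale and are
#' all exposed here.
#'
#' @param source puff release position `c(x, y, z)`.
#' @param release_rate puffs released per tick (>= 0; fractions accumulate).
#' @param wind_mean mean wind vector `c(wx, wy)` (model units per tick).
#' @param wind_noise_sd standard deviation of the coloured wind
#'   perturbation (model units per tick).
#' @param wind_corr one-tick autocorrelation of the wind perturbation in
#'   [0, 1).
#' @param wind_spatial_mag amplitude of the smooth spatial wind modulation
#'   (0 disables it); nearby points differ by at most
#'   `wind_spatial_mag * wind_spatial_freq * distance`.
#' @param wind_spatial_freq spatial frequency (radians per model unit) of
#'   the modulation.
#' @param dispersion_sd per-tick centerline relative-dispersion noise
#'   applied to each puff (model units).
#' @param growth_rate growth of the squared puff radius per tick (> 0).
#' @param init_radius_sq initial squared puff radius (> 0).
#' @param q puff release strength (> 0).
#' @param bounds domain `c(xmin, xmax, ymin, ymax)`; puffs leaving it are
#'   culled.
#' @return a `plume_params` object.
#' @export
plume_params <- function(source = c(0, 0, 0.6),
                         release_rate = 0.5,
                         wind_mean = c(0.05, 0),
                         wind_noise_sd = 0.01,
                         wind_corr = 0.98,
                         wind_spatial_mag = 0,
                         wind_spatial_freq = 0.2,
                         dispersion_sd = 0.02,
                         growth_rate = 0.002,
                         init_radius_sq = 0.5,
                         q = 1,
                         bounds = c(-5, 40, -15, 15)) {
  if (release_rate < 0) stop("release_rate must be >= 0", call. = FALSE)
  if (growth_rate <= 0) stop("growth_rate must be > 0", call. = FALSE)
  if (init_radius_sq <= 0) stop("init_radius_sq must be > 0", call. = FALSE)
  if (q <= 0) stop("q must be > 0", call. = FALSE)
  if (bounds[1] >= bounds[2] || bounds[3] >= bounds[4]) {
    stop("bounds must be well-ordered (xmin < xmax, ymin < ymax)",
         call. = FALSE)
  }
  if (wind_corr < 0 || wind_corr >= 1) {
    stop("wind_corr must be in [0, 1)", call. = FALSE)
  }
  structure(as.list(environment()), class = "plume_params")
}

#' Initialise a plume state
#'
#' @param params a [plume_params()].
#' @param seed integer seed for the plume's private RNG stream.
#' @return a `plume_state`: puff matrix (columns x, y, z, s), wind
#'   perturbation state, release accumulator, tick counter and puff-count
#'   bookkeeping (`released`, `culled`).
#' @export
plume_init <- function(params, seed = 1) {
  rng <- structure(list(), class = "plume_rng")
  state <- structure(
    list(params = params,
         puffs = matrix(numeric(0), 0, 4,
                        dimnames = list(NULL, c("x", "y", "z", "s"))),
         wind_pert = c(0, 0),
         release_acc = 0,
         tick = 0L,
         released = 0L,
         culled = 0L,
         rng_state = NULL),
    class = "plume_state")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  state$rng_state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  state
}

# run expr under the plume's private RNG stream
with_plume_rng <- function(state, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  assign(".Random.seed", state$rng_state, globalenv())
  val <- force(expr)
  new_rng <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(value = val, rng_state = new_rng)
}

#' Advance the plume by one step
#'
#' Releases `floor(release_rate * dt)` new puffs (the fractional remainder
#' accumulates across calls), advances the coloured wind perturbation,
#' advects every puff by the local wind plus its centerline-dispersion
#' noise, grows every squared radius by `growth_rate * dt` and culls puffs
#' that left the domain. Deterministic given the state's RNG stream.
#'
#' @param state a [plume_state][plume_init()].
#' @param dt time step in ticks (> 0).
#' @return the advanced `plume_state`.
#' @export
plume_step <- function(state, dt = 1) {
  stopifnot(dt > 0)
  p <- state$params
  res <- with_plume_rng(state, {
    state$release_acc <- state$release_acc + p$release_rate * dt
    n_new <- floor(state$release_acc)
    state$release_acc <- state$release_acc - n_new
    if (n_new > 0) {
      state$puffs <- rbind(state$puffs,
                           matrix(c(rep(p$source, each = n_new),
                                    rep(p$init_radius_sq, n_new)),
                                  n_new, 4))
      state$released <- state$released + n_new
    }
    a <- p$wind_corr^dt
    state$wind_pert <- a * state$wind_pert +
      p$wind_noise_sd * sqrt(1 - a^2) * stats::rnorm(2)
    np <- nrow(state$puffs)
    if (np > 0) {
      w <- wind_field(p, state$wind_pert, state$puffs[, 1, drop = TRUE],
                      state$puffs[, 2, drop = TRUE])
      state$puffs[, 1] <- state$puffs[, 1] + w[, 1] * dt +
        stats::rnorm(np, 0, p$dispersion_sd * sqrt(dt))
      state$puffs[, 2] <- state$puffs[, 2] + w[, 2] * dt +
        stats::rnorm(np, 0, p$dispersion_sd * sqrt(dt))
      state$puffs[, 4] <- state$puffs[, 4] + p$growth_rate * dt
      inside <- state$puffs[, 1] >= p$bounds[1] &
        state$puffs[, 1] <= p$bounds[2] &
        state$puffs[, 2] >= p$bounds[3] & state$puffs[, 2] <= p$bounds[4]
      state$culled <- state$culled + sum(!inside)
      state$puffs <- state$puffs[inside, , drop = FALSE]
    }
    state$tick <- state$tick + 1L
    state
  })
  out <- res$value
  out$rng_state <- res$rng_state
  out
}

# deterministic wind field: mean + uniform coloured perturbation + optional
# smooth spatial modulation; x, y vectorised
wind_field <- function(p, pert, x, y) {
  wx <- p$wind_mean[1] + pert[1]
  wy <- p$wind_mean[2] + pert[2]
  if (p$wind_spatial_mag > 0) {
    wx <- wx + p$wind_spatial_mag * sin(p$wind_spatial_freq * y)
    wy <- wy + p$wind_spatial_mag * sin(p$wind_spatial_freq * x)
  }
  cbind(wx + 0 * x, wy + 0 * y)
}

#' Odour concentration at a point
#'
#' Superposition of the puffs' normalised 3-D Gaussian kernels; zero with
#' no puffs, strictly positive otherwise, and linear in the puff set.
#'
#' @param state a `plume_state`.
#' @param point `c(x, y, z)` query position.
#' @return scalar concentration (>= 0).
#' @export
concentration_at <- function(state, point) {
  pf <- state$puffs
  if (nrow(pf) == 0) return(0)
  d2 <- (pf[, 1] - point[1])^2 + (pf[, 2] - point[2])^2 +
    (pf[, 3] - point[3])^2
  sum(state$params$q * (2 * pi * pf[, 4])^(-1.5) * exp(-d2 / (2 * pf[, 4])))
}

#' Wind vector at a point
#'
#' Mean wind plus the current coloured-noise perturbation (and the optional
#' smooth spatial modulation). With zero noise magnitudes this is exactly
#' the mean wind.
#'
#' @param state a `plume_state`.
#' @param point `c(x, y)` (or `c(x, y, z)`) query position.
#' @return wind vector `c(wx, wy)` in model units per tick.
#' @export
wind_at <- function(state, point) {
  drop(wind_field(state$params, state$wind_pert, point[1], point[2]))
}

#' Number of live puffs
#' @param state a `plume_state`.
#' @return integer puff count (equals released minus culled).
#' @export
n_puffs <- function(state) nrow(state$puffs)
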