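# shared fixtures: one default model for the whole suite
default_model <- build_ant_model()

# a random reachable tip target for one leg, drawn in joint space so
# reachability is guaranteed by construction
random_reachable_target <- function(model, leg) {
  ang <- c(stats::runif(1, -80, 80), stats::runif(1, -20, 100),
           stats::runif(1, -150, -5))
  leg_forward_kinematics(model, leg, ang)
}

# a small textured scene giving a non-degenerate panorama
textured_scene <- function() {
  scene(list(
    list(type = "cylinder", center = c(15, 5, 0), radius = 2, height = 6),
    list(type = "sphere", center = c(-10, 8, 3), radius = 3),
    list(type = "cone", center = c(4, -12, 0), radius = 3, height = 8),
    list(type = "cylinder", center = c(-6, -14, 0), radius = 1.5,
         height = 9)))
}

circshift_cols <- function(img, s) {
  n <- ncol(img)
  img[, ((seq_len(n) - 1 - s) %% n) + 1]
}
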