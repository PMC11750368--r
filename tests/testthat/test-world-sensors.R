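test_that("an empty scene renders as uniform background", {
  img <- render_panorama(scene(background = 200), body_pose())
  expect_equal(dim(img), c(72, 72))
  expect_true(all(img == 200))
})

test_that("panorama columns shift with agent yaw", {
  sc <- textured_scene()
  p0 <- render_panorama(sc, body_pose(0, 0, 0))
  for (cols in c(3, 10, 31)) {
    delta <- 2 * pi * cols / 72
    p1 <- render_panorama(sc, body_pose(0, 0, delta))
    expect_equal(unclass(p1), unclass(circshift_cols(p0, cols)),
                 ignore_attr = TRUE)
  }
})

test_that("a dark cylinder appears as a dark column block at its bearing", {
  bearing <- pi / 3
  sc <- scene(list(list(type = "cylinder",
                        center = c(12 * cos(bearing), 12 * sin(bearing), 0),
                        radius = 1.5, height = 8)))
  img <- render_panorama(sc, body_pose(0, 0, 0))
  dark_cols <- which(apply(unclass(img) < 255, 2, any))
  # column 1 looks along the heading; azimuth decreases across columns
  expected_col <- round((-bearing %% (2 * pi)) * 72 / (2 * pi)) + 1
  expect_true(all(abs(dark_cols - expected_col) <= 2 |
                    abs(dark_cols - expected_col) >= 70))
})

test_that("binocular projection follows the pinhole model", {
  sc <- scene(list(list(type = "cylinder", center = c(10, 0, 0),
                        radius = 1, height = 5)))
  img <- render_binocular(sc, body_pose(), "left")
  expect_equal(dim(img), c(19, 74))
  mask <- binarize_image(img)
  centroid <- mean(col(mask)[mask] - 0.5)
  expect_lt(abs(centroid - 37), 1)

  # off-axis landmark: centroid ~ W/2 + f tan(phi), phi positive to the
  # image right (clockwise)
  phi <- -0.35   # landmark 0.35 rad to the left
  sc2 <- scene(list(list(type = "cylinder",
                         center = c(10 * cos(phi), -10 * sin(phi), 0),
                         radius = 1, height = 5)))
  mask2 <- binarize_image(render_binocular(sc2, body_pose(), "left"))
  centroid2 <- mean(col(mask2)[mask2] - 0.5)
  f <- 37 / tan(1)
  expect_lt(abs(centroid2 - (37 + f * tan(phi))), 2)

  # no landmark in the field of view -> all background
  behind <- scene(list(list(type = "cylinder", center = c(-10, 0, 0),
                            radius = 1, height = 5)))
  expect_true(all(render_binocular(behind, body_pose(), "left") == 255))
})

test_that("left and right views of a centred landmark are mirror images", {
  sc <- scene(list(list(type = "cylinder", center = c(8, 0, 0),
                        radius = 1.2, height = 5)))
  l <- render_binocular(sc, body_pose(), "left")
  r <- render_binocular(sc, body_pose(), "right")
  expect_equal(unclass(l), unclass(r)[, ncol(r):1], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("binarisation marks exactly the non-background pixels", {
  expect_false(any(binarize_image(matrix(255, 10, 10), 18)))
  img <- matrix(255, 19, 74)
  img[8:12, 30:40] <- 40
  expect_equal(sum(binarize_image(img, 18)), 5 * 11)
  img2 <- matrix(255, 5, 5); img2[3, 3] <- 254
  expect_equal(sum(binarize_image(img2, 0)), 1)
})

test_that("trail sensor reads bilinear reflectance in 0-1000", {
  tr <- make_trail_map(width = 2, curvature = 0, length = 10, seed = 1,
                       start = c(5, 0), heading0 = pi)
  # interior of the band
  expect_gte(trail_sensor_read(tr, c(2, 0)), 900)
  # far off the trail
  expect_lt(trail_sensor_read(tr, c(2, 5)), 5)
  # straddling the edge: strictly between the adjacent samples
  edge_y <- 1 + tr$res / 2
  r_edge <- trail_sensor_read(tr, c(2, edge_y))
  r_in <- trail_sensor_read(tr, c(2, edge_y - tr$res))
  r_out <- trail_sensor_read(tr, c(2, edge_y + tr$res))
  expect_gt(r_edge, r_out)
  expect_lt(r_edge, r_in)
  # outside the raster entirely
  expect_equal(trail_sensor_read(tr, c(100, 100)), 0)
})

test_that("generated trails have the requested width and are reproducible", {
  tr1 <- make_trail_map(width = 2, curvature = 0.3, length = 12, seed = 9)
  tr2 <- make_trail_map(width = 2, curvature = 0.3, length = 12, seed = 9)
  expect_identical(tr1$raster, tr2$raster)
  # band width across perpendicular sections ~ width +/- 1 px
  cl <- tr1$centerline
  for (i in c(30, 60, 90)) {
    tang <- cl[i + 1, ] - cl[i - 1, ]
    nrm <- c(-tang[2], tang[1]) / sqrt(sum(tang^2))
    ts <- seq(-2, 2, by = tr1$res / 2)
    vals <- sapply(ts, function(t) {
      trail_sensor_read(tr1, cl[i, ] + t * nrm)
    })
    measured <- diff(range(ts[vals > 500]))
    expect_lt(abs(measured - 2), 2 * tr1$res + 0.11)
  }
  # doubling the width keeps the centerline
  tr3 <- make_trail_map(width = 4, curvature = 0.3, length = 12, seed = 9)
  expect_equal(tr3$centerline, tr1$centerline)
  expect_gt(mean(tr3$raster > 0), mean(tr1$raster > 0))
})

test_that("antennal sweeping oscillates laterally in antiphase", {
  fixed <- antenna_state("fixed")
  m <- default_model
  a0 <- antenna_sweep(fixed, 0, m)
  a9 <- antenna_sweep(fixed, 9, m)
  expect_identical(a0, a9)

  mov <- antenna_state("moving", amplitude = 30, period = 20)
  expect_equal(antenna_sweep(mov, 3, m), antenna_sweep(mov, 23, m))
  defl <- sapply(0:19, function(t) {
    a <- antenna_sweep(mov, t, m)
    a$AL[1] - a0$AL[1]
  })
  expect_equal(max(abs(defl)), 30, tolerance = 1e-9)
  # antiphase: the right yaw offset is the negative of the left
  for (t in c(2, 7, 13)) {
    a <- antenna_sweep(mov, t, m)
    expect_equal(a$AL[1] - a0$AL[1], -(a$AR[1] - a0$AR[1]),
                 tolerance = 1e-9)
  }
})

test_that("moving antennae sweep a strictly wider lateral band", {
  m <- default_model
  pose <- body_pose()
  band <- function(state) {
    ys <- sapply(0:19, function(t) {
      antenna_tips_world(m, pose, state, t)$AL[2]
    })
    diff(range(ys))
  }
  expect_gt(band(antenna_state("moving")), band(antenna_state("fixed")) + 0.5)
})

test_that("trail maps survive a PNG round trip", {
  tr <- make_trail_map(width = 2, curvature = 0.2, length = 8, seed = 4)
  path <- withr::local_tempfile(fileext = ".png")
  write_trail_png(tr, path)
  back <- read_trail_png(path)
  expect_equal(back$raster, tr$raster, tolerance = 1)
  expect_equal(back$res, tr$res)
})

test_that("scene validation rejects malformed primitives", {
  expect_error(scene(list(list(type = "cube", center = c(0, 0, 0),
                               radius = 1))), "unknown primitive")
  expect_error(scene(list(list(type = "sphere", center = c(0, 0, 0),
                               radius = -1))), "radius")
  expect_error(scene(list(list(type = "cylinder", center = c(0, 0, 0),
                               radius = 1))), "height")
  expect_error(scene(background = 300), "background")
})
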