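test_that("camera pose reproduces the closed-form placement convention", {
  # front view: azimuth 90, zenith 90 -> camera in the aisle, looking at +y
  p <- camera_pose(90, 90, 0, target = c(0, 0, 1), range_m = 0.5)
  expect_equal(p$position, c(0, -0.5, 1), tolerance = 1e-9)
  expect_equal(p$direction, c(0, 1, 0), tolerance = 1e-9)

  # zenith 60 looks upward: v = (0, sin60, cos60)
  p60 <- camera_pose(90, 60, 0, target = c(0, 0, 1), range_m = 0.5)
  expect_equal(p60$direction, c(0, sqrt(3) / 2, 0.5), tolerance = 1e-9)
  expect_equal(p60$position, c(0, -sqrt(3) / 4, 0.75), tolerance = 1e-9)

  # zenith 120 looks downward
  expect_lt(camera_pose(90, 120, 0, c(0, 0, 1))$direction[3], 0)

  # offset shifts position and target together along the row
  poff <- camera_pose(90, 90, 0.15, target = c(0, 0, 1))
  expect_equal(poff$position[1], 0.15, tolerance = 1e-12)

  expect_equal(sqrt(sum(p60$direction^2)), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum((p60$position - p60$target)^2)), 0.5,
               tolerance = 1e-12)
})

test_that("mirrored azimuths give mirror-symmetric positions about the target plane", {
  a <- camera_pose(30, 90, 0, c(0, 0, 1))
  b <- camera_pose(150, 90, 0, c(0, 0, 1))
  expect_equal(a$position * c(-1, 1, 1), b$position, tolerance = 1e-12)
})

test_that("aisle-side zenith poses stay in the half-space in front of the crop", {
  for (z in c(60, 90, 120)) {
    p <- camera_pose(90, z, 0, c(0, 0, 1))
    expect_lt(p$position[2], 0)
  }
})

test_that("degenerate pose parameters are rejected", {
  expect_error(camera_pose(90, 0, 0), "zenith")
  expect_error(camera_pose(90, 180, 0), "zenith")
  expect_error(camera_pose(0, 90, 0), "azimuth")
  expect_error(camera_pose(90, 90, 0, range_m = 0), "range")
})

test_that("quantization snaps to the nearest level, midpoints rounding down", {
  expect_equal(quantize_fv(100), 100)
  expect_equal(quantize_fv(47), 50)
  expect_equal(quantize_fv(15), 10)    # midpoint of 10 and 20
  expect_equal(quantize_fv(2.5), 0)    # midpoint of 0 and 5
  expect_equal(quantize_fv(c(0, 7.4, 7.6, 94.9, 95)),
               c(0, 5, 10, 90, 90))
  expect_error(quantize_fv(101), "\\[0, 100\\]")
  # idempotent on the level set
  expect_equal(quantize_fv(fv_levels()), fv_levels())
})

test_that("an unoccluded fruit is fully visible and a covered one invisible", {
  sc <- bare_scene()
  pose <- camera_pose(90, 90, 0, target = c(0, 0, 1), range_m = 0.5)
  expect_equal(fruit_visibility(sc, pose, 1, n_rays = 500, seed = 1), 100)

  covered <- add_disc(sc, centre = c(0, -0.25, 1), normal = c(0, 1, 0),
                      axis1 = c(1, 0, 0), semi_a = 0.5, semi_b = 0.5)
  expect_equal(fruit_visibility(covered, pose, 1, n_rays = 500, seed = 1), 0)
})

test_that("a half-covering occluder leaves about half the projected area", {
  sc <- bare_scene()
  pose <- camera_pose(90, 90, 0, target = c(0, 0, 1), range_m = 0.5)
  # huge disc in the plane y = -0.25 whose edge passes through the projected
  # fruit centre: blocks (essentially) the lower half of the projected disc
  half <- add_disc(sc, centre = c(0, -0.25, 1 - 10), normal = c(0, 1, 0),
                   axis1 = c(1, 0, 0), semi_a = 10, semi_b = 10)
  hits <- vapply(1:5, function(s)
    fruit_visibility(half, pose, 1, n_rays = 10000, seed = s), numeric(1))
  expect_true(all(abs(hits - 50) <= 2))
})

test_that("visibility is monotone in the occluder set", {
  sc <- generate_scene(scene_params(n_plants = 2, leaf_density = 20,
                                    leaf_up_bias = 0.3), seed = 5)
  pose <- camera_pose(90, 90, 0,
                      target = c(sc$targets$x[1], 0, sc$targets$z[1]))
  full <- fruit_visibility(sc, pose, 1, n_rays = 400, seed = 9)
  fewer <- sc
  fewer$leaves <- fewer$leaves[seq_len(nrow(fewer$leaves) %/% 2), ,
                               drop = FALSE]
  expect_gte(fruit_visibility(fewer, pose, 1, n_rays = 400, seed = 9), full)
  # other fruit spheres also occlude; with them and the leaves gone the
  # fruit must be fully visible
  none <- sc
  none$leaves <- none$leaves[0, , drop = FALSE]
  none$fruits <- none$fruits[1, , drop = FALSE]
  expect_equal(fruit_visibility(none, pose, 1, n_rays = 400, seed = 9), 100)
})

test_that("visibility is invariant under rigid translation along the row", {
  sc <- generate_scene(scene_params(n_plants = 2, leaf_density = 15),
                       seed = 3)
  pose <- camera_pose(90, 70, 0,
                      target = c(sc$targets$x[1], 0, sc$targets$z[1]))
  fv0 <- fruit_visibility(sc, pose, 1, n_rays = 300, seed = 4)
  shift <- 0.37
  sc2 <- sc
  sc2$fruits$x <- sc2$fruits$x + shift
  sc2$leaves$cx <- sc2$leaves$cx + shift
  pose2 <- camera_pose(90, 70, 0,
                       target = c(sc$targets$x[1] + shift, 0,
                                  sc$targets$z[1]))
  expect_equal(fruit_visibility(sc2, pose2, 1, n_rays = 300, seed = 4), fv0,
               tolerance = 1e-12)
})

test_that("a camera inside the fruit or another fruit is rejected", {
  sc <- bare_scene()
  inside <- camera_pose(90, 90, 0, target = c(0, 0, 1), range_m = 0.01)
  expect_error(fruit_visibility(sc, inside, 1, n_rays = 200), "inside")
})
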