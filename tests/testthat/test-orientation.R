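test_that("active-zone frames enforce orthogonality", {
  f <- az_frame(head = c(1, 0, 0), tail = c(0, 0, 1))
  expect_equal(f$long_axis, c(0, 1, 0) * -1 * -1, tolerance = 1e-12)
  expect_error(az_frame(head = c(1, 0, 0.2), tail = c(0, 0, 1)), "orthogonal")
})

# a minimal model stub: only transforms and members are needed for arrows
stub_model <- function(rotations) {
  structure(list(members = seq_along(rotations),
                 transforms = lapply(rotations, function(R)
                   rigid_transform(R, c(24, 24, 24)))),
            class = "alignment_model")
}

test_that("the reference vesicle's arrow equals the frame construction", {
  m <- stub_model(list(diag(3), diag(3)))
  frames <- list(az_frame(), az_frame())
  arr <- orientation_arrows(m, frames, reference_id = 1)
  expect_equal(c(arr$shaft_x[1], arr$shaft_y[1], arr$shaft_z[1]), c(1, 0, 0),
               tolerance = 1e-9)
  expect_equal(c(arr$tail_x[1], arr$tail_y[1], arr$tail_z[1]), c(0, 0, 1),
               tolerance = 1e-9)
  # a member whose registration equals the reference gets the same arrow
  expect_equal(arr$shaft_angle[2], 0, tolerance = 1e-9)
  expect_equal(arr$tail_angle[2], 0, tolerance = 1e-9)
})

test_that("a member rotated about the vertical rotates its shaft, not tail", {
  # member 2's assembly is rotated 90 degrees about z relative to member 1:
  # its registration into the model carries the inverse rotation
  m <- stub_model(list(diag(3), t(euler_rot(0, 0, 90))))
  frames <- list(az_frame(), az_frame())
  arr <- orientation_arrows(m, frames, reference_id = 1)
  expect_equal(arr$shaft_angle[2], 90, tolerance = 1e-6)
  expect_equal(arr$tail_angle[2], 0, tolerance = 1e-6)
  expect_error(orientation_arrows(m, frames, reference_id = 9), "lookup error")
})

test_that("arrow construction is equivariant under a global rotation", {
  # rotating the whole scene (member poses AND active-zone frames) by G
  # leaves every frame-relative arrow unchanged
  set.seed(8)
  Rs <- rand_rotation(4)
  m1 <- stub_model(Rs)
  G <- euler_rot(20, -10, 35)
  m2 <- stub_model(lapply(Rs, function(R) R %*% t(G)))
  frames1 <- replicate(4, az_frame(), simplify = FALSE)
  frames2 <- replicate(4, az_frame(head = as.numeric(G %*% c(1, 0, 0)),
                                   tail = as.numeric(G %*% c(0, 0, 1))),
                       simplify = FALSE)
  a1 <- orientation_arrows(m1, frames1, 1)
  a2 <- orientation_arrows(m2, frames2, 1)
  expect_equal(a1$shaft_angle, a2$shaft_angle, tolerance = 1e-6)
  expect_equal(a1$tail_angle, a2$tail_angle, tolerance = 1e-6)
  expect_equal(a1[, c("shaft_x", "shaft_y", "shaft_z")],
               a2[, c("shaft_x", "shaft_y", "shaft_z")], tolerance = 1e-6)
})

test_that("orientation classification applies the double-cone criterion", {
  ref <- list(shaft = c(1, 0, 0), tail = c(0, 0, 1))
  same <- classify_orientation(ref, ref)
  expect_true(same$oriented)
  expect_equal(same$shaft_angle, 0)
  rot45 <- list(shaft = as.numeric(euler_rot(0, 0, 45) %*% c(1, 0, 0)),
                tail = c(0, 0, 1))
  expect_false(classify_orientation(rot45, ref)$oriented)
  # symmetric in its arguments
  r1 <- classify_orientation(rot45, ref)
  r2 <- classify_orientation(ref, rot45)
  expect_equal(r1$oriented, r2$oriented)
  expect_equal(r1$shaft_angle, r2$shaft_angle)
  # missing tail: partial classification on the shaft alone
  part <- classify_orientation(list(shaft = c(1, 0, 0), tail = c(NA, NA, NA)),
                               ref)
  expect_true(part$partial)
  expect_true(part$oriented)
})

test_that("docked members classify as oriented; Haar rotations match the
           Monte-Carlo expectation of the criterion", {
  # docked: small registration noise stays inside the 30-degree cones
  set.seed(12)
  jit <- lapply(1:6, function(i) euler_rot(rnorm(1, 0, 4), rnorm(1, 0, 4),
                                           rnorm(1, 0, 4)))
  m <- stub_model(c(list(diag(3)), jit))
  frames <- replicate(7, az_frame(), simplify = FALSE)
  arr <- classify_orientations(orientation_arrows(m, frames, 1))
  expect_true(all(arr$oriented))
  # Haar-random poses: pipeline fraction vs direct Monte-Carlo of the test
  set.seed(13)
  Rs <- rand_rotation(200)
  m2 <- stub_model(c(list(diag(3)), lapply(Rs, t)))
  frames2 <- replicate(201, az_frame(), simplify = FALSE)
  arr2 <- classify_orientations(orientation_arrows(m2, frames2, 1))
  frac_pipeline <- mean(arr2$oriented[-1])
  set.seed(14)
  oracle <- mean(vapply(rand_rotation(4000), function(R) {
    vec_ang <- function(a, b) acos(pmin(1, pmax(-1, sum(a * b)))) * 180 / pi
    vec_ang(R %*% c(1, 0, 0), c(1, 0, 0)) <= 30 &&
      vec_ang(R %*% c(0, 0, 1), c(0, 0, 1)) <= 30
  }, logical(1)))
  se <- sqrt(oracle * (1 - oracle) / 200)
  expect_lt(abs(frac_pipeline - oracle), 3 * se + 0.01)
})

test_that("overlay orientation flags a sphere as low confidence", {
  # orientation-free shape: a spherical shell of points
  set.seed(3)
  sph <- matrix(rnorm(3000), ncol = 3)
  sph <- sph / sqrt(rowSums(sph^2)) * 12
  d <- 48
  grid <- array(0, rep(d, 3))
  gi <- floor(sph + d / 2) + 1
  grid[gi] <- 620
  idx <- which(grid > 0)
  ijk <- cbind((idx - 1) %% d, ((idx - 1) %/% d) %% d,
               (idx - 1) %/% (d * d)) + 0.5
  rep_sph <- structure(list(id = NULL, points = sweep(ijk, 2, rep(d / 2, 3)),
                            weights = rep(620, length(idx)), grid = grid,
                            side = d, centroid = rep(d / 2, 3), voxel_size = 1,
                            mesh = sph),
                       class = "assembly_rep")
  model <- structure(list(method = "density", density = grid,
                          region = grid > 0, threshold = 100, voxel_size = 1,
                          side = d), class = "alignment_model")
  r <- orient_by_overlay(rep_sph, model, start_grid_step = 60)
  expect_true(attr(r, "low_confidence"))
})
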