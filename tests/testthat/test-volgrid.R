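test_that("virtual slices are exact on constants and linear in thickness", {
  v <- vox_volume(array(400, dim = c(12, 12, 12)))
  expect_true(all(virtual_slice(v, "z", 5) == 400))
  ramp <- vox_volume(array(rep(seq(0, 110, by = 10), each = 144),
                           dim = c(12, 12, 12)))
  s3 <- virtual_slice(ramp, "z", 4, thickness = 3)
  s_each <- (virtual_slice(ramp, "z", 4) + virtual_slice(ramp, "z", 5) +
               virtual_slice(ramp, "z", 6)) / 3
  expect_equal(s3, s_each)
  expect_error(virtual_slice(v, "z", 13), "range")
})

test_that("an oblique slice through a sphere shows the analytic chord circle", {
  d <- 30
  ball <- ball_volume(d, pad = 8)
  ctr <- dim(ball$data)[1] / 2 * ball$voxel_size  # center (nm, all axes)
  offset <- 5
  n <- unit(c(1, 1, 0))
  img <- virtual_slice(ball, list(point = rep(ctr, 3) + offset * n, normal = n))
  # expected cross-section radius at distance `offset` from center
  r_expect <- sqrt((d / 2)^2 - offset^2)
  area <- sum(img < 500) * ball$voxel_size^2
  r_meas <- sqrt(area / pi)
  expect_lt(abs(r_meas - r_expect), 1)
})

test_that("segment_voi recovers a noise-free structure with a 1-voxel shell", {
  sc <- clean_scene()
  truth <- sc$truth
  m <- truth$masks[[1]]
  crop <- crop_volume(sc$volume, truth, 1)
  lum <- logical(prod(m$dims)); lum[m$lumen] <- TRUE
  voi <- segment_voi(crop, array(lum, m$dims),
                     list(method = "fixed", value = 500), label = "assembly")
  # support equals the rendered assembly exactly; mask adds <= 1-voxel shell
  expect_setequal(voi$support, m$assembly)
  expect_true(all(m$assembly %in% voi$mask))
  shell <- setdiff(voi$mask, voi$support)
  sup <- logical(prod(m$dims)); sup[voi$support] <- TRUE
  dil <- lumenmap:::cpp_dilate26(sup, m$dims)
  expect_true(all(shell %in% which(dil)))
})

test_that("segment_voi errors on background-only bounds and is monotone", {
  sc <- clean_scene()
  crop <- crop_volume(sc$volume, sc$truth, 1)
  hi <- dim(crop$data)
  expect_error(segment_voi(crop, list(lo = hi - 5, hi = hi)),
               "segmentation error")
  m <- sc$truth$masks[[1]]
  lum <- logical(prod(m$dims)); lum[m$lumen] <- TRUE
  v1 <- segment_voi(crop, array(lum, m$dims), list(method = "fixed", value = 450))
  v2 <- segment_voi(crop, array(lum, m$dims), list(method = "fixed", value = 550))
  expect_true(all(v1$support %in% v2$support))
})

test_that("segmented assembly voxel count tracks ground truth within 15%", {
  sc <- small_scene()
  s <- segment_vesicle(sc$volume, sc$truth, 1)
  n_true <- length(sc$truth$masks[[1]]$assembly)
  expect_lt(abs(length(s$assembly$support) - n_true) / n_true, 0.15)
})

test_that("isodensity surface of a sphere has the analytic area", {
  d <- 51.3
  ball <- ball_volume(d)
  voi <- segment_voi(ball, list(lo = c(1, 1, 1), hi = dim(ball$data)),
                     list(method = "fixed", value = 500))
  sm <- extract_surface(ball, voi, closed = TRUE)
  expect_true(surface_is_closed(sm))
  expect_lt(abs(surface_area(sm) - pi * d^2) / (pi * d^2), 0.03)
})

test_that("surface extraction fails cleanly when no surface exists", {
  ball <- ball_volume(20, pad = 4)
  voi <- segment_voi(ball, list(lo = c(1, 1, 1), hi = dim(ball$data)),
                     list(method = "fixed", value = 500))
  flat <- vox_volume(array(600, dim = dim(ball$data)))
  expect_error(extract_surface(flat, voi, closed = TRUE), "extraction error")
})

test_that("membrane surface vertices sit within a voxel of the true radii", {
  sc <- clean_scene()
  s <- segment_vesicle(sc$volume, sc$truth, 1)
  sm <- extract_surface(s$crop, s$membrane)
  ves <- sc$truth$vesicles[1, ]
  ctr <- c(ves$cx, ves$cy, ves$cz)
  r <- sqrt(rowSums(sweep(sm$vertices, 2, ctr)^2))
  dev <- pmin(abs(r - ves$d_outer / 2), abs(r - ves$d_luminal / 2))
  # the bulk of the surface tracks the two radii; the remainder wraps the
  # attachment sites of nubs, bands and outer macromolecules
  expect_gt(mean(dev <= 1), 0.90)
  expect_lt(median(dev), 0.5)
})

test_that("surface area estimates are stable under voxel-size doubling", {
  d <- 36
  a1 <- surface_area(extract_surface(
    ball_volume(d, voxel_size = 0.6),
    segment_voi(ball_volume(d, voxel_size = 0.6),
                list(lo = c(1, 1, 1), hi = dim(ball_volume(d, voxel_size = 0.6)$data)),
                list(method = "fixed", value = 500)), closed = TRUE))
  a2 <- surface_area(extract_surface(
    ball_volume(d, voxel_size = 1.2),
    segment_voi(ball_volume(d, voxel_size = 1.2),
                list(lo = c(1, 1, 1), hi = dim(ball_volume(d, voxel_size = 1.2)$data)),
                list(method = "fixed", value = 500)), closed = TRUE))
  expect_lt(abs(a1 - a2) / a1, 0.05)
})
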