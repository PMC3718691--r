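test_that("five-axis diameters recover a perfect shell phantom", {
  vol <- shell_volume(51.3, 35.7)
  voi <- segment_voi(vol, list(lo = c(1, 1, 1), hi = dim(vol$data)),
                     list(method = "fixed", value = 500), label = "membrane")
  dia <- vesicle_diameters(vol, voi)
  expect_gte(dia$d_outer, 50.3)
  expect_lte(dia$d_outer, 52.3)
  expect_lt(abs(dia$d_luminal - 35.7), 1)
})

test_that("an ellipsoid reports the average of its axis diameters", {
  a <- c(25, 25, 27)  # semi-axes: 50/50/54 diameters
  side <- 70
  ax <- (seq_len(side) - 0.5 - side / 2)
  q <- outer(outer((ax / a[1])^2, (ax / a[2])^2, "+"), (ax / a[3])^2, "+")
  qin <- outer(outer((ax / (a[1] - 7))^2, (ax / (a[2] - 7))^2, "+"),
               (ax / (a[3] - 7))^2, "+")
  g <- array(600, dim = rep(side, 3))
  g[q <= 1 & qin >= 1] <- 450
  vol <- vox_volume(g)
  voi <- segment_voi(vol, list(lo = c(1, 1, 1), hi = rep(side, 3)),
                     list(method = "fixed", value = 500), label = "membrane")
  dia <- vesicle_diameters(vol, voi)
  expect_gt(dia$d_outer, 50)
  expect_lt(dia$d_outer, 54)
  expect_equal(dia$d_outer, mean(dia$per_axis_outer))
})

test_that("luminal diameters of default-noise phantoms are accurate", {
  sc <- small_scene()
  errs <- vapply(1:3, function(v) {
    s <- segment_vesicle(sc$volume, sc$truth, v)
    s$diameters$d_luminal - sc$truth$vesicles$d_luminal[v]
  }, numeric(1))
  expect_lt(max(abs(errs)), 1.5)
})

test_that("sphere and spherical-zone areas follow the closed forms", {
  ar <- sphere_and_zone_areas(51.3, 35.3)
  expect_equal(ar$SA_SV, pi * 51.3^2, tolerance = 1e-12)
  expect_equal(ar$SA_SV, 8267.5, tolerance = 1e-4)
  expect_equal(ar$zone_fraction, 0.137, tolerance = 0.005)
  # hemisphere: base chord equal to the diameter
  expect_equal(sphere_and_zone_areas(51.3, 51.3)$zone_fraction, 0.5,
               tolerance = 1e-12)
  expect_error(sphere_and_zone_areas(51.3, 60), "domain error")
})

test_that("areas are monotone in their arguments", {
  d <- seq(30, 60, by = 5)
  expect_true(all(diff(sphere_and_zone_areas(d, 20)$SA_SV) > 0))
  z <- sphere_and_zone_areas(51.3, seq(10, 50, by = 5))$zone_fraction
  expect_true(all(diff(z) > 0))
})

test_that("cap areas agree with Monte-Carlo sphere sampling", {
  set.seed(7)
  for (i in 1:10) {
    d_sv <- runif(1, 40, 60)
    d_azm <- runif(1, 0.3, 0.95) * d_sv
    zf <- sphere_and_zone_areas(d_sv, d_azm)$zone_fraction
    # sample points uniformly on the sphere; the zone is a cap whose base
    # circle has chord diameter d_azm, i.e. polar angle asin(d_azm / d_sv)
    u <- matrix(rnorm(3e5), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    cap <- mean(u[, 3] > cos(asin(d_azm / d_sv)))
    expect_lt(abs(zf - cap), 0.005)
  }
})

test_that("lumen fill fraction handles the limit cases", {
  dims <- c(10, 10, 10)
  lum <- voi("lumen", 1:500, dims)
  expect_error(lumen_fill_fraction(voi("lumen", integer(), dims), lum),
               "empty")
  expect_equal(lumen_fill_fraction(lum, lum), 1)
  sub <- voi("assembly", 1:50, dims)
  expect_equal(lumen_fill_fraction(lum, sub), 0.1)
  # clipping is reported, not fatal
  over <- voi("assembly", 490:520, dims)
  expect_message(f <- lumen_fill_fraction(lum, over), "clipped")
  expect_equal(f, 11 / 500)
})

test_that("per-vesicle fill fractions reproduce the narrow observed range", {
  sc <- synthesize_scene(scene_params(n_docked = 6, n_undocked = 0), seed = 31)
  fills <- vapply(1:6, function(v)
    segment_vesicle(sc$volume, sc$truth, v)$fill, numeric(1))
  expect_true(all(fills > 0.085 & fills < 0.115))
  expect_lt(abs(mean(fills) - 0.10), 0.01)
})
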