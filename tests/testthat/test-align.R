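# Small synthetic assembly representations, built directly from the
# template rasterization (no scene rendering), keep these tests fast.

tpl_rep <- function(rotate = diag(3), side = 48, jiggle = 0) {
  tpl <- cached("tpl_seed7", make_assembly_template(scene_params(), seed = 7))
  caps <- lumenmap:::assembly_capsules(tpl, jitter_arm = jiggle)
  seg <- rbind(caps$arms, caps$nubs)
  seg[, 1:3] <- seg[, 1:3, drop = FALSE] %*% t(rotate)
  seg[, 4:6] <- seg[, 4:6, drop = FALSE] %*% t(rotate)
  ras <- lumenmap:::rasterize_capsules(seg, tpl$r_lum, 1)
  idx <- which(ras$mask)
  d <- rep(ras$side, 3)
  ijk <- cbind((idx - 1) %% d[1], ((idx - 1) %/% d[1]) %% d[2],
               (idx - 1) %/% (d[1] * d[2])) + 0.5
  ctr <- colMeans(ijk)
  P <- sweep(ijk, 2, ctr)
  grid <- array(0, rep(side, 3))
  gi <- floor(P + side / 2) + 1
  keep <- apply(gi >= 1 & gi <= side, 1, all)
  grid[gi[keep, , drop = FALSE]] <- 620
  structure(list(id = NULL, points = P, weights = rep(620, nrow(P)),
                 grid = grid, side = side, centroid = ctr, voxel_size = 1,
                 mesh = NULL),
            class = "assembly_rep")
}

test_that("density alignment of a volume with itself is the identity", {
  a <- tpl_rep()
  r <- density_align(a, a)
  expect_true(r$converged)
  expect_lt(rot_angle(r$transform$R), 1e-9)
  expect_equal(r$transform$t, rep(24, 3))
  # the identity placement scores at least as high as any perturbation
  full <- lumenmap:::member_density_score(a, a$grid, r$transform)
  bumped <- lumenmap:::member_density_score(
    a, a$grid, rigid_transform(euler_rot(0, 0, 4), r$transform$t))
  expect_gte(full, bumped)
})

test_that("density alignment recovers a known rotation within a degree", {
  a <- tpl_rep()
  b <- tpl_rep(rotate = euler_rot(10, 0, 0))
  # align b onto a: expect the inverse rotation
  r <- density_align(b, a)
  expect_true(r$converged)
  err <- rot_angle(r$transform$R %*% euler_rot(10, 0, 0))
  expect_lt(err, 1.5)
})

test_that("initialization within the basin recovers; far outside does not", {
  a <- tpl_rep()
  b <- tpl_rep(rotate = euler_rot(0, 0, 25))
  r_good <- density_align(b, a)  # 25 degrees off identity, inside +/-30
  expect_lt(rot_angle(r_good$transform$R %*% euler_rot(0, 0, 25)), 1.5)
  c45 <- tpl_rep(rotate = euler_rot(0, 0, 45))
  r_bad <- density_align(c45, a)  # outside the local search window
  expect_false(r_bad$converged)
})

test_that("density score is invariant under a lattice rotation of both inputs", {
  a <- tpl_rep()
  R90 <- euler_rot(0, 0, 90)
  side <- a$side
  # rotate the fixed grid by 90 degrees about z on the lattice
  g2 <- array(0, dim = rep(side, 3))
  for (k in seq_len(side)) g2[, , k] <- t(a$grid[, , k])[side:1, ]
  ctr <- rep(side / 2, 3)
  tf <- rigid_transform(diag(3), ctr)
  s1 <- lumenmap:::member_density_score(a, a$grid, tf)
  a2 <- a
  a2$points <- a$points %*% t(R90)
  s2 <- lumenmap:::member_density_score(a2, g2, tf)
  expect_equal(s1, s2)
})

test_that("ICP recovers a pure translation to sub-voxel accuracy", {
  set.seed(5)
  sph <- matrix(rnorm(900), ncol = 3)
  sph <- sph / sqrt(rowSums(sph^2)) * 10
  sph <- sph * matrix(c(1, 1.4, 0.7), nrow(sph), 3, byrow = TRUE)  # ellipsoid
  moved <- sweep(sph, 2, c(2, 0, 0), "+")
  r <- icp_align(sph, moved, init = rigid_transform(diag(3), c(0, 0, 0)))
  expect_lt(max(abs(r$transform$t - c(2, 0, 0))), 0.1)
  expect_lt(r$score, 0.2)
})

test_that("multi-start ICP escapes a large rotation that traps a single start", {
  a <- tpl_rep()
  caps_pts <- a$points
  R140 <- euler_rot(0, 0, 140)
  b_pts <- caps_pts %*% t(R140)
  single <- icp_align(b_pts, caps_pts,
                      init = rigid_transform(diag(3), c(0, 0, 0)))
  multi <- icp_align(b_pts, caps_pts, start_grid_step = 20)
  err_multi <- rot_angle(multi$transform$R %*% R140)
  expect_lt(err_multi, 2)
  expect_gt(rot_angle(single$transform$R %*% R140), 10)
})

test_that("ICP on unrelated clouds converges with a large residual", {
  set.seed(9)
  A <- matrix(rnorm(450, sd = 8), ncol = 3)
  B <- matrix(rnorm(450, sd = 8), ncol = 3) + 30
  r <- icp_align(A, B, start_grid_step = 90)
  expect_true(r$converged)
  expect_gt(r$score, 1)
})

test_that("degenerate vertex sets are rejected", {
  flat <- cbind(matrix(rnorm(200), ncol = 2), 0)
  good <- matrix(rnorm(300), ncol = 3)
  expect_error(icp_align(flat, good), "degenerate")
})

test_that("a model from identical copies reproduces the single assembly", {
  a <- tpl_rep()
  copies <- lapply(1:5, function(i) { a$id <- i; a })
  m <- build_alignment_model(copies, "density", "given", rounds = 2)
  v_single <- nrow(a$points)
  expect_lt(abs(model_volume(m) - v_single) / v_single, 0.02)
  for (tf in m$transforms) expect_lt(rot_angle(tf$R), 1e-9)
  cont <- containment_fraction(a, m, m$transforms[[1]])
  expect_gt(cont, 0.97)
})

test_that("refinement is non-divergent on a jittered cohort", {
  set.seed(31)
  members <- lapply(1:4, function(i) {
    r <- tpl_rep(jiggle = 1.5)
    r$id <- i
    r
  })
  m <- build_alignment_model(members, "density", "given", rounds = 3)
  tr <- m$score_trace
  expect_true(all(diff(tr) > -1e-6 * abs(tr[1])))
})

test_that("model overlap is exact for identity and nested regions", {
  a <- tpl_rep()
  copies <- lapply(1:3, function(i) { a$id <- i; a })
  m <- build_alignment_model(copies, "density", "given", rounds = 1)
  self <- model_overlap(m, m)
  expect_equal(unname(self), c(1, 1), tolerance = 1e-6)
  # nested spheres of radius r and 2r
  mk_ball_model <- function(r, side = 64) {
    ax <- seq_len(side) - 0.5 - side / 2
    r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
    structure(list(method = "surface", region = r2 <= r^2, threshold = 0.5,
                   voxel_size = 1), class = "alignment_model")
  }
  o <- model_overlap(mk_ball_model(10), mk_ball_model(20))
  expect_equal(unname(o[1]), 1, tolerance = 0.02)
  expect_equal(unname(o[2]), 0.125, tolerance = 0.02)
})

test_that("containment handles the zero and full cases", {
  a <- tpl_rep()
  empty <- structure(list(method = "surface",
                          region = array(FALSE, rep(48, 3)), threshold = 0.5,
                          voxel_size = 1), class = "alignment_model")
  expect_equal(containment_fraction(a, empty,
                                    rigid_transform(diag(3), rep(24, 3))), 0)
  full <- empty; full$region <- array(TRUE, rep(48, 3))
  expect_equal(containment_fraction(a, full,
                                    rigid_transform(diag(3), rep(24, 3))), 1)
})
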