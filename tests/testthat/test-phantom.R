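test_that("template generation is deterministic and hits the fill target", {
  p <- scene_params()
  t1 <- make_assembly_template(p, seed = 7)
  t2 <- make_assembly_template(p, seed = 7)
  expect_identical(t1$arms, t2$arms)
  expect_identical(t1$nubs, t2$nubs)
  fill <- template_fill_fraction(t1)
  expect_gte(fill, 0.09)
  expect_lte(fill, 0.11)
})

test_that("template satisfies its structural invariants", {
  tpl <- make_assembly_template(scene_params(), seed = 7)
  expect_length(tpl$arms, 4)
  # focal point below (toward fusion domain) and behind (away from the AZM)
  expect_lt(tpl$focal[3], 0)
  expect_lt(tpl$focal[1], 0)
  # one arm tip per quadrant seen from the median plane (y-z signs)
  tips <- t(vapply(tpl$arms, function(a) a$ctrl[nrow(a$ctrl), ], numeric(3)))
  quad <- paste(sign(tips[, 2]), sign(tips[, 3]))
  expect_setequal(quad, c("1 1", "-1 1", "1 -1", "-1 -1"))
  # arms facing the fusion domain are shorter
  len <- vapply(tpl$arms, function(a)
    sum(sqrt(rowSums(diff(a$ctrl)^2))), numeric(1))
  expect_lt(max(len[tips[, 3] < 0]), min(len[tips[, 3] > 0]))
})

test_that("the assembly is chiral: its mirror image cannot be rotated back", {
  tpl <- make_assembly_template(scene_params(), seed = 7)
  ras <- function(t) {
    caps <- lumenmap:::assembly_capsules(t)
    lumenmap:::rasterize_capsules(rbind(caps$arms, caps$nubs), t$r_lum, 1)$mask
  }
  A <- ras(tpl)
  M <- ras(mirror_template(tpl))
  self_score <- lumenmap:::best_rotation_overlap(A, A, step = 10)
  mirror_score <- lumenmap:::best_rotation_overlap(M, A, step = 10)
  expect_lt(mirror_score, 0.97 * self_score)
})

test_that("scene synthesis is deterministic and structurally consistent", {
  sc1 <- small_scene()
  sc2 <- synthesize_scene(scene_params(n_docked = 3, n_undocked = 1), seed = 7)
  expect_identical(sc1$volume$data, sc2$volume$data)
  expect_identical(sc1$truth$sites, sc2$truth$sites)
  truth <- sc1$truth
  expect_equal(nrow(truth$vesicles), 4)
  expect_equal(sum(truth$vesicles$docked), 3)
  # docked vesicles share the template orientation exactly
  for (v in which(truth$vesicles$docked))
    expect_equal(truth$vesicles$pose[[v]], diag(3))
  # undocked pose is a proper rotation
  Ru <- truth$vesicles$pose[[4]]
  expect_equal(crossprod(Ru), diag(3), tolerance = 1e-9)
  expect_equal(det(Ru), 1, tolerance = 1e-9)
})

test_that("every paired site links to exactly one partner, both directions", {
  truth <- small_scene()$truth
  st <- truth$sites
  paired <- st[!is.na(st$pair_id), ]
  expect_true(all(table(paired$pair_id) == 1))
  # symmetry of the link
  back <- st$pair_id[match(paired$pair_id, st$site_id)]
  expect_equal(back, paired$site_id)
  # nubs on the luminal surface only, other classes outer only
  expect_true(all(st$surface[st$class == "nub"] == "luminal"))
  expect_true(all(st$surface[st$class != "nub"] == "outer"))
})

test_that("zero pairing dropout pairs every nub", {
  p <- scene_params(n_docked = 2, n_undocked = 0, pairing_dropout_prob = 0)
  truth <- synthesize_scene(p, seed = 3)$truth
  nubs <- truth$sites[truth$sites$class == "nub", ]
  expect_true(all(!is.na(nubs$pair_id)))
})

test_that("no nub site falls in the fusion domain", {
  truth <- small_scene()$truth
  theta_f <- acos(1 - 2 * truth$params$fusion_domain_area_fraction) * 180 / pi
  for (v in which(truth$vesicles$docked)) {
    st <- truth$sites[truth$sites$vesicle_id == v &
                        truth$sites$class == "nub", ]
    # angle between the site direction and the downward vertical
    ang <- acos(pmin(1, pmax(-1, -st$uz))) * 180 / pi
    expect_true(all(ang > theta_f))
  }
})

test_that("per-class outer counts match their generating distributions", {
  p <- scene_params(n_docked = 11, n_undocked = 0)
  truth <- synthesize_scene(p, seed = 5)$truth
  st <- truth$sites[truth$sites$surface == "outer", ]
  rib_mean <- mean(table(factor(st$vesicle_id[st$class == "rib"], levels = 1:11)))
  expect_gte(rib_mean, 3.8)
  expect_lte(rib_mean, 4.6)
})

test_that("site centroids lie within 1 voxel of their mask terminal voxels", {
  sc <- small_scene()
  truth <- sc$truth
  v <- 1
  m <- truth$masks[[v]]
  lo <- truth$vesicles$crop_lo[[v]]
  for (id in names(m$nubs)[1:6]) {
    site <- truth$sites[truth$sites$site_id == as.integer(id), ]
    idx <- m$nubs[[id]]
    d <- m$dims
    ijk <- cbind((idx - 1) %% d[1], ((idx - 1) %/% d[1]) %% d[2],
                 (idx - 1) %/% (d[1] * d[2])) + 0.5
    pts <- sweep(ijk * truth$voxel_size, 2,
                 -(truth$origin + lo * truth$voxel_size))
    dmin <- sqrt(min(rowSums(sweep(pts, 2,
      c(site$x_nm, site$y_nm, site$z_nm))^2)))
    expect_lt(dmin, 1.0 * truth$voxel_size + 1e-9)
  }
})

test_that("undocked poses follow the uniform-rotation angle distribution", {
  set.seed(99)
  angles <- vapply(rand_rotation(200), rot_angle, numeric(1))
  expect_lt(abs(mean(angles) - haar_mean_angle()), 5)
})

test_that("rendering: noise-free volumes equal the class target means", {
  sc <- clean_scene()
  truth <- sc$truth
  st <- truth$params$stain
  m <- truth$masks[[1]]
  lo <- truth$vesicles$crop_lo[[1]]
  vol <- sc$volume$data
  sh <- function(idx) lumenmap:::crop_to_scene(idx, m$dims, lo, dim(vol))
  asm <- sh(m$assembly)
  expect_true(all(vol[asm] == st$assembly))
  mem <- setdiff(sh(m$membrane), sh(sort(unique(unlist(m$bands)))))
  expect_true(all(vol[mem] == st$membrane))
})

test_that("rendering orders mean grays: background > membrane > assembly", {
  sc <- small_scene()
  truth <- sc$truth
  m <- truth$masks[[1]]
  lo <- truth$vesicles$crop_lo[[1]]
  vol <- sc$volume$data
  sh <- function(idx) lumenmap:::crop_to_scene(idx, m$dims, lo, dim(vol))
  g_asm <- mean(vol[sh(m$assembly)])
  g_mem <- mean(vol[sh(m$membrane)])
  bg_idx <- setdiff(seq_len(1000) * 311, sh(sort(unique(unlist(m)))))
  g_bg <- mean(vol[bg_idx[bg_idx <= length(vol)]])
  expect_gt(g_bg, g_mem)
  expect_gt(g_mem, g_asm)
})

test_that("stain rendering is deterministic under a fixed seed", {
  truth <- small_scene()$truth
  v1 <- render_stain(truth, seed = 12)
  v2 <- render_stain(truth, seed = 12)
  expect_identical(v1$data, v2$data)
})

test_that("empirical fill fraction tracks the target over a cohort", {
  fills <- c(
    vapply(small_scene()$truth$masks,
           function(m) length(m$assembly) / length(m$lumen), numeric(1)),
    vapply(synthesize_scene(scene_params(n_docked = 6, n_undocked = 0),
                            seed = 21)$truth$masks,
           function(m) length(m$assembly) / length(m$lumen), numeric(1)))
  expect_lt(abs(mean(fills) - 0.10), 0.015)
})

test_that("infeasible fill targets raise a parameter error", {
  expect_error(scene_params(fill_fraction_target = 0.9), "fill_fraction_target")
  p <- scene_params()
  p$fill_fraction_target <- 0.45
  expect_error(make_assembly_template(p, seed = 1), "parameter error")
})
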