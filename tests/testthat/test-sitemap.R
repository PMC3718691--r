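# site extraction, pairing, bands, projections, composite maps, distances

test_that("connection sites are extracted at the ground-truth anchors", {
  sc <- clean_scene()
  truth <- sc$truth
  v <- 1
  s <- segment_vesicle(sc$volume, truth, v)
  m <- truth$masks[[v]]
  ids <- names(m$nubs)
  vois <- lapply(ids, function(id) truth_voi(truth, v, "nubs", id))
  st <- extract_sites(vois, rep("nub", length(ids)),
                      rep("luminal", length(ids)), s$membrane, s$crop,
                      vesicle_id = v, site_ids = as.integer(ids))
  expect_equal(nrow(st), length(ids))
  cat_sites <- truth$sites[match(st$site_id, truth$sites$site_id), ]
  err <- sqrt((st$x_nm - cat_sites$x_nm)^2 + (st$y_nm - cat_sites$y_nm)^2 +
                (st$z_nm - cat_sites$z_nm)^2)
  expect_lt(max(err), 1.5 * truth$voxel_size)
})

test_that("macromolecule VOIs away from the membrane emit warnings, not sites", {
  sc <- clean_scene()
  s <- segment_vesicle(sc$volume, sc$truth, 1)
  d <- s$membrane$dims
  # a blob at the crop corner, far from the membrane
  blob <- voi("stray", c(1, 2, d[1] + 1), d, composite = TRUE)
  expect_warning(
    st <- extract_sites(list(blob), "nonAZM", "outer", s$membrane, s$crop),
    "does not reach")
  expect_equal(nrow(st), 0)
})

test_that("detected nub counts track the generating distribution", {
  sc <- small_scene()
  truth <- sc$truth
  counts <- vapply(which(truth$vesicles$docked), function(v)
    length(truth$masks[[v]]$nubs), numeric(1))
  expect_true(all(counts >= 10 & counts <= 40))
})

test_that("exactly antipodal sites pair perfectly at zero offset", {
  set.seed(2)
  U <- matrix(rnorm(36), ncol = 3)
  U <- U / sqrt(rowSums(U^2))
  ctr <- c(50, 50, 50)
  nub <- tibble::tibble(site_id = 1:12, class = "nub", surface = "luminal",
                        x_nm = ctr[1] + 17 * U[, 1],
                        y_nm = ctr[2] + 17 * U[, 2],
                        z_nm = ctr[3] + 17 * U[, 3])
  out <- tibble::tibble(site_id = 101:112, class = "rib", surface = "outer",
                        x_nm = ctr[1] + 25 * U[, 1],
                        y_nm = ctr[2] + 25 * U[, 2],
                        z_nm = ctr[3] + 25 * U[, 3])
  pr <- pair_sites(nub, out, ctr)
  expect_equal(pr$paired_fraction, 1)
  expect_lt(max(pr$pairs$offset_deg), 1e-5)
  expect_equal(pr$pairs$outer_id, pr$pairs$nub_id + 100L)
})

test_that("greedy pairing equals the optimal assignment on small cohorts", {
  # instances with the geometry the generator produces: paired sites nearly
  # antipodal (small offsets), unpaired sites well separated
  set.seed(21)
  for (case in 1:12) {
    n_nub <- sample(6:12, 1)
    U <- matrix(rnorm(3 * n_nub), ncol = 3); U <- U / sqrt(rowSums(U^2))
    k <- sample(3:n_nub, 1)
    n_out <- k + sample(0:2, 1)
    V <- matrix(0, n_out, 3)
    for (i in seq_len(k)) {
      ax <- rnorm(3); ax <- ax - sum(ax * U[i, ]) * U[i, ]
      V[i, ] <- as.numeric(axis_rot(ax, runif(1, 0, 12)) %*% U[i, ])
    }
    if (n_out > k) for (i in (k + 1):n_out) {
      repeat {
        v <- rnorm(3); v <- v / sqrt(sum(v^2))
        if (min(angdeg(rbind(v), U)) > 25) { V[i, ] <- v; break }
      }
    }
    ctr <- c(0, 0, 0)
    nub <- tibble::tibble(site_id = seq_len(n_nub), class = "nub",
                          surface = "luminal", x_nm = 17 * U[, 1],
                          y_nm = 17 * U[, 2], z_nm = 17 * U[, 3])
    out <- tibble::tibble(site_id = 100 + seq_len(n_out), class = "rib",
                          surface = "outer", x_nm = 25 * V[, 1],
                          y_nm = 25 * V[, 2], z_nm = 25 * V[, 3])
    pr <- pair_sites(nub, out, ctr, max_offset = 20)
    opt <- optimal_matching(angdeg(U, V), max_offset = 20)
    expect_equal(nrow(pr$pairs), opt$n_paired)
    expect_lt(abs(sum(pr$pairs$offset_deg) - opt$total_offset),
              1e-6 + 0.02 * max(1, opt$total_offset))
  }
})

test_that("band detection sees rendered bands and not their absence", {
  sc <- small_scene()
  truth <- sc$truth
  v <- 1
  s <- segment_vesicle(sc$volume, truth, v)
  ctr <- s$center_nm
  st <- truth$sites
  paired <- st[st$vesicle_id == v & st$surface == "outer" &
                 !is.na(st$pair_id), ]
  with_band <- paired[which(paired$band)[1], ]
  no_band <- paired[which(!paired$band), ]
  nub1 <- st[st$site_id == with_band$pair_id, ]
  set.seed(5)
  db <- detect_band(s$crop, c(nub1$x_nm, nub1$y_nm, nub1$z_nm),
                    c(with_band$x_nm, with_band$y_nm, with_band$z_nm),
                    s$membrane, ctr)
  expect_true(db$present)
  expect_lt(db$stats$Avg[1], db$stats$Avg[2])
  if (nrow(no_band) > 0) {
    nub0 <- st[st$site_id == no_band$pair_id[1], ]
    db0 <- detect_band(s$crop, c(nub0$x_nm, nub0$y_nm, nub0$z_nm),
                       c(no_band$x_nm[1], no_band$y_nm[1], no_band$z_nm[1]),
                       s$membrane, ctr)
    expect_false(db0$present)
  }
})

test_that("sphere mapping and the Robinson projection behave analytically", {
  ctr <- c(0, 0, 0)
  sites <- tibble::tibble(site_id = 1:2, class = c("rib", "nub"),
                          surface = c("outer", "luminal"),
                          x_nm = c(25, 17), y_nm = 0, z_nm = 0)
  sm <- sphere_map(sites, ctr, d_outer = 50, d_luminal = 34)
  expect_equal(sm$lat, c(0, 0))
  expect_equal(sm$lon, c(0, 0))
  expect_equal(sm$rx, c(0, 0))
  expect_equal(sm$ry, c(0, 0))
  # antipodal pair across the membrane: same lat/lon after normalization
  expect_equal(sm$radius_norm[1], sm$radius_norm[2], tolerance = 1e-9)
  # equator x is linear in longitude
  r1 <- robinson_xy(0, 30); r2 <- robinson_xy(0, 60)
  expect_equal(r2$x / r1$x, 2, tolerance = 1e-12)
  expect_error(sphere_map(tibble::tibble(site_id = 1, class = "rib",
                                         surface = "outer", x_nm = 0,
                                         y_nm = 0, z_nm = 0),
                          ctr, 50, 34), "projection error")
})

test_that("composite maps align identical and jittered site sets", {
  set.seed(6)
  base <- matrix(rnorm(12), ncol = 3)
  base <- base / sqrt(rowSums(base^2))
  mk <- function(v, R) tibble::tibble(
    vesicle_id = v, class = "rib", surface = "outer",
    ux = (base %*% t(R))[, 1], uy = (base %*% t(R))[, 2],
    uz = (base %*% t(R))[, 3], ref = TRUE)
  # identical sets: optimal relative rotation is the identity and the
  # score reaches the self-overlap of the base set
  cm <- composite_map(dplyr::bind_rows(mk(1, diag(3)), mk(2, diag(3))))
  rel <- cm$rotations[[1]] %*% t(cm$rotations[[2]])
  expect_lt(rot_angle(rel), 2)
  s_self <- sum(pmax(0, 1 - angdeg(base, base) / 30)) / (nrow(base)^2)
  expect_gte(tail(cm$score_trace, 1), s_self - 1e-6)
  # single-site pair is brought to zero separation (score 1)
  one <- dplyr::bind_rows(
    tibble::tibble(vesicle_id = 1, class = "rib", surface = "outer",
                   ux = 1, uy = 0, uz = 0, ref = TRUE),
    tibble::tibble(vesicle_id = 2, class = "rib", surface = "outer",
                   ux = 0.2588, uy = 0.9659, uz = 0, ref = TRUE))
  cm1 <- composite_map(one)
  expect_equal(tail(cm1$score_trace, 1), 1, tolerance = 1e-4)
  # score trace never decreases
  expect_true(all(diff(cm$score_trace) >= -1e-9))
  expect_true(all(diff(cm1$score_trace) >= -1e-9))
})

test_that("composite maps recover known vesicle rotations under jitter", {
  # a shared reference-site template with varied elevations and azimuths
  # (identifiable: no rival rotation maps it near-onto itself), 8-degree
  # per-site angular jitter, random true poses
  dom <- lumenmap:::domain_geometry(scene_params())
  set.seed(200)
  base <- t(vapply(1:6, function(i)
    lumenmap:::cap_dir(dom$u_bind, dom$theta_b * runif(1, 0.25, 1.05),
                       runif(1, -90, 90) * pi / 180), numeric(3)))
  set.seed(17)
  true_R <- c(list(diag(3)), rand_rotation(10))
  sites <- dplyr::bind_rows(lapply(1:11, function(v) {
    jit <- base
    for (i in seq_len(nrow(jit))) {
      ax <- rnorm(3); ax <- ax - sum(ax * jit[i, ]) * jit[i, ]
      jit[i, ] <- as.numeric(axis_rot(ax, rnorm(1, 0, 8)) %*% jit[i, ])
    }
    M <- jit %*% t(true_R[[v]])
    tibble::tibble(vesicle_id = v, class = "rib", surface = "outer",
                   ux = M[, 1], uy = M[, 2], uz = M[, 3], ref = TRUE)
  }))
  cm <- composite_map(sites)
  errs <- vapply(2:11, function(v) {
    rel <- t(cm$rotations[[1]]) %*% cm$rotations[[v]]
    rot_angle(t(rel) %*% (true_R[[1]] %*% t(true_R[[v]])))
  }, numeric(1))
  expect_lt(median(errs), 10)
  expect_lt(max(errs), 12)
  # zero jitter: exact recovery
  sites0 <- dplyr::bind_rows(lapply(1:11, function(v) {
    M <- base %*% t(true_R[[v]])
    tibble::tibble(vesicle_id = v, class = "rib", surface = "outer",
                   ux = M[, 1], uy = M[, 2], uz = M[, 3], ref = TRUE)
  }))
  cm0 <- composite_map(sites0)
  errs0 <- vapply(2:11, function(v) {
    rel <- t(cm0$rotations[[1]]) %*% cm0$rotations[[v]]
    rot_angle(t(rel) %*% (true_R[[1]] %*% t(true_R[[v]])))
  }, numeric(1))
  expect_lt(max(errs0), 2)
  # the overlap score is invariant under one global rotation of every vesicle
  G <- euler_rot(25, 10, -40)
  sites2 <- sites
  M2 <- as.matrix(sites[, c("ux", "uy", "uz")]) %*% t(G)
  sites2$ux <- M2[, 1]; sites2$uy <- M2[, 2]; sites2$uz <- M2[, 3]
  cm2 <- composite_map(sites2)
  expect_equal(tail(cm$score_trace, 1), tail(cm2$score_trace, 1),
               tolerance = 0.02)
  expect_warning(composite_map(dplyr::bind_rows(
    sites, tibble::tibble(vesicle_id = 99, class = "boom", surface = "outer",
                          ux = 1, uy = 0, uz = 0, ref = FALSE))), "excluding")
})

test_that("the two-vesicle optimizer matches a brute-force rotation oracle", {
  set.seed(29)
  mkcap <- function(R) {
    ax0 <- c(0, 0.2, 0.98)
    M <- t(vapply(1:4, function(i) {
      ax <- rnorm(3); ax <- ax - sum(ax * ax0) * ax0
      as.numeric(axis_rot(ax, runif(1, 5, 35)) %*% lumenmap:::unit(ax0))
    }, numeric(3)))
    M %*% t(R)
  }
  A <- mkcap(diag(3)); B <- mkcap(rand_rotation(1)[[1]])
  sites <- dplyr::bind_rows(
    tibble::tibble(vesicle_id = 1, class = "rib", surface = "outer",
                   ux = A[, 1], uy = A[, 2], uz = A[, 3], ref = TRUE),
    tibble::tibble(vesicle_id = 2, class = "rib", surface = "outer",
                   ux = B[, 1], uy = B[, 2], uz = B[, 3], ref = TRUE))
  cm <- composite_map(sites)
  # brute force over the relative rotation of vesicle 2 on a 6-degree grid
  kern <- function(RB) {
    th <- angdeg(A, B %*% t(RB))
    sum(pmax(0, 1 - th / 30)) / 16
  }
  best <- 0
  for (az in seq(0, 354, 6)) for (ay in seq(0, 174, 6)) for (ax in seq(0, 354, 6)) {
    s <- kern(euler_rot(ax, ay, az))
    if (s > best) best <- s
  }
  # optimizer's score matches the exhaustive optimum (grid resolution slack)
  expect_gte(tail(cm$score_trace, 1), best - 0.03)
})

test_that("distance profiles normalize to the rib reference and scale", {
  sites <- tibble::tibble(
    vesicle_id = 1,
    site_id = 1:4,
    class = c("rib", "rib", "boom", "nub"),
    surface = c("outer", "outer", "outer", "luminal"),
    partner_class = c(NA, NA, NA, "rib"),
    x_nm = c(0, 5, 0, 0), y_nm = c(0, 0, 5, 0),
    z_nm = c(10, 14, 30, 12 * 34 / 50))
  ves <- tibble::tibble(vesicle_id = 1, d_outer = 50, d_luminal = 34)
  dp <- distance_profile(sites, list(point = c(0, 0, 0), normal = c(0, 0, 1)),
                         ves)
  # rib sites average to zero by construction
  expect_equal(mean(dp$norm_distance[dp$class == "rib"]), 0, tolerance = 1e-9)
  # the luminal site at the scaled height of the rib mean has distance zero
  expect_equal(dp$norm_distance[dp$class == "nub"], 0, tolerance = 1e-9)
  expect_equal(dp$norm_distance[dp$class == "boom"], 18, tolerance = 1e-9)
})

test_that("class ordering of distances matches the domain layout", {
  sc <- small_scene()
  truth <- sc$truth
  st <- truth$sites %>%
    dplyr::filter(.data$vesicle_id %in% which(truth$vesicles$docked),
                  .data$surface == "outer")
  st$partner_class <- NA_character_
  dp <- distance_profile(st, list(point = c(0, 0, 0), normal = c(0, 0, 1)),
                         truth$vesicles[, c("vesicle_id", "d_outer", "d_luminal")])
  med <- tapply(dp$norm_distance, dp$class, mean)
  expect_lt(med[["rib"]], med[["spar"]])
  expect_lt(med[["spar"]], med[["boom"]])
})

test_that("the printed counts imply a sixfold site-density asymmetry", {
  ratio <- site_density_ratio(4.2 + 2.0 + 7.0, 3.9 + 8.5,
                              binding_frac = 0.137, fusion_frac = 0.05)
  expect_gt(ratio, 5.5)
  expect_lt(ratio, 6.5)
})
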