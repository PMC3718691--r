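test_that("child seeds are deterministic, distinct and 31-bit", {
  s <- vapply(1:20, function(k) child_seed(7, k), integer(1))
  expect_equal(s, vapply(1:20, function(k) child_seed(7, k), integer(1)))
  expect_equal(length(unique(s)), 20)
  expect_true(all(s >= 0 & s < 2^31))
  expect_false(child_seed(7, 1) == child_seed(8, 1))
})

test_that("the pipeline runs end to end and reports every headline metric", {
  cfg <- run_config(
    scene = scene_params(n_docked = 3, n_undocked = 0),
    align = list(methods = "density", rounds = 1, side = 48, step_coarse = 5,
                 angle_range = 30, tmax = 3, start_grid_step = 60),
    map = list(pair_threshold = 20, kernel_cutoff = 30, band_radius = 2,
               band_perm = 60),
    seed = 7)
  rb <- cached("pipeline_small", run_pipeline(cfg, verbose = FALSE))
  expect_s3_class(rb$headline, "tbl_df")
  core <- c("fill_fraction_mean", "d_outer_mean", "model_volume_lumen_pct",
            "containment_min_pct", "nub_sites_mean", "pairing_fraction_pct",
            "binding_domain_pct", "band_detection_rib_pct",
            "oriented_docked_fraction")
  vals <- setNames(rb$headline$value, rb$headline$metric)[core]
  expect_true(all(is.finite(vals)))
  expect_true(all(rb$orientation$oriented))
  expect_gt(vals["pairing_fraction_pct"], 70)
  expect_s3_class(tidy(rb), "tbl_df")
})

test_that("deterministic stages reproduce exactly under one seed", {
  cfg <- run_config(scene = scene_params(n_docked = 2, n_undocked = 0),
                    seed = 5)
  r1 <- run_pipeline(cfg, stages = c("simulate", "segment"), verbose = FALSE)
  r2 <- run_pipeline(cfg, stages = c("simulate", "segment"), verbose = FALSE)
  expect_identical(r1$morphometry, r2$morphometry)
  expect_identical(r1$volume$data, r2$volume$data)
})

test_that("a scene without docked vesicles degrades to empty tables", {
  cfg <- run_config(scene = scene_params(n_docked = 0, n_undocked = 2),
                    seed = 9)
  expect_warning(
    rb <- run_pipeline(cfg, verbose = FALSE),
    "docked")
  expect_equal(nrow(rb$orientation), 0)
  expect_equal(nrow(rb$pairing), 0)
  # schema is stable: the headline metrics exist, possibly NA
  expect_true(all(c("pairing_fraction_pct", "model_volume_lumen_pct") %in%
                    rb$headline$metric))
})

test_that("scene outputs round-trip through the on-disk formats", {
  sc <- clean_scene()
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  expect_true(all(file.exists(file.path(
    dir, c("scene.mrc", "labels.mrc", "truth.json", "sites.csv")))))
  v2 <- read_mrc(file.path(dir, "scene.mrc"))
  expect_equal(v2$voxel_size, sc$volume$voxel_size, tolerance = 1e-3)
  expect_equal(max(abs(v2$data - sc$volume$data)), 0, tolerance = 0.01)
  lab <- read_mrc(file.path(dir, "labels.mrc"))
  expect_true(all(sort(unique(as.integer(lab$data))) %in% 0:5))
  sites <- utils::read.csv(file.path(dir, "sites.csv"))
  expect_equal(nrow(sites), nrow(sc$truth$sites))
  js <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(length(js$vesicles), nrow(sc$truth$vesicles))
})
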