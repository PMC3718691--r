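#' Pipeline configuration
#'
#' A fully serializable description of one end-to-end run: scene parameters,
#' alignment, mapping and statistics settings, the master seed and an
#' optional output directory. The master seed is fanned out to per-stage
#' child seeds by a counter scheme so stages are reproducible in isolation.
#'
#' @param scene a [scene_params].
#' @param align list: `methods` (subset of density/surface_given/
#'   surface_random), `rounds`, `side`, `step_coarse`, `angle_range`,
#'   `tmax`, `start_grid_step`.
#' @param map list: `pair_threshold` (degrees), `kernel_cutoff` (degrees),
#'   `band_radius` (nm), `band_perm` (permutation draws).
#' @param stats list: `alpha`.
#' @param seed master seed.
#' @param out_dir optional output directory.
#' @export
run_config <- function(scene = scene_params(),
                       align = list(methods = c("density", "surface_given",
                                                "surface_random"),
                                    rounds = 5, side = 48, step_coarse = 5,
                                    angle_range = 30, tmax = 3,
                                    start_grid_step = 60),
                       map = list(pair_threshold = 20, kernel_cutoff = 30,
                                  band_radius = 2, band_perm = 200),
                       stats = list(alpha = 0.05),
                       seed = 1L, out_dir = NULL) {
  structure(list(scene = scene, align = align, map = map, stats = stats,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param seed master seed.
#' @param k stage counter.
#' @return `child_seed()` returns a deterministic 31-bit child seed.
#' @export
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 65536 * 30269 + k * 16807) %% 2147483647)
}

#' Segment one vesicle of a phantom scene
#'
#' Membrane (shell-bounded bimodal threshold), lumen (membrane interior) and
#' luminal-assembly VOIs, plus the five-axis diameter set and lumen fill
#' fraction.
#'
#' @param volume the scene [vox_volume].
#' @param truth the `scene_truth` (provides the programmatic bounding
#'   regions that replace interactive marking).
#' @param v vesicle id.
#' @return list: `crop`, `membrane`, `lumen`, `assembly`, `diameters`,
#'   `fill`, `center_nm` (measured, crop frame).
#' @export
segment_vesicle <- function(volume, truth, v) {
  crop <- crop_volume(volume, truth, v)
  ves <- truth$vesicles[v, ]
  d <- dim(crop$data)
  ctr <- c(ves$cx, ves$cy, ves$cz)
  ax <- lapply(1:3, function(a) crop$origin[a] + (seq_len(d[a]) - 0.5) *
                 crop$voxel_size - ctr[a])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  shell <- r2 >= (ves$d_luminal / 2 - 2)^2 & r2 <= (ves$d_outer / 2 + 2.5)^2
  membrane <- segment_voi(crop, shell, label = "membrane")
  lumen <- lumen_from_membrane(membrane)
  assembly <- segment_voi(crop, lumen$support, label = "assembly")
  dia <- vesicle_diameters(crop, membrane)
  fill <- lumen_fill_fraction(lumen, assembly)
  # dia$center is already in voxel-center units of the crop
  center_nm <- crop$origin + dia$center * crop$voxel_size
  list(crop = crop, membrane = membrane, lumen = lumen, assembly = assembly,
       diameters = dia, fill = fill, center_nm = center_nm)
}

#' Run the full phantom analysis pipeline
#'
#' simulate -> segment -> align -> orient -> map -> stats, producing a
#' report bundle with per-stage tables and a headline metrics table. Stage
#' failures abort with a stage-tagged error; empty stages (for example no
#' docked vesicles) produce empty tables with a warning.
#'
#' @param config a [run_config].
#' @param stages subset of stages to run (later stages need earlier ones).
#' @param verbose print stage progress to standard error.
#' @return a `report_bundle` list.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "segment", "align", "orient",
                                    "map", "stats"),
                         verbose = TRUE) {
  say <- function(...) if (verbose) message("[lumenmap] ", ...)
  stage <- function(name, expr) {
    say("stage ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  out <- list(config = config)

  scene <- stage("simulate",
    synthesize_scene(config$scene, seed = child_seed(config$seed, 1)))
  out$truth <- scene$truth
  out$volume <- scene$volume
  if (!"segment" %in% stages) return(finish_report(out))

  n <- nrow(scene$truth$vesicles)
  docked <- which(scene$truth$vesicles$docked)
  seg <- stage("segment", lapply(seq_len(n), function(v)
    segment_vesicle(scene$volume, scene$truth, v)))
  out$segmentation <- seg
  out$morphometry <- tibble(
    vesicle_id = seq_len(n),
    docked = scene$truth$vesicles$docked,
    d_outer = vapply(seg, function(s) s$diameters$d_outer, 1),
    d_luminal = vapply(seg, function(s) s$diameters$d_luminal, 1),
    fill_fraction = vapply(seg, function(s) s$fill, 1)) %>%
    mutate(SA_SV = pi * .data$d_outer^2)

  if ("align" %in% stages && length(docked) >= 3) {
    al <- config$align
    reps <- lapply(docked, function(v)
      assembly_rep(seg[[v]]$crop, seg[[v]]$assembly, side = al$side, id = match(v, docked)))
    models <- list()
    if ("density" %in% al$methods)
      models$density <- stage("align", withr::with_seed(
        child_seed(config$seed, 2),
        build_alignment_model(reps, "density", "given", rounds = al$rounds,
                              side = al$side, angle_range = al$angle_range,
                              step_coarse = al$step_coarse, tmax = al$tmax,
                              start_grid_step = al$start_grid_step)))
    if ("surface_given" %in% al$methods)
      models$surface_given <- stage("align", withr::with_seed(
        child_seed(config$seed, 3),
        build_alignment_model(reps, "surface", "given", rounds = al$rounds,
                              side = al$side, start_grid_step = al$start_grid_step)))
    if ("surface_random" %in% al$methods)
      models$surface_random <- stage("align", withr::with_seed(
        child_seed(config$seed, 4),
        build_alignment_model(reps, "surface", "random", rounds = al$rounds,
                              side = al$side, start_grid_step = al$start_grid_step)))
    out$models <- models
    out$reps <- reps
    if (length(models) >= 1) {
      vol_nm3 <- vapply(models, model_volume, 1)
      lumen_sphere <- 4 / 3 * pi * (config$scene$d_luminal_mean / 2)^3
      out$model_volume <- tibble(model = names(models), volume_nm3 = vol_nm3,
                                 lumen_fraction = vol_nm3 / lumen_sphere)
      cont <- lapply(names(models), function(mn)
        tibble(model = mn, member = seq_along(reps),
               containment = vapply(seq_along(reps), function(i)
                 containment_fraction(reps[[i]], models[[mn]]), 1)))
      out$containment <- bind_rows(cont)
      if (length(models) >= 2) {
        pr <- utils::combn(names(models), 2)
        ov <- lapply(seq_len(ncol(pr)), function(c2) {
          o <- model_overlap(models[[pr[1, c2]]], models[[pr[2, c2]]])
          tibble(modelA = pr[1, c2], modelB = pr[2, c2],
                 A_in_B = o[1], B_in_A = o[2])
        })
        out$model_overlap <- bind_rows(ov)
      }
    }
  } else if ("align" %in% stages) {
    warning("fewer than 3 docked vesicles; alignment stage skipped")
  }

  if ("orient" %in% stages && !is.null(out$models$density)) {
    frames <- lapply(docked, function(v) frame_from_truth(scene$truth, v))
    arrows <- stage("orient",
      orientation_arrows(out$models$density, frames, reference_id = 1))
    arrows$vesicle_id <- docked[arrows$vesicle_id]
    out$orientation <- classify_orientations(arrows,
                                             docked = rep(TRUE, nrow(arrows)))
  } else if ("orient" %in% stages) {
    out$orientation <- tibble(vesicle_id = integer(), oriented = logical())
    if (length(docked) == 0) warning("no docked vesicles; orientation table empty")
  }

  if ("map" %in% stages) {
    mp <- config$map
    res <- stage("map", withr::with_seed(child_seed(config$seed, 5),
      map_stage(scene, seg, docked, mp)))
    out[names(res)] <- res
  }

  if ("stats" %in% stages && !is.null(out$bands)) {
    out$stain_stats <- stage("stats",
      stain_stage(scene, seg, out$band_vois, docked, config$stats$alpha))
  }

  finish_report(out)
}

# connection-site mapping across docked vesicles
map_stage <- function(scene, seg, docked, mp) {
  truth <- scene$truth
  sites_all <- list(); pairs_all <- list(); bands_all <- list()
  zone_rows <- list(); band_vois <- list(); local_sites <- list()
  for (v in docked) {
    s <- seg[[v]]
    m <- truth$masks[[v]]
    ids_nub <- names(m$nubs); ids_out <- names(m$outer)
    vois <- c(lapply(ids_nub, function(id) truth_voi(truth, v, "nubs", id)),
              lapply(ids_out, function(id) truth_voi(truth, v, "outer", id)))
    cat_tbl <- truth$sites
    cls <- c(rep("nub", length(ids_nub)),
             cat_tbl$class[match(as.integer(ids_out), cat_tbl$site_id)])
    surf <- c(rep("luminal", length(ids_nub)), rep("outer", length(ids_out)))
    st <- extract_sites(vois, cls, surf, s$membrane, s$crop,
                        vesicle_id = v,
                        site_ids = as.integer(c(ids_nub, ids_out)))
    ctr <- s$center_nm
    pr <- pair_sites(st[st$surface == "luminal", ], st[st$surface == "outer", ],
                     ctr, max_offset = mp$pair_threshold)
    # binding domain from extracted rib/spar/boom sites
    zf <- binding_domain_fraction(st, ctr, s$diameters$d_outer)
    if (is.finite(zf)) {
      zone_rows[[length(zone_rows) + 1]] <- tibble(
        vesicle_id = v, zone_fraction = zf,
        SA_SV = pi * s$diameters$d_outer^2,
        fusion_fraction = truth$params$fusion_domain_area_fraction)
    }
    # transmembrane bands on every pair
    if (nrow(pr$pairs) > 0) {
      for (pidx in seq_len(nrow(pr$pairs))) {
        nid <- pr$pairs$nub_id[pidx]; oid <- pr$pairs$outer_id[pidx]
        nxyz <- as.numeric(st[st$site_id == nid, c("x_nm", "y_nm", "z_nm")])
        oxyz <- as.numeric(st[st$site_id == oid, c("x_nm", "y_nm", "z_nm")])
        db <- detect_band(s$crop, nxyz, oxyz, s$membrane, ctr,
                          radius = mp$band_radius, n_perm = mp$band_perm)
        bands_all[[length(bands_all) + 1]] <- tibble(
          vesicle_id = v, nub_id = nid, outer_id = oid,
          outer_class = pr$pairs$outer_class[pidx],
          present = db$present, p_value = db$p_value,
          truth_band = isTRUE(truth$sites$band[match(oid, truth$sites$site_id)]))
        if (!is.null(db$band_voi))
          band_vois[[length(band_vois) + 1]] <-
            list(vesicle_id = v, outer_class = pr$pairs$outer_class[pidx],
                 present = db$present, voi = db$band_voi)
      }
    }
    # vesicle-local site directions for composite mapping / projections
    frame <- frame_from_truth(truth, v)
    B <- rbind(frame$head, frame$long_axis, frame$tail)
    U <- site_dirs(st, ctr) %*% t(B)
    partner_class <- rep(NA_character_, nrow(st))
    partner_class[match(pr$pairs$nub_id, st$site_id)] <- pr$pairs$outer_class
    local_sites[[length(local_sites) + 1]] <- st %>%
      mutate(ux = U[, 1], uy = U[, 2], uz = U[, 3],
             partner_class = partner_class,
             ref = (.data$surface == "outer" & .data$class == "rib") |
               (.data$surface == "luminal" & !is.na(partner_class) &
                  partner_class == "rib"))
    sites_all[[length(sites_all) + 1]] <- st
    pairs_all[[length(pairs_all) + 1]] <-
      tibble(vesicle_id = v, n_nubs = sum(st$surface == "luminal"),
             n_outer = sum(st$surface == "outer"),
             n_paired = nrow(pr$pairs),
             paired_fraction = pr$paired_fraction)
  }
  if (length(sites_all) == 0) {
    warning("no docked vesicles; mapping tables empty")
    return(list(sites = tibble(), pairing = tibble(), zones = tibble(),
                bands = tibble(), composite = NULL, band_vois = list(),
                distances = tibble()))
  }
  lsites <- bind_rows(local_sites)
  comp <- if (length(docked) >= 2)
    composite_map(lsites %>% filter(.data$surface == "outer")) else NULL
  dist_tbl <- distance_profile(
    lsites, list(point = c(0, 0, 0), normal = c(0, 0, 1)),
    tibble(vesicle_id = docked,
           d_outer = vapply(seg[docked], function(s) s$diameters$d_outer, 1),
           d_luminal = vapply(seg[docked], function(s) s$diameters$d_luminal, 1)))
  list(sites = bind_rows(sites_all), pairing = bind_rows(pairs_all),
       zones = bind_rows(zone_rows), bands = bind_rows(bands_all),
       composite = comp, band_vois = band_vois, distances = dist_tbl)
}

# per-vesicle regional gray statistics and ANOVA + Tukey vs rest of membrane
stain_stage <- function(scene, seg, band_vois, docked, alpha) {
  out <- list()
  for (v in docked) {
    s <- seg[[v]]
    bl <- Filter(function(b) b$vesicle_id == v, band_vois)
    if (length(bl) == 0) next
    band_idx_all <- sort(unique(unlist(lapply(bl, function(b) b$voi$support))))
    rest_idx <- setdiff(s$membrane$support, band_idx_all)
    groups <- region_gray_stats(
      s$crop, voi("rest", rest_idx, s$membrane$dims, s$membrane$voxel_size,
                  s$membrane$origin, composite = TRUE), region = "rest")
    for (cl in unique(vapply(bl, function(b) b$outer_class, ""))) {
      idx <- sort(unique(unlist(lapply(
        Filter(function(b) b$outer_class == cl, bl),
        function(b) b$voi$support))))
      if (length(idx) < 2) next
      groups <- bind_rows(groups, region_gray_stats(
        s$crop, voi(cl, idx, s$membrane$dims, s$membrane$voxel_size,
                    s$membrane$origin, composite = TRUE),
        region = paste0("nubs-", cl)))
    }
    if (nrow(groups) < 2) next
    a <- anova_tukey(groups, alpha = alpha, reference = "rest")
    out[[length(out) + 1]] <- tibble(vesicle_id = v, tidy(a),
                                     F = attr(a, "F"), p = attr(a, "p"))
  }
  bind_rows(out)
}

finish_report <- function(out) {
  hm <- list(
    fill_fraction_mean = if (!is.null(out$morphometry))
      mean(out$morphometry$fill_fraction) else NA_real_,
    d_outer_mean = if (!is.null(out$morphometry))
      mean(out$morphometry$d_outer) else NA_real_,
    SA_SV_mean = if (!is.null(out$morphometry))
      mean(out$morphometry$SA_SV) else NA_real_,
    model_volume_lumen_pct = if (!is.null(out$model_volume))
      100 * out$model_volume$lumen_fraction[out$model_volume$model == "density"][1]
      else NA_real_,
    model_concordance_min_pct = if (!is.null(out$model_overlap))
      100 * min(c(out$model_overlap$A_in_B, out$model_overlap$B_in_A))
      else NA_real_,
    containment_min_pct = if (!is.null(out$containment))
      100 * min(out$containment$containment) else NA_real_,
    nub_sites_mean = if (!is.null(out$pairing) && nrow(out$pairing))
      mean(out$pairing$n_nubs) else NA_real_,
    pairing_fraction_pct = if (!is.null(out$pairing) && nrow(out$pairing))
      100 * sum(out$pairing$n_paired) / sum(out$pairing$n_nubs) else NA_real_,
    binding_domain_pct = if (!is.null(out$zones) && nrow(out$zones))
      100 * mean(out$zones$zone_fraction) else NA_real_,
    band_detection_rib_pct = if (!is.null(out$bands) && nrow(out$bands))
      100 * mean(out$bands$present[out$bands$outer_class == "rib"]) else NA_real_,
    oriented_docked_fraction = if (!is.null(out$orientation) &&
                                   nrow(out$orientation))
      mean(out$orientation$oriented) else NA_real_)
  out$headline <- tibble(metric = names(hm), value = unlist(hm))
  class(out) <- "report_bundle"
  if (!is.null(out$config$out_dir)) write_report(out, out$config$out_dir)
  out
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  df <- as.data.frame(x$headline)
  df$value <- round(df$value, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

write_report <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) if (!is.null(df) && nrow(df))
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  wcsv(out$morphometry, "morphometry.csv")
  wcsv(out$model_volume, "model_volume.csv")
  wcsv(out$model_overlap, "model_overlap.csv")
  wcsv(out$containment, "containment.csv")
  wcsv(out$orientation, "orientation.csv")
  wcsv(out$sites, "sites.csv")
  wcsv(out$pairing, "pairing.csv")
  wcsv(out$zones, "zones.csv")
  wcsv(out$bands, "bands.csv")
  wcsv(out$stain_stats, "stain_stats.csv")
  wcsv(out$headline, "headline.csv")
  manifest <- list(seed = out$config$seed,
                   config_hash = rlang::hash(out$config[c("scene", "align",
                                                          "map", "stats")]),
                   package_version = as.character(utils::packageVersion("lumenmap")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
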