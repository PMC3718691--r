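#' Synthesize an active-zone phantom scene
#'
#' Generates a complete synthetic scene: docked vesicles flanking the main
#' body of the AZM in rows on the presynaptic membrane plane (undocked
#' vesicles in a layer above), each carrying a jittered copy of the shared
#' luminal-assembly template, nub connection sites on the luminal membrane
#' surface paired across the membrane with outer AZM/non-AZM macromolecule
#' sites (rib/spar/boom partners confined to the main AZM binding-domain cap,
#' none in the fusion domain), transmembrane stain bands, and full voxel
#' ground truth. Docked vesicles share the template orientation exactly
#' (relative to their own active-zone frame); undocked poses are drawn
#' uniformly (Haar) over rotations.
#'
#' @param params a [scene_params].
#' @param seed RNG seed (defaults to `params$seed`).
#' @return a list with elements `volume` (a [vox_volume] of the stained
#'   scene) and `truth` (a `scene_truth` object holding vesicle poses, the
#'   site catalog, per-structure voxel masks and active-zone frames).
#' @export
synthesize_scene <- function(params = scene_params(), seed = params$seed) {
  withr::with_seed(seed, synthesize_scene_impl(params))
}

synthesize_scene_impl <- function(params) {
  tpl <- make_template_impl(params)
  vs <- params$voxel_size
  n <- params$n_docked + params$n_undocked
  if (n < 1) stop("scene must contain at least one vesicle")

  d_out <- rnorm(n, params$d_outer_mean, params$d_outer_sd)
  d_lum <- vapply(d_out, function(do) {
    repeat {
      dl <- rnorm(1, params$d_luminal_mean, params$d_luminal_sd)
      if (do - dl > 10 && do - dl < 22) return(dl)
    }
  }, numeric(1))
  docked <- seq_len(n) <= params$n_docked

  # ---- layout (nm, scene frame: median plane x = 0, presynaptic plane z = 0)
  r_out_max <- max(d_out) / 2
  row_x <- 26 + r_out_max
  pitch <- max(d_out) + 10
  side_of <- integer(n); cx <- cy <- cz <- numeric(n)
  nd <- params$n_docked
  if (nd > 0) {
    side_of[1:nd] <- ifelse(seq_len(nd) %% 2 == 1, -1L, 1L)
    slot <- (seq_len(nd) + 1) %/% 2
    cx[1:nd] <- side_of[1:nd] * row_x
    cy[1:nd] <- slot * pitch
    cz[1:nd] <- d_out[1:nd] / 2 + params$geometry$cleft
  }
  if (params$n_undocked > 0) {
    iu <- nd + seq_len(params$n_undocked)
    side_of[iu] <- ifelse(seq_along(iu) %% 2 == 1, -1L, 1L)
    slot <- (seq_along(iu) + 1) %/% 2
    cx[iu] <- side_of[iu] * 0.6 * row_x
    cy[iu] <- (slot - 0.5) * pitch
    cz[iu] <- 2.2 * r_out_max + 12 + d_out[iu] / 2
  }
  dm <- as.matrix(stats::dist(cbind(cx, cy, cz)))
  need <- outer(d_out, d_out, "+") / 2 + 2
  diag(dm) <- Inf
  if (any(dm < need))
    stop("placement error: vesicles overlap after layout")

  crop_side <- 2L * as.integer(ceiling((max(d_out) / 2 + 7) / vs)) + 2L
  # scene origin such that every crop is at least 2 voxels inside the grid
  ext_lo <- c(min(cx), min(cy), min(cz)) - crop_side * vs / 2 - 2 * vs
  ext_lo[3] <- min(ext_lo[3], -4)  # keep the presynaptic slab in frame
  origin <- floor(ext_lo / vs) * vs
  ext_hi <- c(max(cx), max(cy), max(cz)) + crop_side * vs / 2 + 2 * vs
  dims <- as.integer(ceiling((ext_hi - origin) / vs))

  dom <- domain_geometry(params)
  # stratified nub-count draws: marginally Normal(mean, sd), but balanced
  # across the scene so cohort means are calibrated rather than noisy
  nub_counts <- pmax(4L, as.integer(round(qnorm(
    (sample(n) - runif(n)) / n, params$nub_count_mean, params$nub_count_sd))))
  vesicles <- vector("list", n)
  masks <- vector("list", n)
  site_rows <- vector("list", n)
  next_site <- 1L

  for (v in seq_len(n)) {
    # snap center to the voxel lattice of its crop
    ctr_vox <- (c(cx[v], cy[v], cz[v]) - origin) / vs
    crop_lo <- round(ctr_vox - crop_side / 2)        # 0-based corner
    ctr <- origin + (crop_lo + crop_side / 2) * vs    # snapped center (nm)
    Fv <- if (side_of[v] > 0) euler_rot(0, 0, 180) else diag(3)
    Rv <- if (docked[v]) diag(3) else rand_rotation(1)[[1]]
    A <- Fv %*% Rv
    r_o <- d_out[v] / 2; r_l <- d_lum[v] / 2
    scale <- d_lum[v] / params$d_luminal_mean

    sites <- draw_vesicle_sites(params, dom, n_nub = nub_counts[v])
    # per-vesicle realized nubs come from the site draw, not the template
    caps <- assembly_capsules(tpl, params$jitter_sd_arm, 0, scale)
    seg_arm <- caps$arms
    arm_pts <- seg_arm[, 1:3, drop = FALSE]
    nub_list <- lapply(which(sites$surface == "luminal"), function(i) {
      tip <- unit(c(sites$ux[i], sites$uy[i], sites$uz[i])) * r_l
      d2 <- rowSums(sweep(arm_pts, 2, tip)^2)
      anchor <- arm_pts[which.min(d2), ] +
        rnorm(3, 0, params$jitter_sd_nub * 0.25)
      rbind(c(anchor, tip, params$geometry$nub_radius * scale))
    })
    # normalize this vesicle's rasterized fill onto the target (the narrow
    # per-vesicle spread the fixed tissue shows), absorbing jitter- and
    # nub-count-driven volume variation into a small arm-radius adjustment
    tv <- params$fill_fraction_target * (1 + max(-0.08, min(0.08, rnorm(1, 0, 0.045))))
    ras0 <- rasterize_capsules(rbind(seg_arm, do.call(rbind, nub_list)), r_l,
                               params$voxel_size)
    fill0 <- sum(ras0$mask) / sum(ras0$lumen)
    sr <- max(0.7, min(1.4, sqrt(tv / fill0)))
    seg_arm[, 7] <- seg_arm[, 7] * sr
    nub_list <- lapply(nub_list, function(s) { s[, 7] <- s[, 7] * sr; s })

    # world-frame capsule coordinates
    to_world <- function(seg) {
      if (is.null(seg) || nrow(seg) == 0) return(seg)
      seg[, 1:3] <- sweep(seg[, 1:3, drop = FALSE] %*% t(A), 2, ctr, "+")
      seg[, 4:6] <- sweep(seg[, 4:6, drop = FALSE] %*% t(A), 2, ctr, "+")
      seg
    }
    seg_arm_w <- to_world(seg_arm)
    nub_w <- lapply(nub_list, to_world)

    # crop-frame geometry
    m <- crop_masks(seg_arm_w, nub_w, sites, A, ctr, r_o, r_l,
                    crop_lo, crop_side, origin, vs, params)

    # site catalog rows (world nm)
    ns <- nrow(sites)
    ids <- next_site:(next_site + ns - 1L)
    next_site <- next_site + ns
    names(m$nubs) <- ids[which(sites$surface == "luminal")]
    names(m$outer) <- ids[which(sites$surface == "outer")]
    if (length(m$bands)) names(m$bands) <- ids[as.integer(names(m$bands))]
    masks[[v]] <- m
    rr <- ifelse(sites$surface == "outer", r_o, r_l)
    uw <- as.matrix(sites[, c("ux", "uy", "uz")]) %*% t(A)
    pair_id <- rep(NA_integer_, ns)
    has_p <- !is.na(sites$partner_row)
    pair_id[has_p] <- ids[sites$partner_row[has_p]]
    site_rows[[v]] <- tibble(
      vesicle_id = v, site_id = ids, class = sites$class,
      surface = sites$surface,
      x_nm = ctr[1] + rr * uw[, 1], y_nm = ctr[2] + rr * uw[, 2],
      z_nm = ctr[3] + rr * uw[, 3],
      ux = uw[, 1], uy = uw[, 2], uz = uw[, 3],
      pair_id = pair_id, band = sites$band)

    vesicles[[v]] <- tibble(
      vesicle_id = v, docked = docked[v],
      cx = ctr[1], cy = ctr[2], cz = ctr[3],
      d_outer = d_out[v], d_luminal = d_lum[v],
      side = side_of[v], scale = scale,
      pose = list(Rv), frame_rot = list(Fv),
      crop_lo = list(as.integer(crop_lo)), crop_side = crop_side)
  }

  sites <- bind_rows(site_rows)
  truth <- structure(list(
    params = params, template = tpl,
    vesicles = bind_rows(vesicles), sites = sites, masks = masks,
    scene_dims = dims, voxel_size = vs, origin = origin), class = "scene_truth")
  vol <- render_stain_impl(truth, params)
  list(volume = vol, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d vesicles (%d docked), %d sites, grid %s @ %.2g nm\n",
              nrow(x$vesicles), sum(x$vesicles$docked), nrow(x$sites),
              paste(x$scene_dims, collapse = "x"), x$voxel_size))
  invisible(x)
}

# Draw one vesicle's connection-site layout in the local frame.
# Outer macromolecule counts are drawn per class; nub count is drawn from its
# own distribution; (1 - dropout) of the nubs receive an antipodal outer
# partner (extra partners drawn as non-AZM macromolecules if demand exceeds
# the class draw), the rest are placed away from unpaired outer sites, which
# emulates partner macromolecules that failed to stain.
draw_vesicle_sites <- function(params, dom, n_nub = NULL) {
  deg <- pi / 180
  min_sep <- params$geometry$min_site_sep
  cls <- character(); U <- matrix(0, 0, 3)
  for (cl in outer_classes) {
    mcl <- params$class_counts[[cl]]
    ncl <- max(0L, as.integer(round(rnorm(1, mcl[1], mcl[2]))))
    for (i in seq_len(ncl)) {
      for (try in 1:40) {
        u <- draw_class_dir(cl, dom)
        ok <- nrow(U) == 0 ||
          min(apply(U, 1, function(w) vec_angle(w, u))) >= min_sep
        if (ok) break
      }
      U <- rbind(U, u); cls <- c(cls, cl)
    }
  }
  n_out <- nrow(U)
  if (is.null(n_nub))
    n_nub <- max(4L, as.integer(round(rnorm(1, params$nub_count_mean,
                                            params$nub_count_sd))))
  n_pair <- as.integer(round((1 - params$pairing_dropout_prob) * n_nub))
  while (n_pair > n_out) {  # meet pairing demand with extra non-AZM partners
    u <- draw_class_dir("nonAZM", dom)
    if (min(apply(U, 1, function(w) vec_angle(w, u))) >= min_sep * 0.6) {
      U <- rbind(U, u); cls <- c(cls, "nonAZM"); n_out <- n_out + 1L
    }
  }
  paired_outer <- sample(n_out, n_pair)
  # nub directions: antipodal across the membrane (same radial direction)
  # with tangential jitter of sd jitter_sd_nub nm on the luminal sphere
  sd_ang <- params$jitter_sd_nub / (params$d_luminal_mean / 2)
  nub_u <- t(vapply(paired_outer, function(i) {
    u <- U[i, ]
    t1 <- unit(if (abs(u[3]) < 0.95) c(-u[2], u[1], 0) else c(1, 0, 0) - u[1] * u)
    t2 <- c(u[2] * t1[3] - u[3] * t1[2], u[3] * t1[1] - u[1] * t1[3],
            u[1] * t1[2] - u[2] * t1[1])
    repeat {  # nub connection sites never fall inside the fusion domain
      v <- unit(u + rnorm(1, 0, sd_ang) * t1 + rnorm(1, 0, sd_ang) * t2)
      if (vec_angle(v, c(0, 0, -1)) * deg > dom$theta_f + 0.5 * deg) return(v)
    }
  }, numeric(3)))
  unpaired_out <- setdiff(seq_len(n_out), paired_outer)
  n_free <- n_nub - n_pair
  free_u <- matrix(0, 0, 3)
  while (nrow(free_u) < n_free) {
    u <- unit(rnorm(3))
    if (vec_angle(u, c(0, 0, -1)) < dom$theta_f / deg + 3) next
    if (length(unpaired_out) &&
        min(apply(U[unpaired_out, , drop = FALSE], 1,
                  function(w) vec_angle(w, u))) < 25) next
    if (nrow(nub_u) + nrow(free_u) > 0) {
      others <- rbind(nub_u, free_u)
      if (min(apply(others, 1, function(w) vec_angle(w, u))) < 6) next
    }
    free_u <- rbind(free_u, u)
  }
  bandp <- params$band_presence_prob
  band_out <- rep(NA, n_out)
  band_out[paired_outer] <- runif(n_pair) < bandp[cls[paired_outer]]
  out_tbl <- tibble(class = cls, surface = "outer",
                    ux = U[, 1], uy = U[, 2], uz = U[, 3],
                    partner_row = NA_integer_, band = band_out)
  nub_tbl <- tibble(class = "nub", surface = "luminal",
                    ux = c(nub_u[, 1], free_u[, 1]),
                    uy = c(nub_u[, 2], free_u[, 2]),
                    uz = c(nub_u[, 3], free_u[, 3]),
                    partner_row = c(paired_outer, rep(NA_integer_, n_free)),
                    band = c(band_out[paired_outer], rep(NA, n_free)))
  out_tbl$partner_row[paired_outer] <- n_out + seq_len(n_pair)
  bind_rows(out_tbl, nub_tbl)
}

# rasterize all per-vesicle structures into crop-frame index sets
crop_masks <- function(seg_arm_w, nub_w, sites, A, ctr, r_o, r_l,
                       crop_lo, crop_side, origin, vs, params) {
  cd <- rep(crop_side, 3L)
  ax <- lapply(1:3, function(a)
    origin[a] + (crop_lo[a] + seq_len(crop_side) - 0.5) * vs - ctr[a])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  membrane <- which(r2 >= r_l^2 & r2 <= r_o^2)
  lumen_arr <- r2 < r_l^2
  lumen <- which(lumen_arr)
  w2c <- function(seg) {  # world nm -> crop voxel units
    seg[, 1:3] <- sweep(seg[, 1:3, drop = FALSE], 2, origin + crop_lo * vs) / vs
    seg[, 4:6] <- sweep(seg[, 4:6, drop = FALSE], 2, origin + crop_lo * vs) / vs
    seg[, 7] <- seg[, 7] / vs
    seg
  }
  arm_mask <- cpp_raster_capsules(w2c(seg_arm_w), cd)
  dim(arm_mask) <- cd
  nub_idx <- lapply(nub_w, function(s) {
    m <- cpp_raster_capsules(w2c(s), cd); dim(m) <- cd
    which(m & lumen_arr)
  })
  assembly <- sort(unique(c(which(arm_mask & lumen_arr), unlist(nub_idx))))

  is_out <- sites$surface == "outer"
  uo <- as.matrix(sites[is_out, c("ux", "uy", "uz")]) %*% t(A)
  outer_idx <- lapply(seq_len(nrow(uo)), function(i) {
    p1 <- ctr + r_o * uo[i, ]
    p2 <- ctr + (r_o + params$geometry$outer_len) * uo[i, ]
    s <- w2c(matrix(c(p1, p2, params$geometry$outer_radius), 1))
    m <- cpp_raster_capsules(s, cd); dim(m) <- cd
    which(m & r2 >= r_o^2)
  })
  names(outer_idx) <- which(is_out)

  band_idx <- list()
  prow <- sites$partner_row
  out_rows <- which(is_out)
  for (i in out_rows) {
    if (is.na(prow[i]) || !isTRUE(sites$band[i])) next
    j <- prow[i]
    un <- as.numeric(A %*% c(sites$ux[j], sites$uy[j], sites$uz[j]))
    p1 <- ctr + (r_l - 1) * un
    p2 <- ctr + (r_o + 1) * uo[match(i, out_rows), ]
    s <- w2c(matrix(c(p1, p2, params$geometry$band_radius), 1))
    m <- cpp_raster_capsules(s, cd); dim(m) <- cd
    band_idx[[as.character(i)]] <- which(m & r2 >= r_l^2 & r2 <= r_o^2)
  }
  list(membrane = membrane, lumen = lumen, assembly = assembly,
       nubs = nub_idx, outer = outer_idx, bands = band_idx, dims = cd)
}
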