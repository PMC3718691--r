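#' Extract connection sites from macromolecule VOIs
#'
#' A macromolecule's connection site is the centroid of its three terminal
#' voxels nearest its membrane contact. VOIs farther than `max_gap` voxels
#' from the membrane surface produce an "unattached" warning and no site.
#'
#' @param macromolecule_vois list of [voi]s (one per macromolecule).
#' @param classes,surfaces character vectors parallel to the VOI list
#'   (class labels and `"outer"`/`"luminal"`).
#' @param membrane_voi the membrane [voi] on the same grid.
#' @param volume the crop [vox_volume] (geometry reference).
#' @param max_gap maximum membrane gap, voxels.
#' @param vesicle_id,site_ids optional identifiers carried into the output.
#' @return tibble of sites: `site_id`, `class`, `surface`, `x_nm`, `y_nm`,
#'   `z_nm`.
#' @export
extract_sites <- function(macromolecule_vois, classes, surfaces, membrane_voi,
                          volume, max_gap = 2, vesicle_id = NA_integer_,
                          site_ids = NULL) {
  stopifnot(length(macromolecule_vois) == length(classes),
            length(classes) == length(surfaces))
  mem_pts <- voxel_centers(volume, membrane_voi$support) / volume$voxel_size
  rows <- list()
  for (i in seq_along(macromolecule_vois)) {
    v <- macromolecule_vois[[i]]
    pts <- voxel_centers(volume, v$support) / volume$voxel_size
    d2 <- cpp_nn_dist2(pts, mem_pts)
    if (min(d2) > max_gap^2) {
      warning("macromolecule VOI '", v$label, "' does not reach the membrane (",
              round(sqrt(min(d2)), 2), " voxels); no site emitted")
      next
    }
    # terminal 3 voxels: nearest the membrane contact; ties (voxels already
    # touching the membrane) resolved toward the structure's far end
    cand <- which(d2 <= (sqrt(min(d2)) + 1)^2)
    ctr0 <- colMeans(pts)
    far <- order(-rowSums(sweep(pts[cand, , drop = FALSE], 2, ctr0)^2))
    term <- cand[far[seq_len(min(3, length(cand)))]]
    ctr <- colMeans(pts[term, , drop = FALSE]) * volume$voxel_size
    rows[[length(rows) + 1]] <- tibble(
      vesicle_id = vesicle_id,
      site_id = if (is.null(site_ids)) i else site_ids[i],
      class = classes[i], surface = surfaces[i],
      x_nm = ctr[1], y_nm = ctr[2], z_nm = ctr[3])
  }
  if (length(rows) == 0)
    tibble(vesicle_id = integer(), site_id = integer(), class = character(),
           surface = character(), x_nm = numeric(), y_nm = numeric(),
           z_nm = numeric())
  else bind_rows(rows)
}

# radial unit directions of sites about a vesicle center
site_dirs <- function(sites, center) {
  P <- as.matrix(sites[, c("x_nm", "y_nm", "z_nm")])
  P <- sweep(P, 2, center)
  r <- sqrt(rowSums(P^2))
  if (any(r < 1e-9)) stop("projection error: site at the sphere center")
  P / r
}

great_circle_deg <- function(U, V) {
  U <- rbind(U); V <- rbind(V)
  U <- U / sqrt(rowSums(U^2))
  V <- V / sqrt(rowSums(V^2))
  cc <- pmin(1, pmax(-1, tcrossprod(U, V)))
  matrix(acos(cc) * 180 / pi, nrow(U), nrow(V))
}

#' Pair nub sites with outer macromolecule sites
#'
#' After radial normalization to the vesicle's sphere, nub (luminal) sites
#' are matched one-to-one to outer sites by greedy minimum great-circle
#' offset (smallest offset first), rejecting offsets above `max_offset`
#' degrees ("opposite or slightly offset" pairing).
#'
#' @param nub_sites,outer_sites site tibbles (see [extract_sites()]).
#' @param center vesicle center (nm).
#' @param max_offset pairing threshold, degrees.
#' @return list with `pairs` (tibble: `nub_id`, `outer_id`, `offset_deg`,
#'   classes), `unpaired_nubs`, `unpaired_outer`, `paired_fraction`.
#' @export
pair_sites <- function(nub_sites, outer_sites, center, max_offset = 20) {
  if (nrow(nub_sites) == 0 || nrow(outer_sites) == 0) {
    return(list(pairs = tibble(nub_id = integer(), outer_id = integer(),
                               offset_deg = numeric(), outer_class = character()),
                unpaired_nubs = nub_sites$site_id,
                unpaired_outer = outer_sites$site_id,
                paired_fraction = if (nrow(nub_sites)) 0 else NaN))
  }
  U <- site_dirs(nub_sites, center)
  V <- site_dirs(outer_sites, center)
  ang <- matrix(great_circle_deg(U, V), nrow(U), nrow(V))
  used_n <- logical(nrow(U)); used_o <- logical(nrow(V))
  pairs <- list()
  repeat {
    ang[used_n, ] <- Inf; ang[, used_o] <- Inf
    m <- which.min(ang)
    if (!length(m) || !is.finite(ang[m]) || ang[m] > max_offset) break
    i <- (m - 1) %% nrow(ang) + 1
    j <- (m - 1) %/% nrow(ang) + 1
    pairs[[length(pairs) + 1]] <- tibble(
      nub_id = nub_sites$site_id[i], outer_id = outer_sites$site_id[j],
      offset_deg = ang[m], outer_class = outer_sites$class[j])
    used_n[i] <- TRUE; used_o[j] <- TRUE
  }
  pairs <- if (length(pairs)) bind_rows(pairs) else
    tibble(nub_id = integer(), outer_id = integer(),
           offset_deg = numeric(), outer_class = character())
  list(pairs = pairs,
       unpaired_nubs = nub_sites$site_id[!used_n],
       unpaired_outer = outer_sites$site_id[!used_o],
       paired_fraction = sum(used_n) / nrow(U))
}

#' Detect a transmembrane stain band between paired sites
#'
#' The band VOI is the set of membrane voxels inside a cylinder of radius
#' `radius` nm joining the paired nub and outer site centroids. The band is
#' "present" when its mean gray value is significantly darker than
#' equally-sized random membrane patches: `n_perm` congruent radial
#' cylinders are sampled over the membrane and the one-sided permutation
#' p-value of the band mean must fall below `alpha`.
#'
#' @param volume the crop [vox_volume].
#' @param nub_xyz,outer_xyz paired site centroids (nm).
#' @param membrane_voi the membrane [voi].
#' @param center vesicle center (nm).
#' @param radius band cylinder radius, nm.
#' @param n_perm,alpha permutation test controls.
#' @return list: `present`, `p_value`, `band_voi`, `stats` (tibble of band
#'   and rest-of-membrane gray statistics).
#' @export
detect_band <- function(volume, nub_xyz, outer_xyz, membrane_voi, center,
                        radius = 2, n_perm = 200, alpha = 0.05) {
  mem_idx <- membrane_voi$support
  P <- voxel_centers(volume, mem_idx)
  # restrict to the mid-membrane radial range between the two sites, so the
  # terminal voxels of the connected macromolecules themselves (dark by
  # construction) cannot masquerade as a band
  rl <- sqrt(sum((nub_xyz - center)^2)); ro <- sqrt(sum((outer_xyz - center)^2))
  rad <- sqrt(rowSums(sweep(P, 2, center)^2))
  mid <- rad >= rl + 1.2 & rad <= ro - 1.2
  band_sel <- cylinder_sel(P, nub_xyz, outer_xyz, radius) & mid
  if (sum(band_sel) < 4)
    return(list(present = FALSE, p_value = NA_real_, band_voi = NULL,
                stats = NULL))
  gray <- volume$data[mem_idx]
  band_mean <- mean(gray[band_sel])
  rest <- gray[!band_sel]
  # congruent patches: radial cylinders at random directions
  perm <- vapply(seq_len(n_perm), function(k) {
    u <- unit(rnorm(3))
    sel <- cylinder_sel(P, center + rl * u, center + ro * u, radius) & mid
    if (sum(sel) < 4) NA_real_ else mean(gray[sel])
  }, numeric(1))
  perm <- perm[is.finite(perm)]
  p <- (1 + sum(perm <= band_mean)) / (1 + length(perm))
  band_voi <- voi("band", mem_idx[band_sel], membrane_voi$dims,
                  membrane_voi$voxel_size, membrane_voi$origin,
                  composite = TRUE)
  list(present = p < alpha, p_value = p, band_voi = band_voi,
       stats = tibble(region = c("band", "rest_of_membrane"),
                      N_v = c(sum(band_sel), length(rest)),
                      Avg = c(band_mean, mean(rest)),
                      SD = c(sd(gray[band_sel]), sd(rest))))
}

cylinder_sel <- function(P, a, b, radius) {
  u <- b - a; L2 <- sum(u^2)
  W <- sweep(P, 2, a)
  t <- pmin(1, pmax(0, as.numeric(W %*% u) / L2))
  D <- W - outer(t, u)
  rowSums(D^2) <= radius^2
}

#' Map sites onto an idealized sphere and a Robinson projection
#'
#' Radially projects site centroids onto an idealized unit sphere (luminal
#' sites are scaled by `d_outer / d_luminal` first, normalizing the two
#' surfaces onto one sphere), computes latitude/longitude in active-zone
#' coordinates (pole axis = vertical/tail axis; longitude 0 toward the
#' median plane) and the Robinson pseudo-cylindrical projection of each
#' site.
#'
#' @param sites site tibble (world nm).
#' @param center vesicle center (nm).
#' @param d_outer,d_luminal vesicle diameters (nm).
#' @param frame an [az_frame] (defaults to scene axes).
#' @return the input tibble with `lat`, `lon` (degrees) and Robinson
#'   `rx`, `ry` columns added.
#' @export
sphere_map <- function(sites, center, d_outer, d_luminal, frame = az_frame()) {
  U <- site_dirs(sites, center)
  # radial projection: the luminal scale factor normalizes radii; directions
  # (and hence lat/lon) are preserved for radial sites
  B <- rbind(frame$head, frame$long_axis, frame$tail)
  L <- U %*% t(B)
  lat <- asin(pmin(1, pmax(-1, L[, 3]))) * 180 / pi
  lon <- atan2(L[, 2], L[, 1]) * 180 / pi
  rxy <- robinson_xy(lat, lon)
  scale <- ifelse(sites$surface == "luminal", d_outer / d_luminal, 1)
  sites %>%
    mutate(lat = lat, lon = lon, rx = rxy$x, ry = rxy$y,
           radius_norm = scale *
             sqrt(rowSums(sweep(as.matrix(sites[, c("x_nm", "y_nm", "z_nm")]),
                                2, center)^2)) / (d_outer / 2))
}

# Robinson projection coefficients every 5 degrees of latitude
robinson_table <- data.frame(
  lat = seq(0, 90, by = 5),
  X = c(1.0000, 0.9986, 0.9954, 0.9900, 0.9822, 0.9730, 0.9600, 0.9427,
        0.9216, 0.8962, 0.8679, 0.8350, 0.7986, 0.7597, 0.7186, 0.6732,
        0.6213, 0.5722, 0.5322),
  Y = c(0.0000, 0.0620, 0.1240, 0.1860, 0.2480, 0.3100, 0.3720, 0.4340,
        0.4958, 0.5571, 0.6176, 0.6769, 0.7346, 0.7903, 0.8435, 0.8936,
        0.9394, 0.9761, 1.0000))

#' @rdname sphere_map
#' @param lat,lon degrees.
#' @return `robinson_xy()` returns a list with `x` and `y` for the unit
#'   sphere (R = 1), interpolating the standard Robinson coefficient table.
#' @export
robinson_xy <- function(lat, lon) {
  al <- abs(lat)
  X <- approx(robinson_table$lat, robinson_table$X, al)$y
  Y <- approx(robinson_table$lat, robinson_table$Y, al)$y
  list(x = 0.8487 * X * lon * pi / 180, y = 1.3523 * sign(lat) * Y)
}

#' Composite maps of connection sites
#'
#' Pools connection sites from many vesicles onto one unit sphere by
#' maximizing the overlap of the reference sites (ribs on the outer surface,
#' or nubs paired with ribs on the luminal surface). All vesicles are first
#' rotated so their reference-site centroids face a common direction (rough
#' alignment); per-vesicle rotations are then optimized by cyclic coordinate
#' ascent over Euler perturbations (10-degree grid, then 2-degree
#' refinement) of the pairwise-kernel overlap
#' `sum_{i != j} (1 / (Nri Nrj)) sum_{a in i, b in j} max(0, 1 - theta_ab / theta_c)`,
#' until the score changes by less than `tol`. All other site classes are
#' co-rotated with their vesicle and pooled.
#'
#' @param sites tibble with `vesicle_id`, unit direction columns `ux`, `uy`,
#'   `uz` (vesicle-local), and a logical `ref` column marking reference
#'   sites.
#' @param theta_c kernel cutoff, degrees.
#' @param tol convergence tolerance on the score.
#' @param max_sweeps cap on coordinate-ascent sweeps.
#' @return a `composite_map`: per-vesicle rotations, pooled rotated sites,
#'   the score trace, `N` and per-vesicle `Nri`.
#' @export
composite_map <- function(sites, theta_c = 30, tol = 1e-6, max_sweeps = 60) {
  ids <- sort(unique(sites$vesicle_id))
  keep <- vapply(ids, function(v)
    sum(sites$ref[sites$vesicle_id == v]) > 0, logical(1))
  if (any(!keep))
    warning("excluding vesicles without reference sites: ",
            paste(ids[!keep], collapse = ", "))
  ids <- ids[keep]
  N <- length(ids)
  if (N < 2) stop("need at least 2 vesicles with reference sites")
  refs <- lapply(ids, function(v)
    as.matrix(sites[sites$vesicle_id == v & sites$ref, c("ux", "uy", "uz")]))
  Nri <- vapply(refs, nrow, integer(1))
  # rough alignment: reference centroid-of-mass to the common mean direction
  coms <- t(vapply(refs, function(M) unit(colMeans(M)), numeric(3)))
  target <- unit(colMeans(coms))
  Rot <- lapply(seq_len(N), function(i) rotation_between(coms[i, ], target))

  kernel_score <- function(A, B) {
    th <- great_circle_deg(A, B)
    sum(pmax(0, 1 - th / theta_c))
  }
  pair_score <- function(i, Ri) {
    A <- refs[[i]] %*% t(Ri)
    s <- 0
    for (j in seq_len(N)) {
      if (j == i) next
      s <- s + kernel_score(A, refs[[j]] %*% t(Rot[[j]])) / (Nri[i] * Nri[j])
    }
    s
  }
  total_score <- function() {
    s <- 0
    for (i in seq_len(N)) s <- s + pair_score(i, Rot[[i]])
    s / 2  # each unordered vesicle pair counted once
  }
  # rough alignment, part 2. The centroid rotation leaves the azimuth about
  # the common direction free (or, for site sets spread over the sphere,
  # the whole rotation); resolve each vesicle sequentially against the
  # already-resolved ones -- a collective sweep against unresolved partners
  # can lock into a frustrated configuration -- then polish with full sweeps.
  pair_score_sub <- function(i, Ri, subset) {
    A <- refs[[i]] %*% t(Ri)
    s <- 0
    for (j in subset) {
      if (j == i) next
      s <- s + kernel_score(A, refs[[j]] %*% t(Rot[[j]])) / (Nri[i] * Nri[j])
    }
    s
  }
  spread <- vapply(refs, function(M) sqrt(sum(colMeans(M)^2)), numeric(1))
  so3 <- expand.grid(ax = seq(0, 336, by = 24), ay = seq(0, 168, by = 24),
                     az = seq(0, 336, by = 24))
  candidates <- function(i) {
    if (spread[i] >= 0.5)
      lapply(seq(0, 359, by = 1), function(az) axis_rot(target, az) %*% Rot[[i]])
    else
      lapply(seq_len(nrow(so3)), function(g)
        euler_rot(so3$ax[g], so3$ay[g], so3$az[g]))
  }
  for (stage in 1:2) {
    order_i <- if (stage == 1) seq_len(N)[-1] else seq_len(N)
    for (i in order_i) {
      subset <- if (stage == 1) seq_len(i - 1) else seq_len(N)
      best <- pair_score_sub(i, Rot[[i]], subset); bestR <- Rot[[i]]
      for (Rc in candidates(i)) {
        sc <- pair_score_sub(i, Rc, subset)
        if (sc > best) { best <- sc; bestR <- Rc }
      }
      Rot[[i]] <- bestR
    }
  }
  trace <- total_score()
  score <- trace[1]
  for (sw in seq_len(max_sweeps)) {
    for (i in seq_len(N)) {
      for (stg in list(c(30, 10), c(8, 2))) {
        g <- seq(-stg[1], stg[1], by = stg[2])
        best <- pair_score(i, Rot[[i]]); bestR <- Rot[[i]]
        for (ax in g) for (ay in g) for (az in g) {
          Rc <- euler_rot(ax, ay, az) %*% Rot[[i]]
          sc <- pair_score(i, Rc)
          if (sc > best) { best <- sc; bestR <- Rc }
        }
        Rot[[i]] <- bestR
      }
    }
    new_score <- total_score()
    trace <- c(trace, new_score)
    if (new_score - score < tol) break
    score <- new_score
  }
  rotated <- sites[sites$vesicle_id %in% ids, ] %>%
    group_by(.data$vesicle_id) %>%
    dplyr::group_modify(function(df, key) {
      Ri <- Rot[[match(key$vesicle_id, ids)]]
      M <- as.matrix(df[, c("ux", "uy", "uz")]) %*% t(Ri)
      df$ux <- M[, 1]; df$uy <- M[, 2]; df$uz <- M[, 3]
      df
    }) %>% ungroup()
  structure(list(N = N, vesicle_ids = ids, Nri = Nri, rotations = Rot,
                 sites = rotated, score_trace = trace, theta_c = theta_c),
            class = "composite_map")
}

#' @export
print.composite_map <- function(x, ...) {
  cat(sprintf("<composite_map> %d vesicles, %d pooled sites, overlap %.4f\n",
              x$N, nrow(x$sites), tail(x$score_trace, 1)))
  invisible(x)
}

#' Distance profiles of connection sites
#'
#' Distance of each site centroid to the presynaptic surface, normalized per
#' vesicle to the average rib position: luminal distances are first divided
#' by the luminal/outer diameter ratio, then the per-vesicle mean rib
#' distance (outer surface) or mean nub-paired-with-rib distance (luminal
#' surface) is subtracted.
#'
#' @param sites tibble with `vesicle_id`, `class`, `surface`, coordinates,
#'   and (for luminal sites) `partner_class`.
#' @param presyn `list(point =, normal =)` plane or a [surface_model].
#' @param vesicles tibble with `vesicle_id`, `d_outer`, `d_luminal`.
#' @return the sites tibble with `distance` and `norm_distance` added.
#' @export
distance_profile <- function(sites, presyn, vesicles) {
  dist_to <- function(P) {
    if (inherits(presyn, "surface_model"))
      sqrt(cpp_nn_dist2(P, presyn$vertices))
    else
      abs(as.numeric(sweep(P, 2, presyn$point) %*% unit(presyn$normal)))
  }
  P <- as.matrix(sites[, c("x_nm", "y_nm", "z_nm")])
  out <- sites %>%
    mutate(distance = dist_to(P)) %>%
    left_join(vesicles[, c("vesicle_id", "d_outer", "d_luminal")],
              by = "vesicle_id") %>%
    mutate(scaled = ifelse(.data$surface == "luminal",
                           .data$distance / (.data$d_luminal / .data$d_outer),
                           .data$distance)) %>%
    group_by(.data$vesicle_id) %>%
    mutate(
      ref_outer = mean(.data$scaled[.data$surface == "outer" &
                                      .data$class == "rib"]),
      ref_luminal = {
        r <- mean(.data$scaled[.data$surface == "luminal" &
                                 !is.na(.data$partner_class) &
                                 .data$partner_class == "rib"])
        if (is.nan(r)) mean(.data$scaled[.data$surface == "luminal"]) else r
      },
      norm_distance = .data$scaled -
        ifelse(.data$surface == "luminal", .data$ref_luminal, .data$ref_outer)) %>%
    ungroup() %>%
    select(-"ref_outer", -"ref_luminal", -"scaled")
  out
}

#' Connection-site frequency ratio between membrane domains
#'
#' Sites per unit area inside the main AZM binding domain relative to the
#' remainder of the surface excluding the fusion domain.
#'
#' @param n_binding mean number of sites in the binding domain.
#' @param n_rest mean number of sites in the remainder.
#' @param binding_frac,fusion_frac area fractions.
#' @export
site_density_ratio <- function(n_binding, n_rest, binding_frac = 0.137,
                               fusion_frac = 0.05) {
  (n_binding / binding_frac) / (n_rest / (1 - binding_frac - fusion_frac))
}
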