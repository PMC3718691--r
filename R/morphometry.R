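#' Vesicle diameters by the equator-slice five-axis method
#'
#' Finds the virtual slice through the vesicle's equator (the z-slice with
#' the largest membrane cross-section), then measures diameters to the outer
#' and luminal membrane surfaces along four in-plane axes at 45-degree
#' increments plus the depth axis, and reports the average of the five.
#' Edges are located on radial gray profiles (averaged over a small ray
#' bundle for robustness to particulate staining) at the half-contrast level
#' between background and membrane gray.
#'
#' @param volume a [vox_volume] (the vesicle crop).
#' @param vesicle_voi the membrane [voi].
#' @return a `diameter_set`: list with `d_outer`, `d_luminal`, per-axis
#'   measurements and the equator slice index.
#' @export
vesicle_diameters <- function(volume, vesicle_voi) {
  stopifnot(inherits(vesicle_voi, "voi"))
  d <- vesicle_voi$dims
  sup <- voi_logical(vesicle_voi, "support")
  # bounding-box center of the shell: robust to the asymmetric stain load
  # of bands and macromolecule stubs on the AZM-facing side
  ijk <- which(sup, arr.ind = TRUE)
  center <- (apply(ijk, 2, min) + apply(ijk, 2, max)) / 2 - 0.5
  equator <- max(1, min(d[3], round(center[3] + 0.5)))
  sl <- sup[, , equator]
  if (sum(sl) < 20) stop("measurement error: membrane VOI too sparse at equator")

  axes <- rbind(c(1, 0, 0), c(1, 1, 0) / sqrt(2), c(0, 1, 0),
                c(-1, 1, 0) / sqrt(2), c(0, 0, 1))
  rmax <- min(d) / 2 - 2
  rays <- do.call(rbind, lapply(seq_len(nrow(axes)), function(a)
    rbind(one_ray(volume, center, axes[a, ], rmax),
          one_ray(volume, center, -axes[a, ], rmax))))
  # a ray that stays flagged after its angular retries crosses stained
  # structure at the luminal surface; its luminal radius is imputed with
  # the median of the clean rays (the outer edge is robust regardless)
  bad <- rays[, "ok"] < 0.5
  if (any(bad) && any(!bad))
    rays[bad, "luminal"] <- median(rays[!bad, "luminal"])
  per_axis <- function(col) rays[seq(1, 9, 2), col] + rays[seq(2, 10, 2), col]
  out <- list(d_outer = mean(per_axis("outer")) * volume$voxel_size,
              d_luminal = mean(per_axis("luminal")) * volume$voxel_size,
              per_axis_outer = per_axis("outer") * volume$voxel_size,
              per_axis_luminal = per_axis("luminal") * volume$voxel_size,
              equator = equator, center = center)
  if (!(out$d_luminal < out$d_outer))
    stop("measurement error: luminal diameter not smaller than outer")
  class(out) <- "diameter_set"
  out
}

#' @export
print.diameter_set <- function(x, ...) {
  cat(sprintf("<diameter_set> d_outer %.2f nm, d_luminal %.2f nm (equator slice %d)\n",
              x$d_outer, x$d_luminal, x$equator))
  invisible(x)
}

# one membrane-edge measurement along a ray through the center (voxel
# units). Rays corrupted by a stained macromolecule crossing the membrane
# surface (dark run too thick, or no bright plateau beside an edge) are
# retried at small angular perturbations; thin structures are missed by
# the tilted ray.
one_ray <- function(volume, center, dir, rmax) {
  dir <- unit(dir)
  e <- ray_membrane_edges(volume, center, dir, rmax)
  if (isTRUE(e["ok"] > 0.5)) return(e)
  base <- perp_basis(dir)
  for (ang in c(5, -5, 9, -9)) {
    for (tv in base) {
      d2 <- unit(cos(ang * pi / 180) * dir + sin(ang * pi / 180) * tv)
      e2 <- ray_membrane_edges(volume, center, d2, rmax)
      if (isTRUE(e2["ok"] > 0.5)) return(e2)
      if (is.na(e["outer"])) e <- e2
    }
  }
  if (is.na(e["outer"]))
    stop("measurement error: no membrane band on any ray near this axis")
  e
}

perp_basis <- function(u) {
  t1 <- unit(if (abs(u[3]) < 0.9) c(-u[2], u[1], 0) else c(1, 0, 0) - u[1] * u)
  t2 <- c(u[2] * t1[3] - u[3] * t1[2], u[3] * t1[1] - u[1] * t1[3],
          u[1] * t1[2] - u[2] * t1[1])
  list(t1, t2)
}

# walk a radial gray profile outward and locate the membrane band:
# runs below the half-contrast level, merged across sub-resolution gaps,
# longer than a minimum thickness; outermost such run wins.
ray_membrane_edges <- function(volume, center, u, rmax, step = 0.25) {
  u <- unit(u)
  r <- seq(0.5, rmax, by = step)
  # small bundle of parallel rays for robustness to stain particles
  t1 <- unit(if (abs(u[3]) < 0.9) c(-u[2], u[1], 0) else c(1, 0, 0) - u[1] * u)
  t2 <- c(u[2] * t1[3] - u[3] * t1[2], u[3] * t1[1] - u[1] * t1[3],
          u[1] * t1[2] - u[2] * t1[1])
  offs <- rbind(c(0, 0, 0), t1, -t1, t2, -t2)
  prof <- rowMeans(vapply(seq_len(nrow(offs)), function(o) {
    pts <- outer(r, u) + matrix(center + offs[o, ], length(r), 3, byrow = TRUE)
    cpp_sample_trilinear(as.numeric(volume$data), dim(volume$data), pts)
  }, numeric(length(r))))
  prof <- stats::filter(prof, rep(1 / 5, 5), sides = 2)
  ok <- !is.na(prof)
  # run-detection level between the bright plateau and the dark structures,
  # from quantiles (robust to deep stain-particle minima and to rays that
  # are mostly dark)
  level <- (quantile(prof[ok], 0.9) + quantile(prof[ok], 0.08)) / 2
  dark <- ok & prof < level
  runs <- rle(as.vector(dark))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  seg <- data.frame(start = starts[runs$values], end = ends[runs$values])
  if (nrow(seg) == 0) return(c(outer = NA_real_, luminal = NA_real_, ok = 0))
  # merge runs separated by less than 1.5 voxels (stain gaps)
  merged <- seg[1, , drop = FALSE]
  for (i in seq_len(nrow(seg))[-1]) {
    if ((seg$start[i] - merged$end[nrow(merged)]) * step < 1.5)
      merged$end[nrow(merged)] <- seg$end[i]
    else merged <- rbind(merged, seg[i, ])
  }
  thick <- (merged$end - merged$start + 1) * step
  cand <- merged[thick >= 4, , drop = FALSE]
  if (nrow(cand) == 0) return(c(outer = NA_real_, luminal = NA_real_, ok = 0))
  plateau <- function(i_dark, dir) {
    out_idx <- i_dark - dir * seq(ceiling(1 / step), ceiling(3 / step))
    out_idx <- out_idx[out_idx >= 1 & out_idx <= length(prof)]
    median(prof[out_idx], na.rm = TRUE)
  }
  run_level <- function(b) {
    mid <- b$start + round((b$end - b$start) * c(0.25, 0.75))
    median(prof[mid[1]:mid[2]], na.rm = TRUE)
  }
  run_ok <- function(b) {
    ml <- run_level(b)
    (b$end - b$start + 1) * step <= 14 &&
      isTRUE(plateau(b$end, -1) - ml > 40) &&
      isTRUE(plateau(b$start, 1) - ml > 40)
  }
  # outermost run with clean bright plateaus on both sides; if none is
  # clean, keep the outermost run and flag the ray for a retry
  band <- NULL; ok <- FALSE
  r_outermost <- r[cand$end[nrow(cand)]]
  for (ci in rev(seq_len(nrow(cand)))) {
    # only runs ending near the outermost run can be the membrane; anything
    # deeper is luminal structure (the luminal surface sits at >= ~0.62 of
    # the outer radius, so an inner run's END is well below this cut)
    if (r[cand$end[ci]] < 0.8 * r_outermost) break
    if (run_ok(cand[ci, ])) { band <- cand[ci, ]; ok <- TRUE; break }
  }
  if (is.null(band)) band <- cand[nrow(cand), ]
  mem_level <- run_level(band)
  edge_at <- function(i_dark, dir) {
    # dir = -1: walk outward past band end; dir = +1: walk inward from start.
    # Local background plateau 1..3 nm beyond the edge, then interpolate the
    # half-contrast crossing on the smoothed profile.
    out_idx <- i_dark - dir * seq(ceiling(1 / step), ceiling(3 / step))
    out_idx <- out_idx[out_idx >= 1 & out_idx <= length(prof)]
    bg_level <- median(prof[out_idx], na.rm = TRUE)
    if (!is.finite(bg_level) || bg_level <= mem_level) return(r[i_dark])
    lev <- (bg_level + mem_level) / 2
    i <- i_dark
    while (TRUE) {
      j <- i - dir
      if (j < 1 || j > length(prof) || is.na(prof[j])) return(r[i])
      if (prof[j] >= lev) {
        f <- (lev - prof[i]) / (prof[j] - prof[i])
        return(r[i] + f * (r[j] - r[i]))
      }
      i <- j
    }
  }
  c(outer = edge_at(band$end, -1), luminal = edge_at(band$start, 1),
    ok = as.numeric(ok))
}

#' Sphere and spherical-zone surface areas
#'
#' The vesicle membrane surface is treated as a sphere: `SA_SV = pi d_SV^2`.
#' The main AZM binding domain is treated as a spherical zone (a region of a
#' sphere cut off by a plane) whose base circle has chord diameter `d_AZM`
#' (the maximum distance from the average rib connection site to the
#' furthest boom): `SA_AZM = 2 pi R h` with `R = d_SV / 2` and
#' `h = R - sqrt(R^2 - (d_AZM / 2)^2)`.
#'
#' @param d_SV vesicle outer diameter, nm.
#' @param d_AZM chord diameter of the zone's base circle, nm.
#' @param fusion_fraction area fraction of the fusion domain (carried through
#'   into the report).
#' @return an `area_report` tibble row: `SA_SV`, `d_AZM`, `SA_AZM`,
#'   `zone_fraction`, `fusion_fraction`.
#' @export
sphere_and_zone_areas <- function(d_SV, d_AZM, fusion_fraction = NA_real_) {
  if (any(d_AZM <= 0) || any(d_SV <= 0) || any(d_AZM > d_SV))
    stop("domain error: need 0 < d_AZM <= d_SV")
  R <- d_SV / 2
  h <- R - sqrt(pmax(0, R^2 - (d_AZM / 2)^2))
  tibble(SA_SV = pi * d_SV^2, d_AZM = d_AZM, SA_AZM = 2 * pi * R * h,
         zone_fraction = (2 * pi * R * h) / (pi * d_SV^2),
         fusion_fraction = fusion_fraction)
}

#' Binding-domain area fraction from extracted connection sites
#'
#' Computes `d_AZM` -- the maximum distance from the average rib connection
#' site to the furthest boom -- with all sites first projected radially onto
#' the vesicle's outer sphere (connection sites live on the membrane
#' surface; extracted terminal-voxel centroids sit a fraction of a voxel off
#' it), then applies the spherical-zone formula.
#'
#' @param sites tibble with `class` and `x_nm`, `y_nm`, `z_nm` columns.
#' @param center vesicle center (nm).
#' @param d_sv vesicle outer diameter (nm).
#' @return the zone area fraction (scalar), or `NA` if ribs or booms are
#'   missing.
#' @export
binding_domain_fraction <- function(sites, center, d_sv) {
  ribs <- sites[sites$class == "rib", ]
  booms <- sites[sites$class == "boom", ]
  if (nrow(ribs) == 0 || nrow(booms) == 0) return(NA_real_)
  proj <- function(df) {
    P <- sweep(as.matrix(df[, c("x_nm", "y_nm", "z_nm")]), 2, center)
    P / sqrt(rowSums(P^2)) * (d_sv / 2)
  }
  rib_avg <- colMeans(proj(ribs))
  d_azm <- sqrt(max(rowSums(sweep(proj(booms), 2, rib_avg)^2)))
  sphere_and_zone_areas(d_sv, min(d_azm, d_sv))$zone_fraction
}

#' Lumen fill fraction
#'
#' Fraction of the luminal voxels confined to the stained assembly:
#' `|assembly support| / |lumen support|`. The assembly support is clipped to
#' the lumen; the number of clipped voxels is reported via a message when
#' non-zero.
#'
#' @param lumen_voi,assembly_voi [voi]s on the same grid.
#' @return the fill fraction (scalar).
#' @export
lumen_fill_fraction <- function(lumen_voi, assembly_voi) {
  stopifnot(all(lumen_voi$dims == assembly_voi$dims))
  if (length(lumen_voi$support) == 0) stop("domain error: empty lumen")
  clipped <- setdiff(assembly_voi$support, lumen_voi$support)
  if (length(clipped) > 0)
    message(length(clipped), " assembly voxels clipped outside the lumen")
  length(intersect(assembly_voi$support, lumen_voi$support)) /
    length(lumen_voi$support)
}

#' Segment the lumen as the membrane interior
#'
#' Flood-fills the vesicle interior from its center through the complement of
#' the (dilated) membrane mask, then grows the result back by one voxel and
#' removes membrane support voxels, so the lumen boundary sits at the
#' membrane's luminal isodensity edge.
#'
#' @param membrane_voi the segmented membrane [voi].
#' @return a lumen [voi].
#' @export
lumen_from_membrane <- function(membrane_voi) {
  d <- membrane_voi$dims
  blocked <- logical(prod(d))
  blocked[membrane_voi$mask] <- TRUE
  sup <- voi_logical(membrane_voi, "support")
  ij <- which(sup)
  ctr <- round(colMeans(cbind((ij - 1) %% d[1], ((ij - 1) %/% d[1]) %% d[2],
                              (ij - 1) %/% (d[1] * d[2]))))
  seed <- ctr[1] + d[1] * (ctr[2] + d[2] * ctr[3])
  vis <- cpp_flood6(blocked, d, seed)
  if (!any(vis)) stop("segmentation error: vesicle center lies inside the membrane mask")
  grown <- cpp_dilate26(vis, d)
  grown[membrane_voi$support] <- FALSE
  voi("lumen", which(grown), d, membrane_voi$voxel_size, membrane_voi$origin,
      mask = which(cpp_dilate26(grown, d)))
}
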