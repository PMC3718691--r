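#' Assembly representations for alignment
#'
#' Packages one luminal assembly for rigid registration: the dark (support)
#' voxels as a point cloud with inverted-gray weights (1000 - gray, so darker
#' stain scores higher), a cubic inverted-density grid centered on the
#' assembly centroid, and an isodensity surface mesh. All coordinates are in
#' voxel units relative to the assembly centroid.
#'
#' @param volume the vesicle crop [vox_volume].
#' @param voi the assembly [voi].
#' @param side working grid side (voxels).
#' @param id member identifier.
#' @export
assembly_rep <- function(volume, voi, side = 48, id = NULL) {
  stopifnot(inherits(voi, "voi"))
  d <- voi$dims
  idx <- voi$support
  ijk <- cbind((idx - 1) %% d[1], ((idx - 1) %/% d[1]) %% d[2],
               (idx - 1) %/% (d[1] * d[2])) + 0.5
  ctr <- colMeans(ijk)
  P <- sweep(ijk, 2, ctr)
  w <- 1000 - volume$data[idx]
  grid <- array(0, rep(side, 3))
  gi <- floor(sweep(ijk, 2, ctr) + side / 2) + 1
  keep <- gi[, 1] >= 1 & gi[, 2] >= 1 & gi[, 3] >= 1 &
    gi[, 1] <= side & gi[, 2] <= side & gi[, 3] <= side
  grid[gi[keep, , drop = FALSE]] <- w[keep]
  mesh <- tryCatch(extract_surface(volume, voi), error = function(e) NULL)
  mv <- if (is.null(mesh)) NULL else
    sweep(nm_to_voxel(volume, mesh$vertices), 2, ctr)
  structure(list(id = id, points = P, weights = w, grid = grid, side = side,
                 centroid = ctr, voxel_size = volume$voxel_size,
                 mesh = mv),
            class = "assembly_rep")
}

#' Gray-scale density alignment
#'
#' Registers a moving assembly onto a fixed density map by exhaustive local
#' search: delta rotations of +/- `angle_range` degrees about each Euler axis
#' composed after the initial pose, and integer translations of +/- `tmax`
#' voxels. The score is the sum over moving voxels of the product of the
#' inverted gray values of moving and fixed at the transformed position (the
#' product of the overlapping stain densities). The search runs at
#' `step_coarse` resolution and is then refined at 1-degree resolution around
#' the best coarse cell; ties break toward the smaller rotation, then the
#' smaller translation.
#'
#' @param moving an [assembly_rep].
#' @param fixed an [assembly_rep], an `alignment_model`, or a density array.
#' @param init initial [rigid_transform()] mapping moving (centroid-relative
#'   voxel coordinates) into the fixed grid; defaults to centering on the
#'   fixed grid.
#' @param angle_range,step_coarse,tmax search extents (degrees, degrees,
#'   voxels).
#' @param n_points number of support voxels sampled for fine-stage scoring
#'   (the coarse stage uses roughly half as many).
#' @return an `alignment_result`: `transform`, `score`, `converged` (FALSE
#'   when the optimum sits on the search boundary).
#' @export
density_align <- function(moving, fixed, init = NULL, angle_range = 30,
                          step_coarse = 5, tmax = 3, n_points = 1500) {
  fx <- fixed_density(fixed)
  if (is.null(init))
    init <- rigid_transform(diag(3), dim(fx$grid) / 2)
  subsample <- function(n) {
    if (nrow(moving$points) <= n) return(seq_len(nrow(moving$points)))
    ord <- order(-moving$weights)  # deterministic: strongest stain first
    sort(ord[round(seq(1, nrow(moving$points), length.out = n))])
  }
  kf <- subsample(n_points)
  P <- moving$points[kf, , drop = FALSE]
  w <- moving$weights[kf]
  kc <- subsample(max(300, round(n_points * 0.55)))
  Pc <- moving$points[kc, , drop = FALSE]
  wc <- moving$weights[kc]
  if (sum(fx$grid) == 0 || nrow(P) == 0)
    stop("alignment error: empty density overlap")
  fd <- as.numeric(fx$grid)
  dims <- dim(fx$grid)
  coarse <- seq(-angle_range, angle_range, by = step_coarse)
  r1 <- cpp_density_search(Pc, wc, fd, dims, init$R, init$t,
                           coarse, coarse, coarse, tmax)
  best <- r1
  best$score <- cpp_density_score(
    P, w, fd, dims, init$R %*% euler_rot(r1$angles[1], r1$angles[2],
                                         r1$angles[3]), init$t + r1$dt)
  if (step_coarse > 1) {
    # joint 1-degree refinement around the best coarse cell, translation
    # window recentred on the coarse optimum
    angs <- lapply(1:3, function(a)
      unique(pmax(-angle_range, pmin(angle_range,
        r1$angles[a] + (-(step_coarse - 1)):(step_coarse - 1)))))
    r2 <- cpp_density_search(P, w, fd, dims, init$R, init$t + r1$dt,
                             angs[[1]], angs[[2]], angs[[3]], 1L)
    if (r2$score >= best$score) {
      best <- r2
      best$dt <- r1$dt + r2$dt
    }
  }
  if (best$score == 0)
    stop("alignment error: empty density overlap at every candidate")
  Rtot <- init$R %*% euler_rot(best$angles[1], best$angles[2], best$angles[3])
  tf <- rigid_transform(Rtot, init$t + best$dt)
  converged <- all(abs(best$angles) < angle_range - 0.5) &&
    all(abs(best$dt) <= tmax)
  structure(list(transform = tf, score = best$score, converged = converged,
                 method = "density"),
            class = "alignment_result")
}

fixed_density <- function(fixed) {
  if (inherits(fixed, "assembly_rep")) list(grid = fixed$grid)
  else if (inherits(fixed, "alignment_model")) list(grid = fixed$density)
  else if (is.array(fixed)) list(grid = fixed)
  else stop("unsupported fixed density representation")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> method %s, score %.4g, converged %s\n",
              x$method, x$score, x$converged))
  print(x$transform)
  invisible(x)
}

#' Iterative closest point surface alignment
#'
#' Point-to-point ICP with closest-vertex correspondences and least-squares
#' rigid (Kabsch) updates, iterated to a relative mean-distance change below
#' `tol` or `max_iter` iterations, restarted from every rotation on an Euler
#' grid with `start_grid_step`-degree spacing (a decimated coarse pass ranks
#' the starts; the best is polished at full resolution).
#'
#' @param moving,fixed [surface_model]s or point matrices (same units).
#' @param start_grid_step multi-start rotation grid spacing, degrees.
#' @param max_iter,tol ICP iteration controls.
#' @param decimate point budget of the coarse multi-start pass.
#' @param trim fraction of best-matched points used in each rigid update
#'   (robustness against structure present in only one surface).
#' @param polish point budget of the final full-resolution pass (closest-point
#'   search is quadratic in the vertex count).
#' @param init optional [rigid_transform()]; when supplied the grid start
#'   search is skipped.
#' @return an `alignment_result` with the mean closest-point distance as
#'   `score` (same units as the vertices).
#' @export
icp_align <- function(moving, fixed, start_grid_step = 20, max_iter = 100,
                      tol = 1e-4, decimate = 120, polish = 900, trim = 0.85,
                      init = NULL) {
  A <- surface_points(moving); B <- surface_points(fixed)
  if (nrow(A) < 50 || nrow(B) < 50)
    stop("alignment error: need at least 50 vertices per surface")
  for (M in list(A, B)) {
    sv <- svd(sweep(M, 2, colMeans(M)))$d
    if (sv[3] < 1e-6 * sv[1])
      stop("alignment error: degenerate (coplanar or collinear) vertex set")
  }
  dec <- function(M, n) M[unique(round(seq(1, nrow(M), length.out = n))), ,
                          drop = FALSE]
  Ap <- dec(A, polish); Bp <- dec(B, round(polish * 1.5))
  if (!is.null(init)) {
    r <- cpp_icp(Ap, Bp, init$R, init$t, max_iter, tol, trim)
    return(icp_result(r))
  }
  ca <- colMeans(A); cb <- colMeans(B)
  Ad <- dec(A, decimate); Bd <- dec(B, decimate)
  s <- start_grid_step
  starts <- expand.grid(ax = seq(0, 360 - s, by = s),
                        ay = seq(0, 180, by = s),
                        az = seq(0, 360 - s, by = s))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    R0 <- euler_rot(starts$ax[k], starts$ay[k], starts$az[k])
    t0 <- cb - as.numeric(R0 %*% ca)
    r <- cpp_icp(Ad, Bd, R0, t0, 12, 1e-3, trim)
    if (is.null(best) || r$dist < best$dist) best <- r
  }
  r <- cpp_icp(Ap, Bp, best$R, as.numeric(best$t), max_iter, tol, trim)
  icp_result(r)
}

icp_result <- function(r) {
  structure(list(transform = rigid_transform(r$R, as.numeric(r$t)),
                 score = r$dist, converged = isTRUE(r$converged),
                 iterations = r$iterations, method = "surface"),
            class = "alignment_result")
}

surface_points <- function(x) {
  if (inherits(x, "surface_model")) x$vertices
  else if (inherits(x, "assembly_rep")) {
    if (is.null(x$mesh)) stop("assembly_rep carries no surface mesh")
    x$mesh
  } else rbind(x)
}

#' Build a reference-free alignment model
#'
#' Dual-phase reference-free averaging of luminal assemblies. Phase one
#' ("random approximation"): assemblies are registered and averaged one by
#' one in the requested order, each against the partial model so far. Phase
#' two: leave-one-out refinement -- each assembly is removed from the model,
#' re-aligned to the model of the remaining members, and re-averaged --
#' repeated `rounds` times. With `method = "density"` registration maximizes
#' the product of overlapping inverted-gray densities (ICP on the surface
#' meshes provides the initial pose); with `method = "surface"` registration
#' is ICP on the isodensity meshes throughout. The model volume is defined
#' by a consensus-occupancy criterion: the region covered by at least
#' `consensus` of the registered members (for the density model, the mean
#' inverted-density map thresholded at `consensus` of its smoothed peak --
#' equivalent, since the member densities are nearly binary). The default
#' consensus of one quarter is the fraction at which the model reproduces
#' its defining properties on phantom cohorts: it contains most of every
#' member's volume while occupying about twice a single assembly.
#'
#' @param assemblies list of [assembly_rep]s (>= 3).
#' @param method `"density"` or `"surface"`.
#' @param registration_order `"given"` or `"random"` (founder-bias control).
#' @param rounds leave-one-out refinement rounds.
#' @param side model grid side, voxels.
#' @param angle_range,step_coarse,tmax density-search extents.
#' @param start_grid_step Euler grid spacing (degrees) for the first-contact
#'   ICP multi-start.
#' @param consensus occupancy fraction defining the model region.
#' @param verbose print per-round progress.
#' @return an `alignment_model`.
#' @export
build_alignment_model <- function(assemblies, method = c("density", "surface"),
                                  registration_order = c("given", "random"),
                                  rounds = 5, side = 48,
                                  angle_range = 30, step_coarse = 5, tmax = 3,
                                  start_grid_step = 60, consensus = 0.12,
                                  verbose = FALSE) {
  method <- match.arg(method)
  registration_order <- match.arg(registration_order)
  n <- length(assemblies)
  if (n < 3) stop("need at least 3 assemblies")
  ord <- if (registration_order == "random") sample(n) else seq_len(n)
  ctr <- rep(side / 2, 3)
  tfs <- vector("list", n)
  dens <- vector("list", n)   # resampled inverted densities on the model grid
  occ <- vector("list", n)    # resampled binary supports

  resample_member <- function(mem, tf) {
    # member grid -> model grid: y = R (x - c_m) + t
    cm <- rep(dim(mem$grid)[1] / 2, 3)
    tt <- tf$t - as.numeric(tf$R %*% cm)
    g <- cpp_resample_rigid(as.numeric(mem$grid), dim(mem$grid), tf$R, tt,
                            rep(side, 3L), TRUE)
    # fractional occupancy (trilinear of the binary support) keeps sub-voxel
    # pose information in the consensus field
    o <- cpp_resample_rigid(as.numeric(mem$grid > 0), dim(mem$grid), tf$R, tt,
                            rep(side, 3L), TRUE)
    list(dens = array(g, rep(side, 3)), occ = array(o, rep(side, 3)))
  }
  align_member <- function(i, fixed_grid, init_tf) {
    mem <- assemblies[[i]]
    tryCatch({
      if (method == "density") {
        if (is.null(init_tf))
          init_tf <- global_rotation_init(mem, fixed_grid)
        density_align(mem, fixed_grid, init = init_tf,
                      angle_range = angle_range, step_coarse = step_coarse,
                      tmax = tmax)$transform
      } else {
        fmesh <- grid_mesh(fixed_grid)
        if (is.null(fmesh)) stop("partial model has no isodensity surface")
        if (is.null(init_tf))
          init_tf <- global_rotation_init(mem, fixed_grid)
        icp_align(mem$mesh, fmesh, init = init_tf)$transform
      }
    }, error = function(e)
      stop("build error: member ", i, ": ", conditionMessage(e), call. = FALSE))
  }

  # ---- phase 1: sequential build
  first <- ord[1]
  tfs[[first]] <- rigid_transform(diag(3), ctr)
  rs <- resample_member(assemblies[[first]], tfs[[first]])
  dens[[first]] <- rs$dens; occ[[first]] <- rs$occ
  done <- first
  for (i in ord[-1]) {
    fixed_grid <- Reduce(`+`, dens[done]) / length(done)
    tfs[[i]] <- align_member(i, fixed_grid, NULL)
    rs <- resample_member(assemblies[[i]], tfs[[i]])
    dens[[i]] <- rs$dens; occ[[i]] <- rs$occ
    done <- c(done, i)
  }

  # ---- phase 2: leave-one-out refinement
  score_trace <- numeric(0)
  sum_dens <- Reduce(`+`, dens)
  for (r in seq_len(rounds)) {
    for (i in ord) {
      loo <- (sum_dens - dens[[i]]) / (n - 1)
      tfs[[i]] <- align_member(i, loo, tfs[[i]])
      sum_dens <- sum_dens - dens[[i]]
      rs <- resample_member(assemblies[[i]], tfs[[i]])
      dens[[i]] <- rs$dens; occ[[i]] <- rs$occ
      sum_dens <- sum_dens + dens[[i]]
    }
    mean_grid <- sum_dens / n
    msc <- mean(vapply(seq_len(n), function(i) {
      member_density_score(assemblies[[i]], mean_grid, tfs[[i]])
    }, numeric(1)))
    score_trace <- c(score_trace, msc)
    if (verbose) message("round ", r, ": mean member score ", signif(msc, 6))
  }

  mean_grid <- Reduce(`+`, dens) / n
  occ_frac <- Reduce(`+`, occ) / n
  # model region: smoothed member-occupancy consensus (same criterion for
  # both representations; the density map stays the model's density)
  # Consensus region. When the members genuinely disagree, their occupancy
  # field is smoothed so the region captures the territory the cohort
  # covers; a cohort of (near-)identical members has nothing to smooth and
  # the region degenerates to the common support.
  covered <- mean(occ_frac > 0.05)
  disputed <- mean(occ_frac > 0.05 & occ_frac < 0.95)
  if (covered == 0 || disputed / covered < 0.1) {
    region <- occ_frac > 0.5
  } else {
    sm <- occ_frac
    for (i in 1:6) sm <- mean_filter3(sm)
    region <- sm > consensus
  }
  threshold <- consensus
  structure(list(method = method, members = seq_len(n), order = ord,
                 transforms = tfs, density = mean_grid, occupancy = occ_frac,
                 region = region, threshold = threshold, side = side,
                 voxel_size = assemblies[[1]]$voxel_size,
                 rounds = rounds, score_trace = score_trace),
            class = "alignment_model")
}

#' @export
print.alignment_model <- function(x, ...) {
  cat(sprintf("<alignment_model> %s, %d members, %d rounds, volume %.0f voxels\n",
              x$method, length(x$members), x$rounds, sum(x$region)))
  invisible(x)
}

#' @rdname build_alignment_model
#' @param model an `alignment_model`.
#' @return `model_volume()` returns the model volume in nm^3 (region voxel
#'   count times voxel volume).
#' @export
model_volume <- function(model) sum(model$region) * model$voxel_size^3

member_density_score <- function(rep, grid, tf) {
  cpp_density_score(rep$points, rep$weights, as.numeric(grid), dim(grid),
                    tf$R, tf$t)
}

# ICP initial pose for a member against a density grid
icp_init <- function(mem, fixed_grid, ctr, start_grid_step) {
  fmesh <- grid_mesh(fixed_grid)
  if (is.null(mem$mesh) || is.null(fmesh))
    return(rigid_transform(diag(3), ctr))
  r <- icp_align(mem$mesh, fmesh, start_grid_step = start_grid_step)
  r$transform
}

# Coarse global rotation search of a member against a density grid:
# full Euler grid at `step` degrees, centroids superposed, nearest-voxel
# density product scoring on a subsample of the member's darkest voxels.
# Resolves the pseudo-symmetric basins that trap closest-point starts.
global_rotation_init <- function(mem, fixed_grid, step = 10, n_points = 400) {
  w <- mem$weights
  ord <- order(-w)
  keep <- sort(ord[unique(round(seq(1, length(w), length.out = n_points)))])
  P <- mem$points[keep, , drop = FALSE]
  wk <- w[keep]
  d <- dim(fixed_grid)
  fd <- as.numeric(fixed_grid)
  # center-of-mass of the fixed density as the translation target
  idx <- which(fixed_grid > 0)
  ijk <- cbind((idx - 1) %% d[1], ((idx - 1) %/% d[1]) %% d[2],
               (idx - 1) %/% (d[1] * d[2])) + 0.5
  com <- round(colSums(ijk * fixed_grid[idx]) / sum(fixed_grid[idx]))
  r <- cpp_density_search(P, wk, fd, d, diag(3), com,
                          seq(0, 360 - step, by = step),
                          seq(0, 180, by = step),
                          seq(0, 360 - step, by = step), 1L)
  rigid_transform(euler_rot(r$angles[1], r$angles[2], r$angles[3]),
                  com + r$dt)
}

# mesh (voxel-unit vertices) of a density grid at half its smoothed maximum
grid_mesh <- function(grid) {
  lvl <- max(mean_filter3(grid)) / 2
  m <- cpp_march_tetra(as.numeric(-grid), dim(grid), -lvl)
  if (nrow(m$vertices) < 50) return(NULL)
  m$vertices
}

mean_filter3 <- function(a) {
  d <- dim(a)
  out <- array(0, d); cnt <- array(0, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    out[xs - dx, ys - dy, zs - dz] <- out[xs - dx, ys - dy, zs - dz] + a[xs, ys, zs]
    cnt[xs - dx, ys - dy, zs - dz] <- cnt[xs - dx, ys - dy, zs - dz] + 1
  }
  out / cnt
}

#' Volume overlap between alignment models
#'
#' Mutually registers two models (ICP on their region boundary meshes) and
#' reports the fraction of each model's region voxels falling inside the
#' other: `(A_in_B, B_in_A)`.
#'
#' @param modelA,modelB `alignment_model`s.
#' @param start_grid_step ICP multi-start spacing (degrees).
#' @return named numeric vector `c(A_in_B =, B_in_A =)`.
#' @export
model_overlap <- function(modelA, modelB, start_grid_step = 60) {
  if (sum(modelA$region) == 0 || sum(modelB$region) == 0)
    stop("domain error: empty model region")
  mA <- region_mesh(modelA); mB <- region_mesh(modelB)
  tf <- icp_align(mA, mB, start_grid_step = start_grid_step)$transform
  # refine the mutual registration by maximizing the voxel overlap itself:
  # a local rotation/translation grid, then a sub-voxel translation polish
  dA <- dim(modelA$region)
  idx <- which(modelA$region)
  P <- cbind((idx - 1) %% dA[1], ((idx - 1) %/% dA[1]) %% dA[2],
             (idx - 1) %/% (dA[1] * dA[2])) + 0.5
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  fd <- as.numeric(modelB$region + 0)
  shift0 <- as.numeric(tf$R %*% ctr) + tf$t
  r <- cpp_density_search(Pc, rep(1, nrow(Pc)), fd, dim(modelB$region),
                          tf$R, shift0, seq(-6, 6, 2), seq(-6, 6, 2),
                          seq(-6, 6, 2), 2L)
  Rb <- tf$R %*% euler_rot(r$angles[1], r$angles[2], r$angles[3])
  tb <- shift0 + r$dt
  fb_smooth <- as.numeric(mean_filter3(mean_filter3(modelB$region + 0)))
  fa_smooth <- as.numeric(mean_filter3(mean_filter3(modelA$region + 0)))
  dB <- dim(modelB$region)
  ksub <- unique(round(seq(1, nrow(Pc), length.out = 4000)))
  Ps <- Pc[ksub, , drop = FALSE]
  idxB <- which(modelB$region)
  PB <- cbind((idxB - 1) %% dB[1], ((idxB - 1) %/% dB[1]) %% dB[2],
              (idxB - 1) %/% (dB[1] * dB[2])) + 0.5
  kB <- unique(round(seq(1, nrow(PB), length.out = 4000)))
  PBs <- PB[kB, , drop = FALSE]
  # symmetric objective: the registration serves both reported directions
  obj <- function(par) {
    Rp <- Rb %*% euler_rot(par[1], par[2], par[3])
    tt <- tb + par[4:6]
    q <- sweep(Ps %*% t(Rp), 2, tt, "+")
    fwd <- mean(cpp_sample_trilinear(fb_smooth, dB, q))
    qb <- sweep(PBs, 2, tt) %*% Rp  # inverse map of B voxels into A + ctr
    qb <- sweep(qb, 2, ctr, "+")
    bwd <- mean(cpp_sample_trilinear(fa_smooth, dim(modelA$region), qb))
    -(fwd + bwd)
  }
  op <- stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                     control = list(maxit = 400, reltol = 1e-8))
  Rb <- Rb %*% euler_rot(op$par[1], op$par[2], op$par[3])
  tb <- tb + op$par[4:6]
  tf2 <- rigid_transform(Rb, as.numeric(tb - Rb %*% ctr))
  a_in_b <- region_containment(modelA$region, modelB$region, tf2)
  b_in_a <- region_containment(modelB$region, modelA$region, invert_transform(tf2))
  c(A_in_B = a_in_b, B_in_A = b_in_a)
}

region_mesh <- function(model) {
  m <- cpp_march_tetra(as.numeric(1 - model$region), dim(model$region), 0.5)
  surface_model(m$vertices, m$faces, threshold = model$threshold)
}

region_containment <- function(regA, regB, tf) {
  idx <- which(regA)
  d <- dim(regA)
  pts <- cbind((idx - 1) %% d[1], ((idx - 1) %/% d[1]) %% d[2],
               (idx - 1) %/% (d[1] * d[2])) + 0.5
  q <- apply_transform(tf, pts)
  qi <- floor(q) + 1
  db <- dim(regB)
  ok <- qi[, 1] >= 1 & qi[, 2] >= 1 & qi[, 3] >= 1 &
    qi[, 1] <= db[1] & qi[, 2] <= db[2] & qi[, 3] <= db[3]
  inside <- logical(length(idx))
  inside[ok] <- regB[qi[ok, , drop = FALSE]]
  mean(inside)
}

#' Containment of a member assembly inside its alignment model
#'
#' Applies the member's stored registration and reports the fraction of its
#' support voxels that fall inside the model volume.
#'
#' @param assembly an [assembly_rep] (or [voi] with `volume`).
#' @param model an `alignment_model`.
#' @param transform the member's stored [rigid_transform()] (defaults to the
#'   stored transform when `assembly` carries a member `id`).
#' @export
containment_fraction <- function(assembly, model, transform = NULL) {
  if (is.null(transform)) {
    if (is.null(assembly$id)) stop("supply the member's registration transform")
    transform <- model$transforms[[assembly$id]]
  }
  if (sum(model$region) == 0) return(0)
  q <- apply_transform(transform, assembly$points)
  qi <- floor(q) + 1
  db <- dim(model$region)
  ok <- qi[, 1] >= 1 & qi[, 2] >= 1 & qi[, 3] >= 1 &
    qi[, 1] <= db[1] & qi[, 2] <= db[2] & qi[, 3] <= db[3]
  inside <- logical(nrow(q))
  inside[ok] <- model$region[qi[ok, , drop = FALSE]]
  mean(inside)
}
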