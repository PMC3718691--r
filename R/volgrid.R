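#' Voxel volumes
#'
#' The basic 3D container: a gray-scale grid (0-1000, 0 = black) with an
#' isotropic physical voxel size in nanometres. Voxel `(i, j, k)` (1-based)
#' has its center at `origin + (c(i, j, k) - 0.5) * voxel_size`.
#'
#' @param data a 3D numeric array.
#' @param voxel_size isotropic voxel edge length, nm (0.4-1.5 for tomographic
#'   reconstructions; values outside trigger a warning, not an error).
#' @param origin physical coordinate (nm) of the grid corner.
#' @param validate check gray range and voxel size.
#' @export
vox_volume <- function(data, voxel_size = 1, origin = c(0, 0, 0), validate = TRUE) {
  stopifnot(is.array(data), length(dim(data)) == 3, length(origin) == 3,
            is.numeric(voxel_size), voxel_size > 0)
  if (validate) {
    if (!all(is.finite(data))) stop("volume contains non-finite values")
    rng <- range(data)
    if (rng[1] < 0 || rng[2] > 1000)
      stop("gray values outside [0, 1000]: range ",
           paste(signif(rng, 4), collapse = " .. "))
    if (voxel_size < 0.4 || voxel_size > 1.5)
      warning("voxel size ", voxel_size, " nm outside the usual 0.4-1.5 nm range")
  }
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "vox_volume")
}

#' @export
print.vox_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vox_volume> %d x %d x %d voxels, %.3g nm/voxel, gray %.0f..%.0f\n",
              d[1], d[2], d[3], x$voxel_size, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.vox_volume <- function(x) dim(x$data)

# physical centers (nm) of 1-based voxel indices (n x 3 matrix)
voxel_centers <- function(volume, idx) {
  d <- dim(volume$data)
  ijk <- cbind((idx - 1) %% d[1], ((idx - 1) %/% d[1]) %% d[2],
               (idx - 1) %/% (d[1] * d[2]))
  sweep((ijk + 0.5) * volume$voxel_size, 2, volume$origin, "+")
}

# nm coordinates -> continuous voxel units (center of voxel i at i - 0.5, 1-based)
nm_to_voxel <- function(volume, xyz) {
  sweep(rbind(xyz), 2, volume$origin, "-") / volume$voxel_size
}

#' Volumes of interest
#'
#' A VOI is the voxel mask delimiting one segmented structure. It stores both
#' the thresholded connected component (`support`) and a 1-voxel dilation of
#' it (`mask`): the dilated mask is "slightly larger" than the structure so
#' that isodensity surface extraction has room to interpolate, while voxel
#' counts and volume ratios use the support.
#'
#' @param label structure class label.
#' @param support integer vector of 1-based flat voxel indices.
#' @param mask dilated index set (defaults to `support` dilated by 1 voxel).
#' @param dims parent grid dimensions.
#' @param voxel_size,origin parent grid geometry.
#' @param composite allow multiple connected components.
#' @param threshold gray threshold that produced the support (or NA).
#' @export
voi <- function(label, support, dims, voxel_size = 1, origin = c(0, 0, 0),
                mask = NULL, composite = FALSE, threshold = NA_real_) {
  support <- sort(unique(as.integer(support)))
  if (length(support) == 0) stop("empty VOI for label '", label, "'")
  if (is.null(mask)) {
    m <- logical(prod(dims)); m[support] <- TRUE
    mask <- which(cpp_dilate26(m, as.integer(dims)))
  }
  structure(list(label = label, support = support, mask = as.integer(mask),
                 dims = as.integer(dims), voxel_size = voxel_size,
                 origin = as.numeric(origin), composite = composite,
                 threshold = threshold),
            class = "voi")
}

#' @export
print.voi <- function(x, ...) {
  cat(sprintf("<voi> '%s': %d support voxels (%d dilated), grid %s\n",
              x$label, length(x$support), length(x$mask),
              paste(x$dims, collapse = "x")))
  invisible(x)
}

voi_logical <- function(v, what = c("support", "mask")) {
  what <- match.arg(what)
  m <- logical(prod(v$dims))
  m[v[[what]]] <- TRUE
  array(m, dim = v$dims)
}

#' Virtual slices
#'
#' Resamples a one-voxel-thick plane (or the mean of `thickness` adjacent
#' planes) from a volume. Axis-aligned planes index the grid directly;
#' oblique planes are resampled by trilinear interpolation.
#'
#' @param volume a [vox_volume].
#' @param plane `"x"`, `"y"` or `"z"` for axis-aligned slices, or
#'   `list(point =, normal =)` (nm) for an oblique plane.
#' @param position 1-based slice index for axis-aligned planes.
#' @param thickness number of adjacent planes to average.
#' @return a numeric matrix (the slice image).
#' @export
virtual_slice <- function(volume, plane, position = NULL, thickness = 1) {
  d <- dim(volume$data)
  stopifnot(thickness >= 1)
  if (is.character(plane)) {
    ax <- match(plane, c("x", "y", "z"))
    if (is.na(ax)) stop("plane must be 'x', 'y', 'z' or a list(point, normal)")
    if (is.null(position)) stop("position required for axis-aligned slices")
    idx <- position + seq_len(thickness) - 1
    if (position < 1 || max(idx) > d[ax])
      stop("range error: slice positions ", position, "..", max(idx),
           " outside 1..", d[ax])
    sl <- lapply(idx, function(i) switch(ax,
      volume$data[i, , ], volume$data[, i, ], volume$data[, , i]))
    Reduce(`+`, sl) / length(sl)
  } else {
    n <- unit(plane$normal)
    p0 <- plane$point
    # in-plane basis
    e1 <- unit(if (abs(n[1]) < 0.9) c(1, 0, 0) - n[1] * n else c(0, 1, 0) - n[2] * n)
    e2 <- c(n[2] * e1[3] - n[3] * e1[2], n[3] * e1[1] - n[1] * e1[3],
            n[1] * e1[2] - n[2] * e1[1])
    ext <- max(d) * volume$voxel_size
    s <- seq(-ext / 2, ext / 2, by = volume$voxel_size)
    grid <- as.matrix(expand.grid(u = s, v = s))
    layers <- lapply(seq_len(thickness) - (thickness - 1) / 2, function(o) {
      pts <- sweep(grid[, 1, drop = FALSE] %*% rbind(e1) +
                   grid[, 2, drop = FALSE] %*% rbind(e2), 2,
                   p0 + o * volume$voxel_size * n, "+")
      vox <- nm_to_voxel(volume, pts)
      cpp_sample_trilinear(as.numeric(volume$data), dim(volume$data), vox)
    })
    img <- matrix(Reduce(`+`, layers) / thickness, nrow = length(s))
    if (all(img == 0)) stop("range error: plane does not intersect the volume")
    img
  }
}

#' Segment a VOI by gray-scale thresholding
#'
#' Emulates interactive marking with a programmatic bounding region: within
#' `bounds`, voxels darker than (<=) the threshold are selected, the largest
#' 26-connected component is kept as the VOI support, and the support is
#' dilated by one voxel for the VOI mask. The threshold comes from the policy:
#' a fixed gray value, or the bimodal histogram split (Otsu) of the bounded
#' region.
#'
#' @param volume a [vox_volume].
#' @param bounds a `list(lo =, hi =)` of 1-based corner indices, a logical
#'   array, or an integer index vector restricting the search region.
#' @param threshold_policy `list(method = "fixed", value =)` or
#'   `list(method = "bimodal")`.
#' @param label VOI label.
#' @param min_voxels smallest acceptable component.
#' @return a [voi].
#' @export
segment_voi <- function(volume, bounds, threshold_policy = list(method = "bimodal"),
                        label = "structure", min_voxels = 30) {
  d <- dim(volume$data)
  inb <- bounds_logical(bounds, d)
  if (!any(inb)) stop("segmentation error: empty bounds")
  vals <- volume$data[inb]
  thr <- switch(threshold_policy$method,
    fixed = threshold_policy$value,
    bimodal = {
      t0 <- otsu_split(vals)
      if (split_contrast(vals, t0) < 3)
        stop("segmentation error: bounds show no bimodal gray contrast ",
             "(best split at ", round(t0, 1), ")")
      t0
    },
    stop("unknown threshold policy ", threshold_policy$method))
  sel <- inb & (volume$data <= thr)
  if (!any(sel))
    stop("segmentation error: no voxels at or below threshold ", round(thr, 1))
  lab <- cpp_label26(as.logical(sel), d)
  if (length(lab$sizes) == 0 || max(lab$sizes) < min_voxels)
    stop("segmentation error: largest dark component has ",
         if (length(lab$sizes)) max(lab$sizes) else 0,
         " voxels (minimum ", min_voxels, ") at threshold ", round(thr, 1))
  best <- which.max(lab$sizes)
  support <- which(lab$labels == best)
  voi(label, support, d, volume$voxel_size, volume$origin, threshold = thr)
}

bounds_logical <- function(bounds, d) {
  if (is.logical(bounds)) {
    stopifnot(all(dim(bounds) == d) || length(bounds) == prod(d))
    array(bounds, dim = d)
  } else if (is.numeric(bounds) && is.null(dim(bounds))) {
    m <- logical(prod(d)); m[as.integer(bounds)] <- TRUE
    array(m, dim = d)
  } else if (is.list(bounds)) {
    lo <- pmax(1, floor(bounds$lo)); hi <- pmin(d, ceiling(bounds$hi))
    if (any(lo > hi)) stop("segmentation error: empty bounds box")
    m <- array(FALSE, dim = d)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    m
  } else stop("unsupported bounds specification")
}

# Otsu's bimodal histogram split. Returns the upper edge of the last bin of
# the dark class, so thresholding at "<= value" keeps the whole dark mode.
otsu_split <- function(vals, nbins = 128) {
  if (diff(range(vals)) < 1e-9) return(vals[1])
  h <- hist(vals, breaks = seq(min(vals), max(vals), length.out = nbins + 1),
            plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  h$breaks[which.max(sigma_b) + 1]
}

# dark/bright contrast of a threshold split, in units of the within-class sd
split_contrast <- function(vals, thr) {
  lo <- vals[vals <= thr]; hi <- vals[vals > thr]
  if (length(lo) < 2 || length(hi) < 2) return(0)
  w_sd <- sqrt((length(lo) * stats::var(lo) + length(hi) * stats::var(hi)) /
                 length(vals))
  if (w_sd < 1e-9) return(Inf)
  (mean(hi) - mean(lo)) / w_sd
}

#' Triangulated isodensity surfaces
#'
#' @param vertices n x 3 matrix of vertex coordinates (nm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param threshold gray value at which the surface was rendered.
#' @export
surface_model <- function(vertices, faces, threshold = NA_real_) {
  vertices <- rbind(vertices)
  structure(list(vertices = vertices, faces = rbind(faces),
                 threshold = threshold),
            class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("<surface_model> %d vertices, %d faces, threshold %.1f, area %.1f nm^2\n",
              nrow(x$vertices), nrow(x$faces), x$threshold, surface_area(x)))
  invisible(x)
}

#' @rdname surface_model
#' @param surface a `surface_model`.
#' @return `surface_area()` returns the summed triangle area (nm^2).
#' @export
surface_area <- function(surface) {
  V <- surface$vertices; Fc <- surface$faces
  a <- V[Fc[, 2], , drop = FALSE] - V[Fc[, 1], , drop = FALSE]
  b <- V[Fc[, 3], , drop = FALSE] - V[Fc[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' @rdname surface_model
#' @return `surface_is_closed()` reports whether every edge is shared by
#'   exactly two faces.
#' @export
surface_is_closed <- function(surface) {
  Fc <- surface$faces
  if (nrow(Fc) == 0) return(FALSE)
  e <- rbind(Fc[, c(1, 2)], Fc[, c(2, 3)], Fc[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

#' Extract an isodensity surface from a VOI
#'
#' Scans 20 candidate gray thresholds between the 5th and 95th percentile of
#' the VOI's gray values and keeps the surface with the largest mean
#' gray-gradient magnitude sampled at its vertices -- the steepest-edge proxy
#' for minimal spatial uncertainty. The volume outside the (dilated) VOI mask
#' is treated as background so the surface is confined to the VOI.
#'
#' @param volume a [vox_volume].
#' @param voi a [voi].
#' @param closed require a watertight surface (vesicle membranes).
#' @param steps number of candidate thresholds.
#' @return a [surface_model] with attributes `score` (mean gradient) and
#'   `crop_offset`.
#' @export
extract_surface <- function(volume, voi, closed = FALSE, steps = 20) {
  stopifnot(inherits(voi, "voi"), all(voi$dims == dim(volume$data)))
  d <- voi$dims
  ijk <- cbind((voi$mask - 1) %% d[1], ((voi$mask - 1) %/% d[1]) %% d[2],
               (voi$mask - 1) %/% (d[1] * d[2])) + 1
  lo <- pmax(1, apply(ijk, 2, min) - 2)
  hi <- pmin(d, apply(ijk, 2, max) + 2)
  crop <- volume$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  cd <- dim(crop)
  inmask <- array(FALSE, dim = d); inmask[voi$mask] <- TRUE
  inmask <- inmask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  # Triangulate and score on a lightly smoothed copy: it suppresses voxel
  # noise, turns sharply rendered edges into short ramps whose interpolated
  # crossings track the geometric boundary (instead of the blocky midpoint
  # surface binary data would give), and peaks the gradient magnitude at the
  # boundary so the mid-contrast threshold wins the scan.
  smooth <- mean_filter3(crop)
  work <- smooth
  work[!inmask] <- 1001  # background: strictly lighter than any candidate
  gmag <- gradient_magnitude(smooth) / volume$voxel_size
  vals <- volume$data[voi$mask]
  cand <- seq(quantile(vals, 0.05), quantile(vals, 0.95), length.out = steps)
  best <- NULL; best_score <- -Inf
  for (th in cand) {
    mesh <- cpp_march_tetra(as.numeric(work), cd, th)
    if (nrow(mesh$faces) == 0) next
    sm <- surface_model(mesh$vertices, mesh$faces, threshold = th)
    if (closed && !surface_is_closed(sm)) next
    sc <- mean(cpp_sample_trilinear(as.numeric(gmag), cd, mesh$vertices))
    if (sc > best_score) { best_score <- sc; best <- sm }
  }
  if (is.null(best))
    stop("extraction error: no ", if (closed) "closed " else "",
         "isodensity surface found in the candidate threshold range ",
         round(cand[1], 1), "..", round(cand[steps], 1))
  # grid coordinates -> nm
  best$vertices <- sweep(best$vertices + rep(lo - 1, each = nrow(best$vertices)),
                         2, volume$origin / volume$voxel_size, "+") * volume$voxel_size
  attr(best, "score") <- best_score
  attr(best, "crop_offset") <- lo - 1
  best
}

# central-difference gradient magnitude (per voxel unit)
gradient_magnitude <- function(a) {
  d <- dim(a)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  gx[2:(d[1] - 1), , ] <- (a[3:d[1], , ] - a[1:(d[1] - 2), , ]) / 2
  gy[, 2:(d[2] - 1), ] <- (a[, 3:d[2], ] - a[, 1:(d[2] - 2), ]) / 2
  gz[, , 2:(d[3] - 1)] <- (a[, , 3:d[3]] - a[, , 1:(d[3] - 2)]) / 2
  sqrt(gx^2 + gy^2 + gz^2)
}
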