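#' Render the stained volume of a phantom scene
#'
#' Converts ground-truth voxel masks into a gray-scale volume (0-1000,
#' 0 = black). The noise-free image is piecewise constant at per-class target
#' gray levels (background lighter than membrane, membrane lighter than the
#' luminal assembly, matching the freeze-substitution staining pattern). With
#' noise enabled, heavy-metal staining is emulated by particulate texture:
#' Poisson-distributed counts of small dark blobs are deposited inside each
#' structure mask (mean-preserving, so sub-sampled placement leaves lighter
#' gaps in the membrane), plus Gaussian sensor noise everywhere.
#'
#' @param truth a `scene_truth` (the masks define where structures are).
#' @param params a [scene_params]; defaults to the scene's own.
#' @param seed RNG seed.
#' @return a [vox_volume].
#' @export
render_stain <- function(truth, params = truth$params, seed = params$seed) {
  withr::with_seed(seed, render_stain_impl(truth, params))
}

render_stain_impl <- function(truth, params) {
  st <- params$stain
  dims <- truth$scene_dims
  n <- prod(dims)
  vol <- rep(st$background, n)

  # presynaptic membrane slab just below z = 0
  zc <- truth$origin[3] + (seq_len(dims[3]) - 0.5) * truth$voxel_size
  slab <- which(zc > -3 & zc <= 0)
  if (length(slab)) {
    base <- (rep(slab, each = dims[1] * dims[2]) - 1) * dims[1] * dims[2]
    vol[base + seq_len(dims[1] * dims[2])] <- st$membrane
  }

  # paste structures in priority order; collect per-type voxel sets
  sets <- list(membrane = integer(), outerm = integer(),
               assembly = integer(), band = integer())
  for (v in seq_len(nrow(truth$vesicles))) {
    m <- truth$masks[[v]]
    lo <- truth$vesicles$crop_lo[[v]]
    sh <- function(idx) crop_to_scene(idx, m$dims, lo, dims)
    mem <- sh(m$membrane)
    out <- sh(sort(unique(unlist(m$outer))))
    asm <- sh(m$assembly)
    bnd <- sh(sort(unique(unlist(m$bands))))
    vol[mem] <- st$membrane
    vol[out] <- st$outer
    vol[asm] <- st$assembly
    vol[bnd] <- st$band
    sets$membrane <- c(sets$membrane, mem)
    sets$outerm <- c(sets$outerm, out)
    sets$assembly <- c(sets$assembly, asm)
    sets$band <- c(sets$band, bnd)
  }
  sets$membrane <- setdiff(sets$membrane, sets$band)

  amp <- st$noise_amp
  if (amp > 0) {
    frac <- c(membrane = st$particle_frac_membrane,
              outerm = st$particle_frac_membrane,
              assembly = st$particle_frac_assembly,
              band = st$particle_frac_assembly)
    for (ty in names(sets)) {
      idx <- sets[[ty]]
      if (length(idx) < 8) next
      vol <- add_blobs(vol, idx, dims, frac[[ty]], -st$particle_depth * amp)
    }
    # sub-sampled stain: occasional lighter gaps in the membrane outline
    if (length(sets$membrane) > 8)
      vol <- add_blobs(vol, sets$membrane, dims, 0.05, 120 * amp)
    vol <- vol + rnorm(n, 0, st$noise_sd * amp)
  }
  vol[vol < 0] <- 0; vol[vol > 1000] <- 1000
  vox_volume(array(vol, dim = dims), truth$voxel_size, truth$origin,
             validate = FALSE)
}

# particulate texture: small blobs at Poisson-counted seeds inside a mask
add_blobs <- function(vol, idx, dims, frac, delta) {
  inset <- logical(length(vol)); inset[idx] <- TRUE
  n_seed <- rpois(1, frac * length(idx) / 4)
  if (n_seed == 0) return(vol)
  seeds <- sample(idx, n_seed, replace = TRUE)
  nbr <- c(1, -1, dims[1], -dims[1], dims[1] * dims[2], -dims[1] * dims[2])
  cand <- c(seeds, rep(seeds, 3) +
              sample(nbr, 3 * length(seeds), replace = TRUE))
  cand <- unique(cand[cand >= 1 & cand <= length(vol)])
  part <- cand[inset[cand]]
  vol[part] <- vol[part] + delta
  vol
}

# 1-based flat indices in a crop grid -> flat indices in the scene grid
crop_to_scene <- function(idx, cd, lo, sd) {
  if (length(idx) == 0) return(integer())
  i <- (idx - 1) %% cd[1]
  j <- ((idx - 1) %/% cd[1]) %% cd[2]
  k <- (idx - 1) %/% (cd[1] * cd[2])
  (i + lo[1]) + sd[1] * ((j + lo[2]) + sd[2] * (k + lo[3])) + 1
}

#' Per-vesicle views of a phantom scene
#'
#' `crop_volume()` extracts the cubic crop around one vesicle;
#' `truth_voi()` wraps a ground-truth mask as a [voi] on the crop grid.
#'
#' @param volume the scene [vox_volume].
#' @param truth the `scene_truth`.
#' @param v vesicle id.
#' @export
crop_volume <- function(volume, truth, v) {
  lo <- truth$vesicles$crop_lo[[v]]
  s <- truth$vesicles$crop_side[v]
  vox_volume(volume$data[lo[1] + 1:s, lo[2] + 1:s, lo[3] + 1:s],
             voxel_size = volume$voxel_size,
             origin = volume$origin + lo * volume$voxel_size,
             validate = FALSE)
}

#' @rdname crop_volume
#' @param what `"membrane"`, `"lumen"`, `"assembly"`, or a site id (as
#'   character) within `"nubs"`, `"outer"` or `"bands"`.
#' @param site optional site id for per-macromolecule masks.
#' @export
truth_voi <- function(truth, v, what, site = NULL) {
  m <- truth$masks[[v]]
  idx <- if (is.null(site)) m[[what]] else m[[what]][[as.character(site)]]
  if (is.null(idx) || length(idx) == 0)
    stop("no ground-truth mask '", what, "' for vesicle ", v)
  voi(paste0(what, if (!is.null(site)) paste0("_", site)),
      idx, m$dims, truth$voxel_size,
      truth$origin + truth$vesicles$crop_lo[[v]] * truth$voxel_size,
      composite = what %in% c("assembly"))
}

#' Write a phantom scene to disk
#'
#' Writes the stained volume as MRC (mode 2, voxel size in the header), the
#' per-vesicle structure masks as a labelled MRC volume (background 0,
#' membrane 1, lumen 2, assembly 3, outer macromolecules 4, bands 5), the
#' ground truth (vesicle table and parameters) as JSON, and the site catalog
#' as CSV.
#'
#' @param scene the list returned by [synthesize_scene()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mrc(scene$volume, file.path(dir, "scene.mrc"))
  truth <- scene$truth
  lab <- rep(0L, prod(truth$scene_dims))
  code <- c(membrane = 1L, lumen = 2L, assembly = 3L)
  for (v in seq_len(nrow(truth$vesicles))) {
    m <- truth$masks[[v]]
    lo <- truth$vesicles$crop_lo[[v]]
    for (nm in names(code))
      lab[crop_to_scene(m[[nm]], m$dims, lo, truth$scene_dims)] <- code[[nm]]
    lab[crop_to_scene(unlist(m$outer), m$dims, lo, truth$scene_dims)] <- 4L
    lab[crop_to_scene(unlist(m$bands), m$dims, lo, truth$scene_dims)] <- 5L
  }
  write_mrc(vox_volume(array(lab, truth$scene_dims), truth$voxel_size,
                       truth$origin, validate = FALSE),
            file.path(dir, "labels.mrc"), mode = 1)
  ves <- truth$vesicles
  ves_json <- lapply(seq_len(nrow(ves)), function(v) list(
    vesicle_id = ves$vesicle_id[v], docked = ves$docked[v],
    center_nm = c(ves$cx[v], ves$cy[v], ves$cz[v]),
    d_outer = ves$d_outer[v], d_luminal = ves$d_luminal[v],
    pose = ves$pose[[v]], frame_rot = ves$frame_rot[[v]],
    crop_lo = ves$crop_lo[[v]], crop_side = ves$crop_side[v]))
  jsonlite::write_json(list(voxel_size = truth$voxel_size,
                            origin = truth$origin,
                            scene_dims = truth$scene_dims,
                            vesicles = ves_json),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  sites <- truth$sites %>%
    select("vesicle_id", "site_id", "class", "surface",
           "x_nm", "y_nm", "z_nm", "pair_id", "band")
  utils::write.csv(sites, file.path(dir, "sites.csv"), row.names = FALSE)
  invisible(dir)
}
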