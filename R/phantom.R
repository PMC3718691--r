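#' Scene parameters for synthetic active-zone phantoms
#'
#' Collects every tunable of the phantom generator with defaults set to the
#' study conditions of fixed/stained frog neuromuscular-junction active
#' zones: docked/undocked vesicle counts, outer and luminal diameter
#' distributions, the luminal-assembly fill fraction, nub and outer
#' macromolecule class count distributions, fusion- and binding-domain area
#' fractions, pairing dropout, transmembrane-band presence probabilities,
#' geometry jitter and stain rendering levels.
#'
#' @param n_docked,n_undocked vesicle counts.
#' @param d_outer_mean,d_outer_sd outer diameter distribution, nm.
#' @param d_luminal_mean,d_luminal_sd luminal diameter distribution, nm.
#' @param fill_fraction_target fraction of the lumen volume occupied by the
#'   luminal assembly.
#' @param nub_count_mean,nub_count_sd nub connection sites per vesicle.
#' @param class_counts per-class outer macromolecule count means and sds.
#' @param fusion_domain_area_fraction area fraction of the fusion domain
#'   (connection-site free cap facing the presynaptic membrane).
#' @param binding_domain_area_fraction area fraction of the main AZM binding
#'   domain cap that confines rib/spar/boom connection sites.
#' @param pairing_dropout_prob probability that a nub has no outer partner.
#' @param band_presence_prob per-class probability that a paired site carries
#'   a rendered transmembrane band.
#' @param jitter_sd_arm,jitter_sd_nub per-vesicle jitter (nm) of arm control
#'   points and nub anchors.
#' @param voxel_size nm per voxel.
#' @param seed default RNG seed for the generator.
#' @param stain gray-scale rendering levels (0-1000, 0 = black) and particle
#'   texture settings.
#' @param geometry luminal-assembly construction constants (arm directions,
#'   twist, radii, tube radii, membrane cleft).
#' @return a `scene_params` object (a validated list).
#' @export
scene_params <- function(n_docked = 4, n_undocked = 3,
                         d_outer_mean = 51.3, d_outer_sd = 3.3,
                         d_luminal_mean = 35.7, d_luminal_sd = 2.6,
                         fill_fraction_target = 0.10,
                         nub_count_mean = 23.8, nub_count_sd = 4.4,
                         class_counts = list(rib = c(4.2, 0.4), spar = c(2.0, 0.4),
                                             boom = c(7.0, 0.9), pin = c(3.9, 1.3),
                                             nonAZM = c(8.5, 1.8)),
                         fusion_domain_area_fraction = 0.05,
                         binding_domain_area_fraction = 0.137,
                         pairing_dropout_prob = 0.09,
                         band_presence_prob = c(rib = 0.97, spar = 0.94,
                                                boom = 0.88, pin = 0.91,
                                                nonAZM = 0.90),
                         jitter_sd_arm = 1.2, jitter_sd_nub = 2.0,
                         voxel_size = 1.0, seed = 1L,
                         stain = list(background = 600, membrane = 450,
                                      assembly = 380, outer = 430, band = 380,
                                      noise_sd = 40, noise_amp = 1,
                                      particle_frac_membrane = 0.25,
                                      particle_frac_assembly = 0.40,
                                      particle_depth = 110),
                         geometry = list(arm_twist = 30, arm_tip_frac_upper = 0.88,
                                         arm_tip_frac_lower = 0.68,
                                         arm_radius_tip = 3.4, arm_radius_focal = 1.5,
                                         focal_offset = c(-0.18, 0, -0.28),
                                         nub_radius = 1.0, outer_len = 8,
                                         outer_radius = 1.6, band_radius = 2.0,
                                         cleft = 3, min_site_sep = 8)) {
  p <- list(n_docked = n_docked, n_undocked = n_undocked,
            d_outer_mean = d_outer_mean, d_outer_sd = d_outer_sd,
            d_luminal_mean = d_luminal_mean, d_luminal_sd = d_luminal_sd,
            fill_fraction_target = fill_fraction_target,
            nub_count_mean = nub_count_mean, nub_count_sd = nub_count_sd,
            class_counts = class_counts,
            fusion_domain_area_fraction = fusion_domain_area_fraction,
            binding_domain_area_fraction = binding_domain_area_fraction,
            pairing_dropout_prob = pairing_dropout_prob,
            band_presence_prob = band_presence_prob,
            jitter_sd_arm = jitter_sd_arm, jitter_sd_nub = jitter_sd_nub,
            voxel_size = voxel_size, seed = seed, stain = stain,
            geometry = geometry)
  probs <- c(pairing_dropout_prob, band_presence_prob,
             fusion_domain_area_fraction, binding_domain_area_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (fusion_domain_area_fraction + binding_domain_area_fraction > 1)
    stop("fusion and binding domain fractions must sum to at most 1")
  if (n_docked < 0 || n_undocked < 0) stop("vesicle counts must be >= 0")
  if (fill_fraction_target <= 0 || fill_fraction_target >= 0.5)
    stop("fill_fraction_target must lie in (0, 0.5)")
  structure(p, class = "scene_params")
}

outer_classes <- c("rib", "spar", "boom", "pin", "nonAZM")

# ---- assembly template -----------------------------------------------------

# uniform Catmull-Rom spline through control points, ~n samples
catmull_rom <- function(ctrl, n = 40) {
  m <- nrow(ctrl)
  P <- rbind(ctrl[1, ], ctrl, ctrl[m, ])
  per <- max(2, ceiling(n / (m - 1)))
  out <- vector("list", m - 1)
  for (s in seq_len(m - 1)) {
    p0 <- P[s, ]; p1 <- P[s + 1, ]; p2 <- P[s + 2, ]; p3 <- P[s + 3, ]
    u <- seq(0, 1, length.out = per)
    if (s < m - 1) u <- u[-length(u)]
    pts <- t(vapply(u, function(t) {
      0.5 * ((2 * p1) + (-p0 + p2) * t + (2 * p0 - 5 * p1 + 4 * p2 - p3) * t^2 +
               (-p0 + 3 * p1 - 3 * p2 + p3) * t^3)
    }, numeric(3)))
    out[[s]] <- pts
  }
  do.call(rbind, out)
}

# capsule segment matrix (x1..z2, r) for one arm: polyline samples + radii
arm_segments <- function(ctrl, radii, n = 40) {
  pts <- catmull_rom(ctrl, n)
  k <- nrow(pts)
  tfrac <- seq(0, 1, length.out = k)
  r <- approx(seq(0, 1, length.out = length(radii)), radii, tfrac)$y
  cbind(pts[-k, , drop = FALSE], pts[-1, , drop = FALSE], (r[-k] + r[-1]) / 2)
}

# directions on the unit sphere around `axis`: polar angle psi, azimuth phi
# measured from basis vector e1 (phi = 0) toward e2
cap_dir <- function(axis, psi, phi) {
  a <- unit(axis)
  ref <- if (abs(a[3]) < 0.95) c(0, 0, -1) else c(1, 0, 0)
  e1 <- unit(ref - sum(ref * a) * a)
  e2 <- c(a[2] * e1[3] - a[3] * e1[2], a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  cos(psi) * a + sin(psi) * (cos(phi) * e1 + sin(phi) * e2)
}

# domain geometry shared by template and per-vesicle site placement
domain_geometry <- function(params) {
  theta_f <- acos(1 - 2 * params$fusion_domain_area_fraction)
  theta_b <- acos(1 - 2 * params$binding_domain_area_fraction)
  tfb <- theta_f + theta_b
  list(theta_f = theta_f, theta_b = theta_b,
       u_bind = c(sin(tfb), 0, -cos(tfb)))  # binding-cap axis, local frame
}

# one outer-site direction for a class (local frame: +x toward median plane,
# +z away from the presynaptic membrane)
draw_class_dir <- function(class, g) {
  # ribs hug the cap rim nearest the fusion domain and booms the opposite
  # rim, so the average-rib-to-furthest-boom chord spans the cap base (the
  # zone readout the binding domain is defined by); spars lie between
  deg <- pi / 180
  switch(class,
    rib  = cap_dir(g$u_bind, g$theta_b * runif(1, 0.96, 1.0), runif(1, -22, 22) * deg),
    spar = cap_dir(g$u_bind, g$theta_b * runif(1, 0.45, 0.85),
                   sample(c(-1, 1), 1) * runif(1, 35, 125) * deg),
    boom = cap_dir(g$u_bind, g$theta_b * runif(1, 0.92, 1.0),
                   pi + runif(1, -32, 32) * deg),
    pin  = {
      repeat {
        d <- cap_dir(c(0, 0, -1), g$theta_f + runif(1, 2, 15) * deg, runif(1, 0, 2 * pi))
        if (vec_angle(d, g$u_bind) > g$theta_b / deg) return(d)
      }
    },
    nonAZM = {
      repeat {
        v <- rnorm(3); d <- unit(v)
        polar <- vec_angle(d, c(0, 0, -1))
        if (polar > (g$theta_f / deg + 15) && vec_angle(d, g$u_bind) > g$theta_b / deg)
          return(d)
      }
    })
}

#' Build the canonical luminal-assembly template
#'
#' Constructs the chiral, bilateral four-arm assembly: arms are cubic-spline
#' tubes radiating from a focal point displaced below (toward the fusion
#' domain) and behind (away from the AZM) the lumen center, with a common
#' azimuthal twist that makes the shape chiral, tapering from their tips near
#' the membrane toward the focal point. Arm radii are calibrated so the
#' rasterized template (arms plus the canonical nub set) occupies the target
#' fraction of the lumen volume. The template also carries a canonical nub
#' catalog (membrane anchor directions and arm anchors).
#'
#' @param params a [scene_params].
#' @param seed RNG seed (defaults to `params$seed`).
#' @return an `assembly_template` object.
#' @export
make_assembly_template <- function(params = scene_params(), seed = params$seed) {
  withr::with_seed(seed, make_template_impl(params))
}

make_template_impl <- function(params) {
  g <- params$geometry
  r_l <- params$d_luminal_mean / 2
  focal <- g$focal_offset * r_l
  # four irregular arms, one per quadrant seen from the median plane; the
  # deliberate irregularity (no two arms are mirror images) is what lets
  # reference-free alignment discriminate the true pose from pseudo-
  # symmetric flips, as the real assembly's irregular arms do
  dirs <- rbind(unit(c(0.38, 0.70, 0.58)), unit(c(0.18, -0.55, 0.85)),
                unit(c(0.40, 0.66, -0.74)), unit(c(0.26, -0.77, -0.55)))
  tipfrac <- c(g$arm_tip_frac_upper, g$arm_tip_frac_upper * 0.94,
               g$arm_tip_frac_lower, g$arm_tip_frac_lower * 1.08)
  arms <- lapply(1:4, function(a) {
    d <- dirs[a, ]
    # arc length to the tip radius: |focal + t d| = tipfrac * r_l
    b <- sum(focal * d); cc <- sum(focal^2) - (tipfrac[a] * r_l)^2
    tmax <- -b + sqrt(b^2 - cc)
    tt <- seq(0, 1, length.out = 5)
    ctrl <- t(vapply(tt, function(t) {
      p <- focal + (t * tmax) * d
      v <- p - focal
      ang <- g$arm_twist * t * pi / 180  # common-handed twist about the head axis
      vr <- c(v[1], cos(ang) * v[2] - sin(ang) * v[3],
              sin(ang) * v[2] + cos(ang) * v[3])
      q <- focal + vr
      if (sqrt(sum(q^2)) > 0.88 * r_l) q <- q * (0.88 * r_l) / sqrt(sum(q^2))
      q
    }, numeric(3)))
    list(ctrl = ctrl, radius = g$arm_radius_focal +
           (g$arm_radius_tip - g$arm_radius_focal) * tt)
  })
  # canonical nub catalog at the rounded class-count means plus two unpaired
  dom <- domain_geometry(params)
  classes <- rep(outer_classes, times = round(vapply(params$class_counts, `[`, 1, i = 1)))
  nub_dir <- t(vapply(classes, draw_class_dir, numeric(3), g = dom))
  extra <- t(vapply(1:2, function(i) {
    repeat {
      d <- unit(rnorm(3))
      if (vec_angle(d, c(0, 0, -1)) * pi / 180 > dom$theta_f) return(d)
    }
  }, numeric(3)))
  nubs <- tibble(class = c(classes, "none", "none"),
                 ux = c(nub_dir[, 1], extra[, 1]),
                 uy = c(nub_dir[, 2], extra[, 2]),
                 uz = c(nub_dir[, 3], extra[, 3]),
                 radius = g$nub_radius)
  tpl <- structure(list(focal = focal, arms = arms, nubs = nubs,
                        chirality_flag = TRUE, r_lum = r_l, params = params),
                   class = "assembly_template")
  # calibrate arm radii against the fill target
  target <- params$fill_fraction_target
  for (it in 1:4) {
    fill <- template_fill_fraction(tpl)
    sc <- sqrt(target / fill)
    tpl$arms <- lapply(tpl$arms, function(a) { a$radius <- a$radius * sc; a })
    if (max(vapply(tpl$arms, function(a) max(a$radius), 1)) > 0.35 * r_l)
      stop("parameter error: fill target ", target,
           " unreachable without arm radii exceeding 0.35 of the lumen radius")
  }
  fill <- template_fill_fraction(tpl)
  if (abs(fill - target) > 0.1 * target)
    stop("parameter error: calibrated template fill ", round(fill, 4),
         " misses fill_fraction_target ", target, " by more than 10%")
  tpl$fill <- fill
  tpl
}

# capsule segments (nm, local frame) for template arms + nubs; jitter in nm.
# Arm tubes keep a clearance from the luminal surface (only nubs touch the
# membrane), so the assembly stays radially inside the lumen.
assembly_capsules <- function(tpl, jitter_arm = 0, jitter_nub = 0, scale = 1) {
  r_lum_s <- tpl$r_lum * scale
  segs <- lapply(tpl$arms, function(a) {
    ctrl <- a$ctrl
    if (jitter_arm > 0) {
      j <- matrix(rnorm(length(ctrl), 0, jitter_arm), nrow(ctrl))
      j[1, ] <- j[1, ] * 0.3  # arms stay conjoined at the focal point
      ctrl <- ctrl + j
    }
    seg <- arm_segments(ctrl * scale, a$radius * scale)
    for (col in c(0, 3)) {  # clearance: tube surface at least 2 nm inside
      P <- seg[, col + 1:3, drop = FALSE]
      lim <- r_lum_s - seg[, 7] - 2
      rr <- sqrt(rowSums(P^2))
      f <- pmin(1, lim / pmax(rr, 1e-9))
      seg[, col + 1:3] <- P * f
    }
    seg
  })
  arm_seg <- do.call(rbind, segs)
  pts <- arm_seg[, 1:3, drop = FALSE]
  r_l <- tpl$r_lum * scale
  nub_seg <- t(vapply(seq_len(nrow(tpl$nubs)), function(i) {
    u <- unit(c(tpl$nubs$ux[i], tpl$nubs$uy[i], tpl$nubs$uz[i]))
    tip <- u * r_l
    if (jitter_nub > 0) tip <- unit(tip + rnorm(3, 0, jitter_nub)) * r_l
    d2 <- rowSums(sweep(pts, 2, tip)^2)
    anchor <- pts[which.min(d2), ]
    c(anchor, tip, tpl$nubs$radius[i] * scale)
  }, numeric(7)))
  list(arms = arm_seg, nubs = nub_seg)
}

# rasterize a capsule set into a centered cubic grid; returns logical array
rasterize_capsules <- function(segs, r_clip, voxel_size = 1) {
  side <- 2L * as.integer(ceiling(r_clip / voxel_size)) + 4L
  half <- side / 2
  vseg <- segs
  vseg[, 1:6] <- vseg[, 1:6] / voxel_size + half
  vseg[, 7] <- vseg[, 7] / voxel_size
  m <- cpp_raster_capsules(vseg, rep(side, 3))
  dim(m) <- rep(side, 3)
  ax <- (seq_len(side) - 0.5 - half) * voxel_size
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  list(mask = m & (r2 < r_clip^2), side = side, lumen = r2 < r_clip^2)
}

#' @rdname make_assembly_template
#' @param tpl an `assembly_template`.
#' @return `template_fill_fraction()` returns the rasterized (jitter-free)
#'   assembly volume divided by the lumen volume.
#' @export
template_fill_fraction <- function(tpl) {
  caps <- assembly_capsules(tpl)
  ras <- rasterize_capsules(rbind(caps$arms, caps$nubs), tpl$r_lum,
                            tpl$params$voxel_size)
  sum(ras$mask) / sum(ras$lumen)
}

#' @rdname make_assembly_template
#' @return `mirror_template()` returns the template reflected across the
#'   median plane (y -> -y); because of the common-handed arm twist the
#'   reflection is not superimposable on the original by any rotation.
#' @export
mirror_template <- function(tpl) {
  tpl$focal[2] <- -tpl$focal[2]
  tpl$arms <- lapply(tpl$arms, function(a) {
    a$ctrl[, 2] <- -a$ctrl[, 2]; a
  })
  tpl$nubs$uy <- -tpl$nubs$uy
  tpl$chirality_flag <- FALSE
  tpl
}

# best overlap count of mask A (moving) onto mask B over an exhaustive Euler
# rotation grid (step degrees); both masks centered cubic arrays
best_rotation_overlap <- function(maskA, maskB, step = 10) {
  side <- dim(maskB)[1]
  pts <- which(maskA)
  d <- dim(maskA)
  ijk <- cbind((pts - 1) %% d[1], ((pts - 1) %/% d[1]) %% d[2],
               (pts - 1) %/% (d[1] * d[2])) + 0.5
  P <- sweep(ijk, 2, d / 2)
  grid <- seq(0, 350, by = step)
  gy <- seq(0, 170, by = step)
  best <- -Inf
  fixed <- as.numeric(maskB)
  for (az in grid) for (ay in gy) for (ax in grid) {
    sc <- cpp_density_score(P, rep(1, nrow(P)), fixed, d,
                            euler_rot(ax, ay, az), rep(side / 2, 3))
    if (sc > best) best <- sc
  }
  best
}
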