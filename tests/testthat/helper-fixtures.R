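# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# a small default-noise scene: 3 docked + 1 undocked vesicles
small_scene <- function() {
  cached("small_scene", synthesize_scene(
    scene_params(n_docked = 3, n_undocked = 1), seed = 7))
}

# a noise-free scene (piecewise-constant gray) with 2 docked vesicles
clean_scene <- function() {
  cached("clean_scene", {
    p <- scene_params(n_docked = 2, n_undocked = 0)
    p$stain$noise_amp <- 0
    synthesize_scene(p, seed = 11)
  })
}

# solid dark ball rendered into a background volume (sharp edges)
ball_volume <- function(d_nm, voxel_size = 1, gray_in = 380, gray_out = 600,
                        pad = 6) {
  side <- 2 * ceiling(d_nm / 2 / voxel_size) + 2 * pad
  ax <- (seq_len(side) - 0.5 - side / 2) * voxel_size
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  vox_volume(array(ifelse(r2 <= (d_nm / 2)^2, gray_in, gray_out),
                   dim = rep(side, 3)), voxel_size)
}

# spherical shell (membrane phantom) volume
shell_volume <- function(d_outer, d_luminal, voxel_size = 1, gray_mem = 450,
                         gray_bg = 600, pad = 6) {
  side <- 2 * ceiling(d_outer / 2 / voxel_size) + 2 * pad
  ax <- (seq_len(side) - 0.5 - side / 2) * voxel_size
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  g <- ifelse(r2 >= (d_luminal / 2)^2 & r2 <= (d_outer / 2)^2, gray_mem, gray_bg)
  vox_volume(array(g, dim = rep(side, 3)), voxel_size)
}

# optimal one-to-one matching oracle (exact, bitmask dynamic program):
# minimizes total offset over matchings that pair as many nubs as possible
# under the rejection threshold. Suitable for <= ~14 outer sites.
optimal_matching <- function(ang, max_offset) {
  n <- nrow(ang); m <- ncol(ang)
  stopifnot(m <= 14)
  full <- bitwShiftL(1L, m) - 1L
  INF <- 1e18
  # dp over nubs (rows), state = set of used outer sites;
  # value = c(-pairs, total offset) lexicographic via big penalty
  dp <- rep(INF, full + 1L); dp[1] <- 0
  penalty <- 1e6  # each unpaired nub costs more than any finite offsets
  for (i in seq_len(n)) {
    nd <- rep(INF, full + 1L)
    for (s in 0:full) {
      if (dp[s + 1] >= INF) next
      v <- dp[s + 1] + penalty  # leave nub i unpaired
      if (v < nd[s + 1]) nd[s + 1] <- v
      for (j in seq_len(m)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(s, bit) > 0 || ang[i, j] > max_offset) next
        s2 <- bitwOr(s, bit)
        v2 <- dp[s + 1] + ang[i, j]
        if (v2 < nd[s2 + 1]) nd[s2 + 1] <- v2
      }
    }
    dp <- nd
  }
  best <- min(dp)
  n_pair <- n - (best %/% 1e6)
  list(n_paired = n_pair, total_offset = best %% 1e6)
}

# expected mean rotation angle of Haar-uniform rotations, by numeric
# integration of the SO(3) angle density (1 - cos t) / pi on [0, pi]
haar_mean_angle <- function() {
  f <- function(t) t * (1 - cos(t)) / pi
  stats::integrate(f, 0, pi)$value * 180 / pi
}

# great-circle angles between two direction matrices
angdeg <- function(U, V) {
  cc <- pmin(1, pmax(-1, tcrossprod(U, V)))
  matrix(acos(cc) * 180 / pi, nrow(U), nrow(V))
}
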