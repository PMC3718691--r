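#' Active-zone reference frame
#'
#' The three cardinal planes of the active zone: the horizontal plane
#' (parallel to the presynaptic membrane beyond the ridge), the median plane
#' (parallel to the long axis of the main body of the AZM) and the transverse
#' plane (orthogonal to both). Each is stored as a point plus unit normal;
#' the three normals must be mutually orthogonal within 1 degree.
#'
#' @param origin a point on all three planes (nm).
#' @param head unit normal of the median plane, pointing from the vesicle
#'   toward the median plane.
#' @param tail unit normal of the horizontal plane, pointing away from the
#'   presynaptic membrane.
#' @export
az_frame <- function(origin = c(0, 0, 0), head = c(1, 0, 0), tail = c(0, 0, 1)) {
  head <- unit(head); tail <- unit(tail)
  if (abs(90 - vec_angle(head, tail)) > 1)
    stop("frame normals must be mutually orthogonal within 1 degree")
  long <- c(tail[2] * head[3] - tail[3] * head[2],
            tail[3] * head[1] - tail[1] * head[3],
            tail[1] * head[2] - tail[2] * head[1])
  structure(list(origin = as.numeric(origin), head = head, tail = tail,
                 long_axis = unit(long)),
            class = "az_frame")
}

frame_from_truth <- function(truth, v) {
  Fv <- truth$vesicles$frame_rot[[v]]
  az_frame(origin = c(truth$vesicles$cx[v], truth$vesicles$cy[v],
                      truth$vesicles$cz[v]),
           head = as.numeric(Fv %*% c(1, 0, 0)),
           tail = as.numeric(Fv %*% c(0, 0, 1)))
}

#' Orientation arrows for alignment-model members
#'
#' Expresses each member's assembly orientation as a 3D arrow in active-zone
#' coordinates. The reference vesicle's arrow is built from its frame: the
#' head/shaft points at the median plane, parallel to the presynaptic
#' membrane, and the tail rises vertical to the membrane. Every other
#' member's arrow is the reference arrow rotated by the relative rotation of
#' that member versus the reference, read off the stored registration
#' transforms (`R_m^-1 R_ref`), and is reported in that member's own
#' active-zone frame.
#'
#' @param model an `alignment_model`.
#' @param frames list of [az_frame]s, one per member (vesicle order).
#' @param reference_id member id of the reference vesicle.
#' @return a tibble with one row per member: shaft and tail direction
#'   components (unit vectors, active-zone coordinates) plus
#'   `shaft_angle`/`tail_angle` relative to the reference arrow.
#' @export
orientation_arrows <- function(model, frames, reference_id) {
  n <- length(model$members)
  if (!reference_id %in% model$members)
    stop("lookup error: reference vesicle ", reference_id, " is not a model member")
  stopifnot(length(frames) == n)
  Rref <- model$transforms[[reference_id]]$R
  Fref <- frames[[reference_id]]
  shaft_ref_w <- Fref$head; tail_ref_w <- Fref$tail
  rows <- lapply(seq_len(n), function(m) {
    Rm <- model$transforms[[m]]$R
    rel <- t(Rm) %*% Rref           # member orientation vs reference, world axes
    sw <- as.numeric(rel %*% shaft_ref_w)
    tw <- as.numeric(rel %*% tail_ref_w)
    Fm <- frames[[m]]
    # express in the member's active-zone coordinates (head, long, tail)
    B <- rbind(Fm$head, Fm$long_axis, Fm$tail)
    sl <- as.numeric(B %*% sw); tl <- as.numeric(B %*% tw)
    tibble(vesicle_id = m,
           shaft_x = sl[1], shaft_y = sl[2], shaft_z = sl[3],
           tail_x = tl[1], tail_y = tl[2], tail_z = tl[3],
           shaft_angle = vec_angle(sl, c(1, 0, 0)),
           tail_angle = vec_angle(tl, c(0, 0, 1)))
  })
  bind_rows(rows)
}

#' Orient an external assembly by model overlay
#'
#' Finds the rotation that maximizes the overlap of the alignment model with
#' an assembly that is not one of its members: multi-start ICP of the
#' assembly surface onto the model region surface, refined by the gray-scale
#' density search. When the rotation-score landscape is flat (an
#' orientation-free shape such as a sphere), the result carries a
#' low-confidence flag instead of an error.
#'
#' @param assembly an [assembly_rep] of the external vesicle.
#' @param model an `alignment_model`.
#' @param start_grid_step multi-start spacing, degrees.
#' @param confidence_floor minimum relative score anisotropy across rotation
#'   starts below which the pose is flagged low confidence.
#' @return an `alignment_result` with attribute `low_confidence`.
#' @export
orient_by_overlay <- function(assembly, model, start_grid_step = 30,
                              confidence_floor = 0.2) {
  fmesh <- region_mesh(model)
  s <- start_grid_step
  starts <- expand.grid(ax = seq(0, 360 - s, by = s),
                        ay = seq(0, 180, by = s),
                        az = seq(0, 360 - s, by = s))
  A <- assembly$mesh
  Ad <- A[unique(round(seq(1, nrow(A), length.out = 120))), , drop = FALSE]
  B <- fmesh$vertices
  Bd <- B[unique(round(seq(1, nrow(B), length.out = 150))), , drop = FALSE]
  ca <- colMeans(Ad); cb <- colMeans(Bd)
  scores <- numeric(nrow(starts))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    R0 <- euler_rot(starts$ax[k], starts$ay[k], starts$az[k])
    r <- cpp_icp(Ad, Bd, R0, cb - as.numeric(R0 %*% ca), 10, 1e-3)
    scores[k] <- -r$dist
    if (is.null(best) || r$dist < best$dist) best <- r
  }
  init <- rigid_transform(best$R, as.numeric(best$t))
  res <- density_align(assembly, model$density, init = init)
  spread <- (max(scores) - median(scores)) / max(abs(median(scores)), 1e-9)
  attr(res, "low_confidence") <- spread < confidence_floor
  res
}

#' Classify orientation stereotypy
#'
#' A vesicle's assembly is "oriented" when its arrow points the same way as
#' the reference arrow within tolerance about both stated references: the
#' shaft (median-plane direction) and the tail (vertical to the presynaptic
#' membrane) must each agree within `tol` degrees.
#'
#' @param arrow,reference list or one-row tibble with `shaft_*`/`tail_*`
#'   components, or a list with `shaft` and `tail` vectors. A missing tail
#'   (`NA`) yields a partial classification on the shaft alone.
#' @param tol tolerance, degrees.
#' @return list with `oriented`, `shaft_angle`, `tail_angle`, `partial`.
#' @export
classify_orientation <- function(arrow, reference, tol = 30) {
  av <- arrow_vectors(arrow); rv <- arrow_vectors(reference)
  shaft_angle <- vec_angle(av$shaft, rv$shaft)
  partial <- any(is.na(av$tail)) || any(is.na(rv$tail))
  tail_angle <- if (partial) NA_real_ else vec_angle(av$tail, rv$tail)
  oriented <- shaft_angle <= tol && (partial || tail_angle <= tol)
  list(oriented = oriented, shaft_angle = shaft_angle,
       tail_angle = tail_angle, partial = partial)
}

arrow_vectors <- function(a) {
  if (!is.null(a$shaft)) return(list(shaft = a$shaft, tail = a$tail))
  list(shaft = c(a$shaft_x, a$shaft_y, a$shaft_z),
       tail = c(a$tail_x, a$tail_y, a$tail_z))
}

#' @rdname classify_orientation
#' @param arrows tibble from [orientation_arrows()].
#' @param docked optional logical vector to carry through.
#' @return `classify_orientations()` returns the arrows tibble with
#'   `oriented` and `partial` columns added (reference arrow = frame axes).
#' @export
classify_orientations <- function(arrows, tol = 30, docked = NULL) {
  ref <- list(shaft = c(1, 0, 0), tail = c(0, 0, 1))
  out <- arrows %>%
    dplyr::rowwise() %>%
    mutate(cls = list(classify_orientation(
      list(shaft = c(.data$shaft_x, .data$shaft_y, .data$shaft_z),
           tail = c(.data$tail_x, .data$tail_y, .data$tail_z)), ref, tol))) %>%
    ungroup() %>%
    mutate(oriented = purrr::map_lgl(.data$cls, "oriented"),
           partial = purrr::map_lgl(.data$cls, "partial")) %>%
    select(-"cls")
  if (!is.null(docked)) out$docked <- docked
  out
}
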