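#' Rigid transforms
#'
#' Rotations are 3x3 orthonormal matrices; the Euler parameterization used
#' throughout the package is R = Rz(az) %*% Ry(ay) %*% Rx(ax) with angles in
#' degrees. A rigid transform maps points by `y = R x + t`.
#'
#' @param ax,ay,az rotation angles about the x, y and z axes, degrees.
#' @return `euler_rot()` returns a 3x3 rotation matrix.
#' @export
euler_rot <- function(ax, ay, az) {
  d <- pi / 180
  cx <- cos(ax * d); sx <- sin(ax * d)
  cy <- cos(ay * d); sy <- sin(ay * d)
  cz <- cos(az * d); sz <- sin(az * d)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' @rdname euler_rot
#' @param R a 3x3 rotation matrix.
#' @return `rot_to_euler()` returns the (ax, ay, az) angles in degrees;
#'   `rot_angle()` the total rotation angle in degrees.
#' @export
rot_to_euler <- function(R) {
  ay <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ay)) > 1e-9) {
    ax <- atan2(R[3, 2], R[3, 3])
    az <- atan2(R[2, 1], R[1, 1])
  } else { # gimbal lock: fold everything into az
    ax <- 0
    az <- atan2(-R[1, 2], R[2, 2])
  }
  c(ax, ay, az) * 180 / pi
}

#' @rdname euler_rot
#' @export
rot_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' @rdname euler_rot
#' @param axis rotation axis (length-3, any norm).
#' @param angle rotation angle in degrees.
#' @export
axis_rot <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' @rdname euler_rot
#' @param u,v unit vectors; returns the minimal rotation taking `u` to `v`.
#' @export
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  ax <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antipodal: rotate 180 degrees about any axis orthogonal to u
    w <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3], u[1] * w[2] - u[2] * w[1])
    return(axis_rot(ax, 180))
  }
  axis_rot(ax, atan2(s, c_) * 180 / pi)
}

#' Uniform (Haar) random rotations
#'
#' Draws rotation matrices uniformly over SO(3) via normalized quaternions.
#'
#' @param n number of rotations.
#' @return a list of 3x3 rotation matrices.
#' @export
rand_rotation <- function(n = 1) {
  lapply(seq_len(n), function(i) {
    q <- rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
      2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
      2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
    ), 3, 3)
  })
}

#' @rdname euler_rot
#' @param t translation (length 3).
#' @return `rigid_transform()` returns an object of class `rigid_transform`
#'   with elements `R` and `t`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)), length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal")
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' @rdname euler_rot
#' @param tf,tf2 rigid transforms.
#' @export
compose_transform <- function(tf, tf2) {
  # (tf o tf2)(x) = tf(tf2(x))
  rigid_transform(tf$R %*% tf2$R, as.numeric(tf$R %*% tf2$t) + tf$t)
}

#' @rdname euler_rot
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$R), as.numeric(-t(tf$R) %*% tf$t))
}

#' @rdname euler_rot
#' @param x an n x 3 matrix of points.
#' @export
apply_transform <- function(tf, x) {
  x <- rbind(x)
  sweep(x %*% t(tf$R), 2, tf$t, "+")
}

#' @export
print.rigid_transform <- function(x, ...) {
  e <- rot_to_euler(x$R)
  cat(sprintf("<rigid_transform> euler xyz = (%.2f, %.2f, %.2f) deg, t = (%.2f, %.2f, %.2f)\n",
              e[1], e[2], e[3], x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

# angle (degrees) between two vectors
vec_angle <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(max(-1, min(1, ca))) * 180 / pi
}

unit <- function(v) v / sqrt(sum(v^2))
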