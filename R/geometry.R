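# Small 3-vector / rotation helpers shared by both kinematics backends.
#
# Conventions used throughout the package:
#   * lab frame: +X walking direction (anterior), +Y up, +Z completes the
#     right-handed triple (subject's right for a subject walking along +X);
#   * anatomical ("canonical") segment axes: x mediolateral (to the subject's
#     right), y anterior, z longitudinal (pointing proximally / up).
# All angles cross the API in degrees; radians never leave a function.

DEG <- 180 / pi

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

norm3 <- function(a) sqrt(sum(a * a))

unit3 <- function(a, what = "vector") {
  n <- norm3(a)
  if (!is.finite(n) || n < 1e-12) {
    stop(sprintf("degenerate geometry: %s has (near-)zero length", what),
         call. = FALSE)
  }
  a / n
}

#' Construct a body-segment coordinate frame
#'
#' A `SegmentFrame` is an origin plus a right-handed orthonormal basis, the
#' package's representation of a segment pose at one instant. The axes are
#' stored as the columns of a 3x3 rotation matrix `R = [x y z]` expressed in
#' lab coordinates.
#'
#' @param origin numeric length-3, metres (lab frame).
#' @param x,y,z numeric length-3 unit axis vectors.
#' @param orthonormalize if `TRUE`, the basis is re-orthonormalized
#'   (Gram-Schmidt keeping `x`, then `y`) before validation; useful when axes
#'   were measured rather than constructed.
#' @return an object of class `segment_frame` with fields `origin` and `R`.
#' @export
segment_frame <- function(origin, x, y, z, orthonormalize = FALSE) {
  stopifnot(length(origin) == 3L, length(x) == 3L, length(y) == 3L,
            length(z) == 3L)
  if (orthonormalize) {
    x <- unit3(x, "x axis")
    y <- unit3(y - sum(y * x) * x, "y axis")
    z <- cross3(x, y)
  }
  R <- cbind(x, y, z, deparse.level = 0)
  G <- crossprod(R)
  if (max(abs(G - diag(3))) > 1e-6) {
    stop("segment frame axes are not orthonormal", call. = FALSE)
  }
  if (det(R) < 0) {
    stop("segment frame is left-handed (det < 0)", call. = FALSE)
  }
  structure(list(origin = as.numeric(origin), R = R), class = "segment_frame")
}

#' @export
format.segment_frame <- function(x, ...) {
  sprintf("<segment_frame origin=(%.4f, %.4f, %.4f)>",
          x$origin[1L], x$origin[2L], x$origin[3L])
}

#' @export
print.segment_frame <- function(x, ...) {
  cat(format(x), "\n")
  print(round(x$R, 6))
  invisible(x)
}

rot_x <- function(deg) {
  t <- deg / DEG; c <- cos(t); s <- sin(t)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3L, 3L)
}

rot_y <- function(deg) {
  t <- deg / DEG; c <- cos(t); s <- sin(t)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3L, 3L)
}

rot_z <- function(deg) {
  t <- deg / DEG; c <- cos(t); s <- sin(t)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3L, 3L)
}

#' Compose a joint rotation from clinical Euler angles
#'
#' Intrinsic (mobile-axis) x-y-z sequence on canonical anatomical frames:
#' flexion about the proximal mediolateral axis, ab/adduction about the
#' rotated anterior axis, axial rotation about the twice-rotated longitudinal
#' axis. For a right limb with canonical axes the signs come out clinical:
#' flexion +, adduction +, internal rotation +.
#'
#' @param flexion,adduction,rotation angles in degrees.
#' @return 3x3 rotation matrix mapping distal-frame coordinates to
#'   proximal-frame coordinates.
#' @export
euler_compose <- function(flexion, adduction, rotation) {
  rot_x(flexion) %*% rot_y(adduction) %*% rot_z(rotation)
}

#' Decompose a joint rotation into clinical Euler angles
#'
#' Exact inverse of [euler_compose()] for `|adduction| < 90` degrees. Near
#' gimbal lock (|adduction| > 89 deg) the decomposition is still returned but
#' flagged.
#'
#' @param R 3x3 rotation matrix (proximal^T distal).
#' @return list with `flexion`, `adduction`, `rotation` (degrees) and a
#'   logical `gimbal` flag.
#' @export
euler_decompose <- function(R) {
  s <- max(-1, min(1, R[1L, 3L]))
  adduction <- asin(s) * DEG
  flexion <- atan2(-R[2L, 3L], R[3L, 3L]) * DEG
  rotation <- atan2(-R[1L, 2L], R[1L, 1L]) * DEG
  list(flexion = flexion, adduction = adduction, rotation = rotation,
       gimbal = abs(adduction) > 89)
}

# Random rotation matrix (uniform via QR of Gaussian), used in tests and
# equivariance checks.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L, 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# Apply a rigid transform to a 3-column coordinate matrix (rows = samples).
apply_rigid <- function(P, R, t = c(0, 0, 0)) {
  sweep(P %*% t(R), 2L, t, `+`)
}
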