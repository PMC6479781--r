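# Depth-sensor ("Kinect-style") joint kinematics from the reduced landmark
# set: pelvis and thigh coordinate frames, hip Euler angles through exactly
# the same machinery as the marker backend, and knee/ankle vector angles
# (the sparse landmark set cannot support full Euler decomposition there).

KINECT_REQUIRED <- c("spine_base", "spine_mid", "hip_l", "hip_r",
                     "knee_r", "ankle_r", "foot_r")

#' Pelvis frame from depth-sensor landmarks
#'
#' As printed for the depth sensor: origin at the spine base; y from spine
#' base to spine mid; x = y cross (hip-left -> hip-right), anterior; z = x
#' cross y, to the subject's right. The y axis is re-orthogonalized against
#' the hip line implicitly through the double cross product.
#'
#' @param spine_base,spine_mid,hip_l,hip_r landmark positions, metres.
#' @return a `segment_frame` with printed axes (x anterior, y up, z right).
#' @export
pelvis_frame_kinect <- function(spine_base, spine_mid, hip_l, hip_r) {
  y <- unit3(spine_mid - spine_base, "spine axis")
  hips <- hip_r - hip_l
  xraw <- cross3(y, hips)
  if (norm3(xraw) < 1e-9 * norm3(hips)) {
    stop("degenerate geometry: spine axis parallel to the hip line",
         call. = FALSE)
  }
  x <- unit3(xraw, "pelvis anterior axis")
  z <- cross3(x, y)
  segment_frame(spine_base, x, y, z)
}

#' Thigh frame from depth-sensor hip, knee and ankle landmarks
#'
#' As printed: origin at the right knee; y from knee to hip; z = y cross
#' (knee - ankle); x = y cross z. With the knee flexed the z axis points to
#' the subject's left; with the leg exactly straight the construction is
#' degenerate, in which case the previous frame's z axis is carried forward
#' (`prev`), or an error is raised when no previous frame exists.
#'
#' @param hip_r,knee_r,ankle_r landmark positions, metres.
#' @param prev optional previous `segment_frame` for the degeneracy fallback.
#' @return a `segment_frame` with printed axes.
#' @export
thigh_frame_kinect <- function(hip_r, knee_r, ankle_r, prev = NULL) {
  y <- unit3(hip_r - knee_r, "thigh long axis")
  zraw <- cross3(y, knee_r - ankle_r)
  if (norm3(zraw) < 1e-6 * norm3(knee_r - ankle_r)) {
    if (is.null(prev)) {
      stop("degenerate geometry: hip, knee and ankle are collinear and no previous frame is available",
           call. = FALSE)
    }
    zprev <- prev$R[, 3L]
    zraw <- zprev - sum(zprev * y) * y    # re-project off the new long axis
  }
  z <- unit3(zraw, "thigh normal")
  x <- cross3(y, z)
  segment_frame(knee_r, x, y, z)
}

# Permute printed depth-sensor frames into the canonical anatomical
# orientation (x right, y anterior, z up) expected by euler_decompose().
canonicalize_pelvis_kinect <- function(frame) {
  R <- frame$R   # printed: x anterior, y up, z right
  segment_frame(frame$origin, R[, 3L], R[, 1L], R[, 2L])
}

canonicalize_thigh_kinect <- function(frame, right_ref = NULL) {
  R <- frame$R   # printed: x posterior-ish, y up, z left-ish (flexed knee)
  xc <- -R[, 3L]; yc <- -R[, 1L]; zc <- R[, 2L]
  # a hyperextended knee flips the cross-product; re-anchor the mediolateral
  # axis to the pelvis so the hip Euler angles stay continuous
  if (!is.null(right_ref) && sum(xc * right_ref) < 0) {
    xc <- -xc; yc <- -yc
  }
  segment_frame(frame$origin, xc, yc, zc)
}

#' Hip Euler angles from depth-sensor pelvis and thigh frames
#'
#' Identical Euler machinery as the marker backend: the printed frames are
#' permuted to the canonical anatomical orientation and decomposed in the
#' flexion -> adduction -> rotation sequence.
#'
#' @param pelvis,thigh printed `segment_frame`s from
#'   [pelvis_frame_kinect()] / [thigh_frame_kinect()].
#' @return list with `flexion`, `adduction`, `rotation` (degrees), `gimbal`.
#' @export
hip_angles_kinect <- function(pelvis, thigh) {
  pc <- canonicalize_pelvis_kinect(pelvis)
  tc <- canonicalize_thigh_kinect(thigh, right_ref = pc$R[, 1L])
  euler_joint_angles(pc, tc)
}

#' Knee vector angle from depth-sensor landmarks
#'
#' The supplement of the angle enclosed at the knee (between the knee->hip and
#' knee->ankle vectors), i.e. the turning angle of the thigh-to-shank line:
#' 0 deg for a perfectly straight leg, increasing with flexion. Unsigned by
#' construction; [compute_kinect_angles()] resolves hyperextension sign via
#' the pelvis mediolateral axis.
#'
#' @param hip_r,knee_r,ankle_r landmark positions, metres.
#' @return knee flexion angle, degrees.
#' @export
knee_angle_kinect <- function(hip_r, knee_r, ankle_r) {
  u <- unit3(knee_r - hip_r, "hip->knee vector")
  v <- unit3(ankle_r - knee_r, "knee->ankle vector")
  acos(max(-1, min(1, sum(u * v)))) * DEG
}

#' Ankle vector angle from depth-sensor landmarks
#'
#' The angle between the ankle->knee and ankle->foot vectors, referenced to
#' 90 degrees and reported dorsiflexion-positive: a foot perpendicular to the
#' shank reads 0, toes raised toward the shank read positive.
#'
#' @param knee_r,ankle_r,foot_r landmark positions, metres.
#' @return ankle dorsiflexion angle, degrees.
#' @export
ankle_angle_kinect <- function(knee_r, ankle_r, foot_r) {
  u <- unit3(knee_r - ankle_r, "ankle->knee vector")
  v <- unit3(foot_r - ankle_r, "ankle->foot vector")
  90 - acos(max(-1, min(1, sum(u * v)))) * DEG
}

#' Depth-sensor five-DOF joint angles for the right limb
#'
#' Per-frame hip Euler angles (pelvis vs thigh frames) and knee/ankle vector
#' angles in the canonical DOF order. The series is expected to be resampled
#' to a uniform grid and low-pass filtered upstream. Knee flexion sign under
#' hyperextension is resolved by projecting the flexion plane normal onto the
#' pelvis mediolateral axis.
#'
#' @param series a `landmark_series` (kinect dialect), uniform time grid.
#' @return an `angle_series` with channels [DOF_NAMES].
#' @export
compute_kinect_angles <- function(series) {
  stopifnot(inherits(series, "landmark_series"))
  for (nm in KINECT_REQUIRED) get_landmark(series, nm)
  lm <- series$landmarks
  n <- length(series$time)
  ang <- matrix(NA_real_, n, 5L, dimnames = list(NULL, DOF_NAMES))
  prev_thigh <- NULL
  for (i in seq_len(n)) {
    pel <- pelvis_frame_kinect(lm$spine_base[i, ], lm$spine_mid[i, ],
                               lm$hip_l[i, ], lm$hip_r[i, ])
    thigh <- thigh_frame_kinect(lm$hip_r[i, ], lm$knee_r[i, ],
                                lm$ankle_r[i, ], prev = prev_thigh)
    prev_thigh <- thigh
    hip <- hip_angles_kinect(pel, thigh)
    knee <- knee_angle_kinect(lm$hip_r[i, ], lm$knee_r[i, ], lm$ankle_r[i, ])
    # flexion-plane normal vs pelvis mediolateral axis: negative projection
    # means the ankle passed anterior to the thigh line (hyperextension)
    u <- lm$knee_r[i, ] - lm$hip_r[i, ]
    v <- lm$ankle_r[i, ] - lm$knee_r[i, ]
    right_axis <- pel$R[, 3L]             # printed pelvis z = subject's right
    if (sum(cross3(u, v) * right_axis) > 0) knee <- -knee
    ankle <- ankle_angle_kinect(lm$knee_r[i, ], lm$ankle_r[i, ],
                                lm$foot_r[i, ])
    ang[i, ] <- c(hip$flexion, hip$adduction, hip$rotation, knee, ankle)
  }
  angle_series(series$time, ang, DOF_NAMES)
}
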