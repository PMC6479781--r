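# Marker-based (reference system) joint kinematics.
#
# Segment frames follow the optical-capture conventions: pelvis from the two
# ASIS markers and the sacrum, thigh/shank from medial+lateral joint markers
# plus the proximal origin, foot from the 2nd metatarsal head, calcaneus and
# the shank origin. All constructed frames except the foot come out in the
# canonical anatomical orientation (x mediolateral-right, y anterior,
# z longitudinal); the foot frame is stored as printed (y along the long axis
# toward the shank origin) and permuted to canonical form before the ankle
# Euler decomposition.

#' Canonical DOF order of the five-channel gait tensor
#' @export
DOF_NAMES <- c("hip_flexion", "hip_adduction", "hip_rotation",
               "knee_flexion", "ankle_dorsiflexion")

# canonical marker vocabulary (right limb + pelvis)
MARKER_REQUIRED_GAIT <- c("sacrum", "asis_l", "asis_r", "knee_lat",
                          "ankle_lat", "heel", "toe",
                          "thigh_1", "thigh_2", "thigh_3",
                          "shank_1", "shank_2", "shank_3")
MARKER_MEDIAL <- c("knee_med", "ankle_med")

#' Pelvis frame from the ASIS markers and the sacrum
#'
#' Origin at the midpoint of mid-ASIS and sacrum; x toward the right ASIS
#' (from mid-ASIS, so it lies in the ASIS-sacrum plane); z normal to that
#' plane, pointing superiorly; y = z x x (anterior).
#'
#' @param asis_l,asis_r,sacrum length-3 marker positions, metres.
#' @return a `segment_frame`.
#' @export
pelvis_frame_marker <- function(asis_l, asis_r, sacrum) {
  mid_asis <- (asis_l + asis_r) / 2
  origin <- (mid_asis + sacrum) / 2
  x <- unit3(asis_r - mid_asis, "ASIS axis")
  zraw <- cross3(sacrum - mid_asis, x)
  if (norm3(zraw) < 1e-9 * norm3(sacrum - mid_asis)) {
    stop("degenerate geometry: ASIS markers and sacrum are collinear",
         call. = FALSE)
  }
  z <- unit3(zraw, "pelvis normal")
  y <- cross3(z, x)
  segment_frame(origin, x, y, z)
}

#' Fractional hip-joint-center model
#'
#' The hip center is placed from the pelvis origin by fractional offsets along
#' the pelvis axes, each scaled by the inter-ASIS distance (the regression
#' approach of Bell and colleagues). Offsets are configuration, never
#' hard-coded into the pipeline; defaults are Bell-style values for the right
#' hip (lateral +, posterior and distal -).
#'
#' @param lateral,anterior,distal dimensionless fractions of the inter-ASIS
#'   distance along the pelvis x (right), y (anterior) and z (up) axes.
#' @return object of class `hip_center_model`.
#' @export
hip_center_model <- function(lateral = 0.36, anterior = -0.19,
                             distal = -0.30) {
  stopifnot(is.finite(lateral), is.finite(anterior), is.finite(distal))
  structure(list(lateral = lateral, anterior = anterior, distal = distal),
            class = "hip_center_model")
}

#' Hip joint center from a pelvis frame
#'
#' @param frame pelvis `segment_frame`.
#' @param model a [hip_center_model()].
#' @param inter_asis inter-ASIS distance, metres.
#' @param side `"right"` or `"left"` (the lateral offset mirrors for left).
#' @return length-3 point, metres.
#' @export
hip_joint_center <- function(frame, model, inter_asis, side = "right") {
  stopifnot(inherits(frame, "segment_frame"),
            inherits(model, "hip_center_model"), inter_asis > 0)
  lat <- if (identical(side, "left")) -model$lateral else model$lateral
  off <- c(lat, model$anterior, model$distal) * inter_asis
  frame$origin + as.numeric(frame$R %*% off)
}

# Shared med/lat + proximal-origin construction for thigh and shank:
# origin mid of the two joint markers, z toward the proximal point, y normal
# to the (proximal, lateral, medial) plane pointing anteriorly (resolved via
# the lateral-to-medial direction), x = y cross z.
medlat_frame <- function(lat, med, proximal, what) {
  origin <- (lat + med) / 2
  z <- unit3(proximal - origin, paste(what, "long axis"))
  ml <- lat - med                        # medial -> lateral: subject's right
  yraw <- cross3(z, ml)
  if (norm3(yraw) < 1e-9 * norm3(ml)) {
    stop(sprintf("degenerate geometry: %s markers collinear with proximal point",
                 what), call. = FALSE)
  }
  y <- unit3(yraw, paste(what, "normal"))
  x <- cross3(y, z)
  segment_frame(origin, x, y, z)
}

#' Thigh frame from knee markers and the hip joint center
#' @param knee_lat,knee_med lateral/medial knee marker positions, metres.
#' @param hip_center hip joint center, metres.
#' @return a `segment_frame` (origin mid-knee, z toward the hip center).
#' @export
thigh_frame_marker <- function(knee_lat, knee_med, hip_center) {
  medlat_frame(knee_lat, knee_med, hip_center, "knee")
}

#' Shank frame from ankle markers and the thigh origin
#' @param ankle_lat,ankle_med lateral/medial malleolus positions, metres.
#' @param thigh_origin thigh-frame origin (mid-knee), metres.
#' @return a `segment_frame` (origin mid-ankle, z toward the thigh origin).
#' @export
shank_frame_marker <- function(ankle_lat, ankle_med, thigh_origin) {
  medlat_frame(ankle_lat, ankle_med, thigh_origin, "ankle")
}

#' Foot frame from the 2nd metatarsal, calcaneus and shank origin
#'
#' Axes as printed for the reference system (with the right-handed completion):
#' origin at the 2nd metatarsal head, y toward the shank origin, x normal to
#' the (heel, origin, shank origin) plane pointing to the subject's right,
#' z = x cross y.
#'
#' @param toe 2nd metatarsal head position, metres.
#' @param heel calcaneus position, metres.
#' @param shank_origin shank-frame origin (mid-ankle), metres.
#' @return a `segment_frame`.
#' @export
foot_frame_marker <- function(toe, heel, shank_origin) {
  y <- unit3(shank_origin - toe, "foot long axis")
  xraw <- cross3(shank_origin - toe, heel - toe)
  if (norm3(xraw) < 1e-9 * norm3(shank_origin - toe)) {
    stop("degenerate geometry: heel, toe and shank origin are collinear",
         call. = FALSE)
  }
  x <- unit3(xraw, "foot normal")
  z <- cross3(x, y)
  segment_frame(toe, x, y, z)
}

# Foot frames are stored as printed (x right, y long toward shank, z = x cross
# y, posterior-ish); permute to canonical (x right, y anterior, z long).
canonicalize_foot_frame <- function(frame) {
  R <- frame$R
  segment_frame(frame$origin, R[, 1L], -R[, 3L], R[, 2L])
}

#' Euler joint angles between two segment frames
#'
#' Decomposes `R = proximal^T distal` in the intrinsic mobile-axis sequence
#' flexion/extension -> ab/adduction -> internal/external rotation (x-y-z on
#' canonical anatomical frames). Right-limb clinical signs: flexion +,
#' adduction +, internal rotation +. Gimbal proximity (|adduction| > 89 deg)
#' is flagged, never thrown.
#'
#' @param proximal,distal `segment_frame`s in canonical orientation.
#' @return list with `flexion`, `adduction`, `rotation` (degrees), `gimbal`.
#' @export
euler_joint_angles <- function(proximal, distal) {
  stopifnot(inherits(proximal, "segment_frame"),
            inherits(distal, "segment_frame"))
  euler_decompose(crossprod(proximal$R, distal$R))
}

# --- medial-marker reconstruction -------------------------------------------

# Least-squares rigid transform (Kabsch) mapping rows of P onto rows of Q.
kabsch_fit <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2L, cp), sweep(Q, 2L, cq))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cq - as.numeric(R %*% cp))
}

# Learn a medial marker's rigid offset from a 3-marker cluster in the static
# trial, then reconstruct its trajectory from the cluster during gait.
reconstruct_from_cluster <- function(static_pos, cluster_names, medial_name,
                                     gait) {
  P <- do.call(rbind, lapply(cluster_names, function(nm) static_pos[[nm]]))
  med <- static_pos[[medial_name]]
  n <- length(gait$time)
  out <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    Q <- do.call(rbind, lapply(cluster_names,
                               function(nm) gait$landmarks[[nm]][i, ]))
    fit <- kabsch_fit(P, Q)
    out[i, ] <- as.numeric(fit$R %*% med) + fit$t
  }
  out
}

# Time-averaged marker positions of a (static) trial.
static_positions <- function(static) {
  lapply(static$landmarks, colMeans)
}

#' Marker-based five-DOF joint angles for the right limb
#'
#' The full reference pipeline: optional zero-phase 6 Hz Butterworth filtering
#' of marker trajectories, reconstruction of the medial knee/ankle markers
#' (removed after the static calibration trial) as cluster-fixed points
#' learned from the static trial, per-frame segment frames, and the Euler /
#' sign conventions above. Knee flexion is reported flexion-positive and the
#' ankle dorsiflexion-positive.
#'
#' @param series gait-trial `landmark_series` (marker dialect).
#' @param static static-calibration `landmark_series` containing the medial
#'   markers and the clusters.
#' @param model a [hip_center_model()].
#' @param filter_cutoff low-pass cutoff in Hz, or `NULL` to skip filtering.
#' @return an `angle_series` with channels [DOF_NAMES].
#' @export
compute_marker_angles <- function(series, static, model = hip_center_model(),
                                  filter_cutoff = 6) {
  stopifnot(inherits(series, "landmark_series"),
            inherits(static, "landmark_series"))
  for (nm in MARKER_REQUIRED_GAIT) get_landmark(series, nm)
  have_medial <- all(MARKER_MEDIAL %in% names(series$landmarks))
  if (!have_medial) {
    for (nm in c(MARKER_MEDIAL, MARKER_REQUIRED_GAIT)) get_landmark(static, nm)
  }
  if (!is.null(filter_cutoff)) {
    series <- butterworth_lowpass(series, cutoff = filter_cutoff)
  }
  if (!have_medial) {
    sp <- static_positions(static)
    series$landmarks$knee_med <- reconstruct_from_cluster(
      sp, c("thigh_1", "thigh_2", "thigh_3"), "knee_med", series)
    series$landmarks$ankle_med <- reconstruct_from_cluster(
      sp, c("shank_1", "shank_2", "shank_3"), "ankle_med", series)
  }
  lm <- series$landmarks
  n <- length(series$time)
  ang <- matrix(NA_real_, n, 5L, dimnames = list(NULL, DOF_NAMES))
  for (i in seq_len(n)) {
    pel <- pelvis_frame_marker(lm$asis_l[i, ], lm$asis_r[i, ], lm$sacrum[i, ])
    w <- norm3(lm$asis_r[i, ] - lm$asis_l[i, ])
    hjc <- hip_joint_center(pel, model, w, side = "right")
    thigh <- thigh_frame_marker(lm$knee_lat[i, ], lm$knee_med[i, ], hjc)
    shank <- shank_frame_marker(lm$ankle_lat[i, ], lm$ankle_med[i, ],
                                thigh$origin)
    foot <- canonicalize_foot_frame(
      foot_frame_marker(lm$toe[i, ], lm$heel[i, ], shank$origin))
    hip <- euler_joint_angles(pel, thigh)
    knee <- euler_joint_angles(thigh, shank)
    ankle <- euler_joint_angles(shank, foot)
    ang[i, ] <- c(hip$flexion, hip$adduction, hip$rotation,
                  -knee$flexion, ankle$flexion)
  }
  angle_series(series$time, ang, DOF_NAMES)
}
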