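# Synthetic gait: ground-truth joint-angle profiles (truncated Fourier
# series over the cycle) plus forward-kinematic marker and depth-sensor
# landmark trajectories, with a parameterized distortion model for the
# markerless stream. The forward models invert the exact frame constructions
# used by the analysis backends, so on noiseless data the pipelines recover
# the generated angles up to interpolation/filter error.

# Evaluate run-preserving RNG: run expr under a seed, restore global state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation (kept below 2^31).
mix_seed <- function(seed, ...) {
  for (k in c(...)) seed <- (seed * 69069 + k * 7919 + 1) %% 2147483647
  as.integer(seed)
}

#' Fourier description of one DOF's cycle profile
#'
#' `value(phi) = a0 + sum_k a[k] cos(2 pi k phi) + b[k] sin(2 pi k phi)`,
#' phi the cycle fraction in [0, 1]; harmonic order at most 4.
#'
#' @param a0 mean value, degrees.
#' @param a,b cosine / sine harmonic amplitudes, degrees.
#' @return list with `a0`, `a`, `b`.
#' @export
fourier_dof <- function(a0 = 0, a = numeric(0), b = numeric(0)) {
  stopifnot(length(a) <= 4L, length(b) <= 4L)
  list(a0 = a0, a = a, b = b)
}

eval_fourier <- function(dof, phi) {
  v <- rep(dof$a0, length(phi))
  for (k in seq_along(dof$a)) v <- v + dof$a[k] * cos(2 * pi * k * phi)
  for (k in seq_along(dof$b)) v <- v + dof$b[k] * sin(2 * pi * k * phi)
  v
}

# Default profiles: shaped to mimic typical mildly crouched pediatric sagittal
# curves (hip flexion ~35 +- 15 deg, knee ~5-55 deg). The sagittal channels
# use cosine (even) harmonics only, so the heel-forward extremum falls exactly
# on the cycle boundary -- the generator's initial-contact definition.
default_fourier_profiles <- function() {
  list(
    hip_flexion        = fourier_dof(35, a = c(15, -2)),
    hip_adduction      = fourier_dof(2, b = c(5, 1)),
    hip_rotation       = fourier_dof(5, b = c(6)),
    knee_flexion       = fourier_dof(30, a = c(-24, 3)),
    ankle_dorsiflexion = fourier_dof(-3, a = c(-2, 6))
  )
}

#' Configuration of a synthetic gait profile
#'
#' @param cadence steps per minute (> 0); one gait cycle spans two steps.
#' @param n_cycles number of gait cycles (>= 1).
#' @param fourier named list of per-DOF Fourier descriptions
#'   (`fourier_dof`-style lists with `a0`, `a`, `b`; order <= 4), one per
#'   entry of [DOF_NAMES].
#' @param anthropometry named numeric: `pelvis_width` (inter-ASIS), `pelvis_depth`,
#'   `thigh`, `shank`, `foot` segment lengths in metres, all > 0.
#' @param seed integer random seed for every stochastic element downstream.
#' @return object of class `gait_profile_config`.
#' @export
gait_profile_config <- function(cadence = 120, n_cycles = 5,
                                fourier = default_fourier_profiles(),
                                anthropometry = c(pelvis_width = 0.20,
                                                  pelvis_depth = 0.12,
                                                  thigh = 0.32, shank = 0.30,
                                                  foot = 0.15),
                                seed = 1L) {
  if (!is.numeric(cadence) || cadence <= 0) {
    stop("cadence must be > 0 steps/min", call. = FALSE)
  }
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  need <- c("pelvis_width", "pelvis_depth", "thigh", "shank", "foot")
  if (!all(need %in% names(anthropometry)) ||
      any(anthropometry[need] <= 0)) {
    stop("anthropometry must name positive lengths: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(DOF_NAMES %in% names(fourier))) {
    stop("fourier must describe all five DOFs", call. = FALSE)
  }
  structure(list(cadence = cadence, n_cycles = as.integer(n_cycles),
                 fourier = fourier,
                 anthropometry = anthropometry[need],
                 seed = as.integer(seed)),
            class = "gait_profile_config")
}

#' Distortion model for the markerless stream
#'
#' Models the depth sensor's systematic under/over-estimation as an affine
#' map per DOF (gain and offset applied to the true angle before landmark
#' synthesis), optionally with a mild cubic term the linear calibration
#' cannot remove, plus landmark position noise, timestamp jitter and frame
#' dropout.
#'
#' @param gain,offset,cubic numeric length 5 (order [DOF_NAMES]): the distorted
#'   angle is `gain * theta + offset + cubic * theta^3` (degrees).
#' @param noise_sd landmark position noise SD, metres (>= 0).
#' @param jitter_sd timestamp jitter SD, seconds (>= 0); clipped so time stays
#'   strictly increasing.
#' @param rate nominal depth-sensor rate, Hz (default 30).
#' @param dropout per-frame drop probability in [0, 1).
#' @return object of class `distortion_config`.
#' @export
distortion_config <- function(gain = rep(1, 5), offset = rep(0, 5),
                              cubic = rep(0, 5), noise_sd = 0,
                              jitter_sd = 0, rate = 30, dropout = 0) {
  stopifnot(length(gain) == 5L, length(offset) == 5L, length(cubic) == 5L)
  if (any(!is.finite(gain)) || any(gain == 0)) {
    stop("gains must be finite and nonzero", call. = FALSE)
  }
  if (noise_sd < 0 || jitter_sd < 0) stop("noise SDs must be >= 0",
                                          call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)",
                                        call. = FALSE)
  structure(list(gain = gain, offset = offset, cubic = cubic,
                 noise_sd = noise_sd, jitter_sd = jitter_sd, rate = rate,
                 dropout = dropout),
            class = "distortion_config")
}

#' The package's stated depth-sensor distortion world
#'
#' Gains below one on the sagittal hip channel (the device underestimates hip
#' flexion and overestimates extension), modest affine error elsewhere, and a
#' strong cubic term on ankle dorsiflexion only: foot tracking is the
#' device's dominant, systematic failure mode, and its error is deliberately
#' non-affine so the linear method cannot remove it. Noise magnitudes are
#' free parameters of the synthetic world, not estimates of any device.
#'
#' @return a `distortion_config`.
#' @export
default_distortion <- function() {
  distortion_config(gain = c(0.70, 0.80, 0.60, 0.85, 0.60),
                    offset = c(-10, -3, 5, -5, -8),
                    cubic = c(0, 0, 0, 0, 8e-3),
                    noise_sd = 0.004, jitter_sd = 0.003,
                    rate = 30, dropout = 0.02)
}

apply_distortion <- function(angles_mat, dist) {
  out <- angles_mat
  for (j in seq_len(5L)) {
    th <- angles_mat[, j]
    out[, j] <- dist$gain[j] * th + dist$offset[j] + dist$cubic[j] * th^3
  }
  out
}

#' Generate ground-truth joint-angle trajectories
#'
#' Samples the configured Fourier profiles at 100 Hz over `n_cycles` cycles.
#' The curves are periodic and C1-smooth by construction; initial contacts
#' sit exactly on the cycle boundaries.
#'
#' @param cfg a [gait_profile_config()].
#' @return object of class `true_angles`: fields `time` (s), `angles`
#'   (n x 5 matrix, degrees, columns [DOF_NAMES]), `ic_times` (s),
#'   `cycle_time` (s).
#' @export
generate_true_angles <- function(cfg) {
  stopifnot(inherits(cfg, "gait_profile_config"))
  cycle_time <- 120 / cfg$cadence            # two steps per gait cycle
  time <- seq(0, cfg$n_cycles * cycle_time, by = 1 / 100)
  phi <- (time / cycle_time) %% 1
  ang <- vapply(DOF_NAMES, function(nm) eval_fourier(cfg$fourier[[nm]], phi),
                numeric(length(time)))
  colnames(ang) <- DOF_NAMES
  structure(list(time = time, angles = ang,
                 ic_times = (0:cfg$n_cycles) * cycle_time,
                 cycle_time = cycle_time),
            class = "true_angles")
}

# --- shared forward-kinematic chain ----------------------------------------

# Pelvis orientation is held constant (canonical axes: x right = lab +Z,
# y anterior = lab +X, z up = lab +Y); the pelvis translates forward at the
# stride-average speed with a small vertical excursion.
PELVIS_R <- cbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))

pelvis_origin_path <- function(time, cfg, cycle_time) {
  a <- cfg$anthropometry
  height <- a[["thigh"]] + a[["shank"]] + 0.10
  speed <- 0.85 * (a[["thigh"]] + a[["shank"]]) * 2 / cycle_time  # ~stride/T
  cbind(speed * time,
        height + 0.01 * cos(4 * pi * time / cycle_time),
        0)
}

# Segment orientations and joint centres for the right limb at the given
# angles (rows of `ang`), pelvis origins `porg` (rows), for config `cfg`.
right_limb_chain <- function(ang, porg, cfg, model) {
  a <- cfg$anthropometry
  n <- nrow(ang)
  out <- list(hjc = matrix(0, n, 3L), knee = matrix(0, n, 3L),
              ankle = matrix(0, n, 3L),
              T = vector("list", n), S = vector("list", n),
              F = vector("list", n))
  w <- a[["pelvis_width"]]
  for (i in seq_len(n)) {
    hjc <- porg[i, ] + as.numeric(PELVIS_R %*%
      (c(model$lateral, model$anterior, model$distal) * w))
    Tm <- PELVIS_R %*% euler_compose(ang[i, 1L], ang[i, 2L], ang[i, 3L])
    knee <- hjc - a[["thigh"]] * Tm[, 3L]
    Sm <- Tm %*% rot_x(-ang[i, 4L])
    ankle <- knee - a[["shank"]] * Sm[, 3L]
    Fm <- Sm %*% rot_x(ang[i, 5L])
    out$hjc[i, ] <- hjc; out$knee[i, ] <- knee; out$ankle[i, ] <- ankle
    out$T[[i]] <- Tm; out$S[[i]] <- Sm; out$F[[i]] <- Fm
  }
  out
}

# local cluster geometry (canonical segment coords, metres)
THIGH_CLUSTER <- list(thigh_1 = c(0.05, 0.05, -0.12),
                      thigh_2 = c(-0.03, 0.06, -0.18),
                      thigh_3 = c(0.02, 0.07, -0.24))
SHANK_CLUSTER <- list(shank_1 = c(0.04, 0.04, -0.08),
                      shank_2 = c(-0.03, 0.05, -0.14),
                      shank_3 = c(0.02, 0.05, -0.20))

#' Forward-synthesize marker-based landmark trajectories
#'
#' Places the optical marker set (pelvis markers, knee/ankle medial+lateral,
#' thigh/shank clusters, calcaneus, 2nd metatarsal head) by the rigid
#' kinematic chain pelvis -> hip Euler -> thigh -> knee flexion -> shank ->
#' ankle flexion -> foot, such that [compute_marker_angles()] on the
#' noiseless output recovers the input angles.
#'
#' @param angles a `true_angles` object.
#' @param cfg the generating [gait_profile_config()].
#' @param noise_sd additive marker noise SD, metres.
#' @param model hip-center model shared with the analysis side.
#' @param include_medial emit the medial knee/ankle markers (kept for static
#'   trials; removed for gait per protocol).
#' @return a `landmark_series` (marker dialect, 100 Hz).
#' @export
forward_markers <- function(angles, cfg, noise_sd = 0,
                            model = hip_center_model(),
                            include_medial = FALSE) {
  stopifnot(inherits(angles, "true_angles"),
            inherits(cfg, "gait_profile_config"))
  a <- cfg$anthropometry
  time <- angles$time
  n <- length(time)
  porg <- pelvis_origin_path(time, cfg, angles$cycle_time)
  ch <- right_limb_chain(angles$angles, porg, cfg, model)

  w <- a[["pelvis_width"]]; d <- a[["pelvis_depth"]]
  pelvis_local <- list(asis_l = c(-w / 2, d / 2, 0),
                       asis_r = c(w / 2, d / 2, 0),
                       sacrum = c(0, -d / 2, 0))
  lm <- lapply(pelvis_local, function(p) {
    off <- as.numeric(PELVIS_R %*% p)
    porg + matrix(off, n, 3L, byrow = TRUE)
  })

  knee_w <- 0.09; ankle_w <- 0.07
  place <- function(center, frames, local) {
    t(vapply(seq_len(n), function(i) center[i, ] +
               as.numeric(frames[[i]] %*% local), numeric(3L)))
  }
  lm$knee_lat <- place(ch$knee, ch$T, c(knee_w / 2, 0, 0))
  lm$knee_med <- place(ch$knee, ch$T, c(-knee_w / 2, 0, 0))
  lm$ankle_lat <- place(ch$ankle, ch$S, c(ankle_w / 2, 0, 0))
  lm$ankle_med <- place(ch$ankle, ch$S, c(-ankle_w / 2, 0, 0))
  for (nm in names(THIGH_CLUSTER)) {
    lm[[nm]] <- place(ch$hjc, ch$T, THIGH_CLUSTER[[nm]])
  }
  for (nm in names(SHANK_CLUSTER)) {
    lm[[nm]] <- place(ch$knee, ch$S, SHANK_CLUSTER[[nm]])
  }
  # toe directly distal along the foot longitudinal axis (a virtual 2nd
  # metatarsal placement that makes the printed foot frame exactly invert);
  # heel posterior-inferior in the foot plane
  hf <- a[["foot"]]
  lm$toe <- place(ch$ankle, ch$F, c(0, 0, -hf))
  lm$heel <- t(vapply(seq_len(n), function(i) {
    lm$toe[i, ] + as.numeric(ch$F[[i]] %*% c(0, -0.06, 0.02))
  }, numeric(3L)))

  if (!include_medial) lm$knee_med <- lm$ankle_med <- NULL
  if (noise_sd > 0) {
    lm <- with_seed(mix_seed(cfg$seed, 11L), {
      lapply(lm, function(m) m + matrix(stats::rnorm(length(m), 0, noise_sd),
                                        nrow(m), 3L))
    })
  }
  landmark_series(time, lm, MARKER_DIALECT, 100)
}

#' Synthesize a static calibration trial
#'
#' A short standing trial (all joint angles at the configured static pose,
#' default slight flexion) including the medial markers, from which the gait
#' pipeline learns the cluster-fixed medial marker positions.
#'
#' @param cfg a [gait_profile_config()].
#' @param duration seconds of standing (default 1).
#' @param pose named numeric of static joint angles, degrees.
#' @param model hip-center model.
#' @return a `landmark_series` including medial markers.
#' @export
synthetic_static_trial <- function(cfg, duration = 1,
                                   pose = c(hip_flexion = 5, hip_adduction = 0,
                                            hip_rotation = 0, knee_flexion = 8,
                                            ankle_dorsiflexion = 0),
                                   model = hip_center_model()) {
  time <- seq(0, duration, by = 1 / 100)
  ang <- matrix(pose[DOF_NAMES], length(time), 5L, byrow = TRUE,
                dimnames = list(NULL, DOF_NAMES))
  ta <- structure(list(time = time, angles = ang, ic_times = numeric(0),
                       cycle_time = 120 / cfg$cadence), class = "true_angles")
  static_cfg <- cfg
  st <- forward_markers(ta, static_cfg, noise_sd = 0, model = model,
                        include_medial = TRUE)
  # standing still: freeze the pelvis path at its first sample
  st$landmarks <- lapply(st$landmarks, function(m) {
    matrix(m[1L, ], nrow(m), 3L, byrow = TRUE)
  })
  st
}

#' Forward-synthesize depth-sensor landmark trajectories
#'
#' Applies the per-DOF distortion to the true angles, then places the reduced
#' landmark set (spine base/mid, hips, knees, ankles, feet; left limb by
#' half-cycle phase shift) on a jittered ~`rate` Hz time base with optional
#' landmark noise and frame dropout. Deterministic given the config seed.
#'
#' @param angles a `true_angles` object.
#' @param cfg the generating [gait_profile_config()].
#' @param dist a [distortion_config()].
#' @param model hip-center model (used to place the hip landmarks).
#' @return a `landmark_series` (kinect dialect).
#' @export
forward_kinect <- function(angles, cfg, dist, model = hip_center_model()) {
  stopifnot(inherits(angles, "true_angles"),
            inherits(cfg, "gait_profile_config"),
            inherits(dist, "distortion_config"))
  a <- cfg$anthropometry
  t0 <- angles$time[1L]
  tn <- angles$time[length(angles$time)]
  tk <- seq(t0, tn, by = 1 / dist$rate)

  with_seed(mix_seed(cfg$seed, 23L), {
    if (dist$jitter_sd > 0) {
      jit <- stats::rnorm(length(tk), 0, dist$jitter_sd)
      lim <- 0.49 / dist$rate
      tk <- tk + pmax(-lim, pmin(lim, jit))
      tk <- pmin(pmax(tk, t0), tn)
      tk <- sort(tk)
      tk <- tk[c(TRUE, diff(tk) > 1e-6)]
    }
    if (dist$dropout > 0) {
      keep <- stats::runif(length(tk)) >= dist$dropout
      keep[c(1L, length(tk))] <- TRUE      # keep the endpoints
      tk <- tk[keep]
    }
    n <- length(tk)
    truth <- interp_columns(angles$time, angles$angles, tk)
    half <- angles$cycle_time / 2
    tleft <- t0 + ((tk - t0 + half) %% (tn - t0 + 1e-12))
    truth_l <- interp_columns(angles$time, angles$angles, tleft)
    ang_r <- apply_distortion(truth, dist)
    ang_l <- apply_distortion(truth_l, dist)

    porg <- pelvis_origin_path(tk, cfg, angles$cycle_time)
    w <- a[["pelvis_width"]]
    lm <- list(
      spine_base = porg,
      spine_mid = porg + matrix(as.numeric(PELVIS_R %*% c(0, 0, 0.25)),
                                n, 3L, byrow = TRUE)
    )
    chain_side <- function(ang_mat, side) {
      m <- model
      if (identical(side, "left")) m$lateral <- -m$lateral
      ch <- right_limb_chain(ang_mat, porg, cfg, m)
      foot <- t(vapply(seq_len(n), function(i) {
        dorsi <- ang_mat[i, 5L]
        dir <- ch$S[[i]] %*% c(0, cos(dorsi / DEG), sin(dorsi / DEG))
        ch$ankle[i, ] + a[["foot"]] * as.numeric(dir)
      }, numeric(3L)))
      list(hip = ch$hjc, knee = ch$knee, ankle = ch$ankle, foot = foot)
    }
    r <- chain_side(ang_r, "right")
    l <- chain_side(ang_l, "left")
    lm$hip_r <- r$hip; lm$knee_r <- r$knee
    lm$ankle_r <- r$ankle; lm$foot_r <- r$foot
    lm$hip_l <- l$hip; lm$knee_l <- l$knee
    lm$ankle_l <- l$ankle; lm$foot_l <- l$foot

    if (dist$noise_sd > 0) {
      lm <- lapply(lm, function(m) m + matrix(
        stats::rnorm(length(m), 0, dist$noise_sd), nrow(m), 3L))
    }
    landmark_series(tk, lm, KINECT_DIALECT, dist$rate)
  })
}

#' Perturb a gait profile into a new synthetic subject
#'
#' Scales the Fourier amplitudes and shifts the per-DOF means by modest
#' random amounts (keeping the even-harmonic structure of the sagittal
#' channels, so initial contacts stay on the cycle boundaries) and jitters
#' the anthropometry. Deterministic given `seed`.
#'
#' @param base a [gait_profile_config()].
#' @param seed integer.
#' @return a new `gait_profile_config`.
#' @export
perturb_profile <- function(base, seed) {
  with_seed(seed, {
    fourier <- base$fourier
    for (nm in names(fourier)) {
      sc <- stats::runif(1, 0.85, 1.15)
      fourier[[nm]]$a <- fourier[[nm]]$a * sc
      fourier[[nm]]$b <- fourier[[nm]]$b * sc
      fourier[[nm]]$a0 <- fourier[[nm]]$a0 + stats::rnorm(1, 0, 2)
    }
    anthro <- base$anthropometry * stats::runif(5, 0.92, 1.08)
    gait_profile_config(cadence = base$cadence * stats::runif(1, 0.9, 1.1),
                        n_cycles = base$n_cycles, fourier = fourier,
                        anthropometry = anthro, seed = mix_seed(seed, 3L))
  })
}

#' Synthesize a full study cohort
#'
#' The stated synthetic world of the validation study: `n_subjects` subjects
#' (default 10) each walking `n_trials` trials (default 3) on one or two
#' days, captured simultaneously by both systems, plus one additional
#' calibration subject. Between-day variation is injected as a per-day
#' profile perturbation (amplitude/offset), emulating day-to-day gait and
#' sensor placement changes.
#'
#' @param n_subjects,n_trials cohort size (defaults 10 and 3).
#' @param days 1 (validity design) or 2 (reliability design).
#' @param dist a [distortion_config()]; default [default_distortion()].
#' @param day_offset_sd SD (degrees) of the per-day, per-DOF mean shift.
#' @param seed master seed.
#' @return list of trial records (`subject`, `day`, `trial`, `cfg`, `truth`,
#'   `markers`, `static`, `kinect`) plus a `calibration` element with the
#'   extra subject's trials.
#' @export
synthetic_cohort <- function(n_subjects = 10, n_trials = 3, days = 1,
                             dist = default_distortion(), day_offset_sd = 2,
                             seed = 1L) {
  base <- gait_profile_config(seed = seed)
  trials <- list()
  make_subject <- function(subj_seed, label) {
    cfg0 <- perturb_profile(base, subj_seed)
    recs <- list()
    for (day in seq_len(days)) {
      cfg_day <- cfg0
      if (days > 1L) {
        cfg_day$fourier <- with_seed(mix_seed(subj_seed, 100L + day), {
          lapply(cfg0$fourier, function(f) {
            f$a0 <- f$a0 + stats::rnorm(1, 0, day_offset_sd)
            f$a <- f$a * stats::runif(1, 0.95, 1.05)
            f
          })
        })
      }
      static <- synthetic_static_trial(cfg_day)
      for (tr in seq_len(n_trials)) {
        cfg_t <- cfg_day
        cfg_t$seed <- mix_seed(subj_seed, day * 37L, tr)
        truth <- generate_true_angles(cfg_t)
        recs[[length(recs) + 1L]] <- list(
          subject = label, day = day, trial = tr, cfg = cfg_t, truth = truth,
          markers = forward_markers(truth, cfg_t, noise_sd = 0.002),
          static = static,
          kinect = forward_kinect(truth, cfg_t, dist))
      }
    }
    recs
  }
  for (s in seq_len(n_subjects)) {
    trials <- c(trials, make_subject(mix_seed(seed, s), sprintf("S%02d", s)))
  }
  calibration <- make_subject(mix_seed(seed, 9999L), "CAL")
  list(trials = trials, calibration = calibration, dist = dist)
}
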