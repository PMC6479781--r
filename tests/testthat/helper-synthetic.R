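# Shared synthetic fixtures, built in code at test time.

tiny_cfg <- function(n_cycles = 2, seed = 7L) {
  gait_profile_config(n_cycles = n_cycles, seed = seed)
}

# Config whose only non-constant channel is a pure knee sinusoid
# 30 + 25 sin(2 pi phi).
knee_sine_cfg <- function(n_cycles = 2) {
  f <- list(
    hip_flexion = fourier_dof(0), hip_adduction = fourier_dof(0),
    hip_rotation = fourier_dof(0),
    knee_flexion = fourier_dof(30, b = c(25)),
    ankle_dorsiflexion = fourier_dof(0)
  )
  gait_profile_config(n_cycles = n_cycles, fourier = f, seed = 1L)
}

zero_cfg <- function(n_cycles = 2) {
  f <- setNames(lapply(1:5, function(i) fourier_dof(0)), DOF_NAMES)
  gait_profile_config(n_cycles = n_cycles, fourier = f, seed = 1L)
}

# Max per-DOF round-trip RMSE of the marker pipeline on noiseless data.
marker_roundtrip_rmse <- function(cfg, filter_cutoff = 6) {
  truth <- generate_true_angles(cfg)
  mk <- forward_markers(truth, cfg, noise_sd = 0)
  st <- synthetic_static_trial(cfg)
  ang <- compute_marker_angles(mk, st, filter_cutoff = filter_cutoff)
  sqrt(colMeans((ang$angles - truth$angles)^2))
}

# Per-DOF RMSE of the kinect pipeline vs (optionally distorted) truth.
kinect_roundtrip_rmse <- function(cfg, dist = distortion_config(),
                                  rate = 30, against = "truth") {
  truth <- generate_true_angles(cfg)
  kin <- forward_kinect(truth, cfg, dist)
  ru <- resample_uniform(kin, rate)
  ang <- compute_kinect_angles(ru)
  tr <- kinectgait:::interp_columns(truth$time, truth$angles, ru$time)
  target <- if (against == "truth") tr else
    kinectgait:::apply_distortion(tr, dist)
  sqrt(colMeans((ang$angles - target)^2))
}

random_cycles <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    phi <- seq(0, 1, length.out = 101)
    vals <- sapply(1:5, function(j)
      rnorm(1, 20, 10) + rnorm(1, 10, 3) * sin(2 * pi * phi + runif(1, 0, 2 * pi)))
    angle_cycle(vals, DOF_NAMES, trial = sprintf("t%d", i))
  })
}
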