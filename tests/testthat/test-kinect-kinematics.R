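test_that("kinect pelvis frame is axis-aligned in the canonical upright pose", {
  # lab: +X anterior, +Y up, +Z right; printed pelvis axes (x ant, y up, z right)
  f <- pelvis_frame_kinect(spine_base = c(0, 1, 0), spine_mid = c(0, 1.3, 0),
                           hip_l = c(0, 0.95, -0.1), hip_r = c(0, 0.95, 0.1))
  expect_equal(f$R, diag(3), tolerance = 1e-12)
  expect_error(pelvis_frame_kinect(c(0, 1, 0), c(0, 1, 0), c(0, 1, -0.1),
                                   c(0, 1, 0.1)), "zero length")
  expect_error(pelvis_frame_kinect(c(0, 1, 0), c(0, 1.3, 0), c(0, 0.5, 0),
                                   c(0, 1.5, 0)), "parallel")
})

test_that("kinect frames are equivariant under rigid rotation", {
  set.seed(13)
  for (i in 1:10) {
    R <- kinectgait:::random_rotation()
    args <- list(c(0.02, 1, 0.03), c(0.05, 1.32, 0.01),
                 c(-0.01, 0.93, -0.1), c(0.01, 0.94, 0.1))
    f0 <- do.call(pelvis_frame_kinect, args)
    f1 <- do.call(pelvis_frame_kinect,
                  lapply(args, function(p) as.numeric(R %*% p)))
    expect_equal(f1$R, R %*% f0$R, tolerance = 1e-9)
    targs <- list(hip_r = c(0, 0.9, 0.1), knee_r = c(0.05, 0.5, 0.1),
                  ankle_r = c(-0.02, 0.15, 0.1))
    t0 <- do.call(thigh_frame_kinect, targs)
    t1 <- do.call(thigh_frame_kinect,
                  lapply(targs, function(p) as.numeric(R %*% p)))
    expect_equal(t1$R, R %*% t0$R, tolerance = 1e-9)
  }
})

test_that("collinear thigh landmarks fall back to the previous frame or fail", {
  expect_error(thigh_frame_kinect(c(0, 1, 0), c(0, 0.5, 0), c(0, 0, 0)),
               "no previous frame")
  prev <- thigh_frame_kinect(c(0, 0.9, 0), c(0.05, 0.5, 0), c(-0.02, 0.1, 0))
  f <- thigh_frame_kinect(c(0, 1, 0), c(0, 0.5, 0), c(0, 0, 0), prev = prev)
  expect_equal(crossprod(f$R), diag(3), tolerance = 1e-9)
  expect_equal(f$R[, 2], c(0, 1, 0), tolerance = 1e-12)   # y up, carried z
})

test_that("knee vector angle matches an independent arccos computation", {
  # straight leg -> 0; right angle -> 90
  expect_equal(knee_angle_kinect(c(0, 1, 0), c(0, 0, 0), c(0, -1, 0)), 0)
  expect_equal(knee_angle_kinect(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 90)
  set.seed(5)
  for (i in 1:25) {
    h <- rnorm(3); k <- rnorm(3); a <- rnorm(3)
    u <- (k - h) / sqrt(sum((k - h)^2))
    v <- (a - k) / sqrt(sum((a - k)^2))
    oracle <- acos(pmin(1, pmax(-1, sum(u * v)))) * 180 / pi
    expect_equal(knee_angle_kinect(h, k, a), oracle, tolerance = 1e-9)
  }
  expect_error(knee_angle_kinect(c(0, 0, 0), c(0, 0, 0), c(0, -1, 0)),
               "zero length")
})

test_that("ankle vector angle is dorsiflexion-positive", {
  # foot perpendicular to shank -> 0
  expect_equal(ankle_angle_kinect(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  # foot at 120 deg from the shank-up vector -> -30 (toe droop)
  foot <- c(sin(120 * pi / 180), cos(120 * pi / 180), 0)
  expect_equal(ankle_angle_kinect(c(0, 1, 0), c(0, 0, 0), foot), -30,
               tolerance = 1e-9)
  set.seed(6)
  for (i in 1:25) {
    k <- rnorm(3); a <- rnorm(3); f <- rnorm(3)
    u <- (k - a) / sqrt(sum((k - a)^2))
    v <- (f - a) / sqrt(sum((f - a)^2))
    oracle <- 90 - acos(pmin(1, pmax(-1, sum(u * v)))) * 180 / pi
    expect_equal(ankle_angle_kinect(k, a, f), oracle, tolerance = 1e-9)
  }
})

test_that("vector angles are invariant to uniform scaling", {
  h <- c(0.1, 0.9, 0.05); k <- c(0.15, 0.5, 0.04); a <- c(0.1, 0.12, 0.02)
  f <- c(0.25, 0.08, 0.03)
  for (s in c(0.5, 2, 17)) {
    expect_equal(knee_angle_kinect(s * h, s * k, s * a),
                 knee_angle_kinect(h, k, a), tolerance = 1e-9)
    expect_equal(ankle_angle_kinect(s * k, s * a, s * f),
                 ankle_angle_kinect(k, a, f), tolerance = 1e-9)
  }
})

test_that("hip Euler machinery matches the marker backend on shared frames", {
  # identical proximal/distal frames in both backends give identical angles
  set.seed(31)
  for (i in 1:10) {
    Rrel <- euler_compose(runif(1, -40, 60), runif(1, -20, 20),
                          runif(1, -30, 30))
    p <- segment_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    d <- segment_frame(c(0, 0, 0), Rrel[, 1], Rrel[, 2], Rrel[, 3])
    a <- euler_joint_angles(p, d)
    # express the same poses as printed kinect frames: pelvis (ant, up, right)
    pk <- segment_frame(c(0, 0, 0), p$R[, 2], p$R[, 3], p$R[, 1])
    tk <- segment_frame(c(0, 0, 0), -d$R[, 2], d$R[, 3], -d$R[, 1])
    b <- hip_angles_kinect(pk, tk)
    expect_equal(c(b$flexion, b$adduction, b$rotation),
                 c(a$flexion, a$adduction, a$rotation), tolerance = 1e-9)
  }
})

test_that("kinect pipeline round-trips identity distortion to < 0.5 deg", {
  rmse <- kinect_roundtrip_rmse(tiny_cfg(n_cycles = 2))
  expect_lt(max(rmse), 0.5)
})

test_that("affine hip distortion is recovered as the distorted line", {
  cfg <- tiny_cfg(n_cycles = 2)
  dist <- distortion_config(gain = c(0.7, 1, 1, 1, 1),
                            offset = c(-10, 0, 0, 0, 0))
  rmse <- kinect_roundtrip_rmse(cfg, dist, against = "distorted")
  expect_lt(rmse[["hip_flexion"]], 0.5)
})

test_that("missing landmarks are reported by name; static pose is constant", {
  cfg <- tiny_cfg(n_cycles = 1)
  truth <- generate_true_angles(cfg)
  kin <- forward_kinect(truth, cfg, distortion_config())
  kin$landmarks$spine_mid <- NULL
  expect_error(compute_kinect_angles(kin), "spine_mid")
})
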