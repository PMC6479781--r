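test_that("pelvis frame from a symmetric canonical pose is axis-aligned", {
  f <- pelvis_frame_marker(asis_l = c(-0.12, 0, 0.9), asis_r = c(0.12, 0, 0.9),
                           sacrum = c(0, -0.15, 0.9))
  expect_equal(f$R[, 1], c(1, 0, 0), tolerance = 1e-12)   # x to right ASIS
  expect_equal(f$origin, c(0, -0.075, 0.9))
  expect_equal(crossprod(f$R), diag(3), tolerance = 1e-12)
  # z is normal to the marker plane (here the z = 0.9 plane)
  expect_equal(abs(f$R[3, 3]), 1, tolerance = 1e-12)
})

test_that("frame constructions are equivariant under rigid rotation", {
  set.seed(9)
  pts <- list(asis_l = c(-0.12, 0.06, 0.95), asis_r = c(0.13, 0.05, 0.94),
              sacrum = c(0, -0.08, 0.96))
  for (i in 1:10) {
    R <- kinectgait:::random_rotation()
    f0 <- pelvis_frame_marker(pts$asis_l, pts$asis_r, pts$sacrum)
    f1 <- pelvis_frame_marker(as.numeric(R %*% pts$asis_l),
                              as.numeric(R %*% pts$asis_r),
                              as.numeric(R %*% pts$sacrum))
    expect_equal(f1$R, R %*% f0$R, tolerance = 1e-9)
    t0 <- thigh_frame_marker(c(0.05, 0, 0.5), c(-0.04, 0, 0.5),
                             c(0, 0.03, 0.9))
    t1 <- thigh_frame_marker(as.numeric(R %*% c(0.05, 0, 0.5)),
                             as.numeric(R %*% c(-0.04, 0, 0.5)),
                             as.numeric(R %*% c(0, 0.03, 0.9)))
    expect_equal(t1$R, R %*% t0$R, tolerance = 1e-9)
  }
})

test_that("degenerate marker geometry raises errors", {
  expect_error(pelvis_frame_marker(c(-0.1, 0, 0), c(0.1, 0, 0), c(0.3, 0, 0)),
               "collinear")
  expect_error(thigh_frame_marker(c(0.05, 0, 0), c(-0.05, 0, 0), c(0.2, 0, 0)),
               "collinear")
  expect_error(foot_frame_marker(c(0, 0, 0), c(0, -0.1, 0), c(0, -0.2, 0)),
               "collinear")
})

test_that("hip_joint_center applies fractional offsets in pelvis axes", {
  f <- segment_frame(c(1, 2, 3), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  m0 <- hip_center_model(0, 0, 0)
  expect_equal(hip_joint_center(f, m0, 0.24), c(1, 2, 3))
  m <- hip_center_model(0.36, -0.19, -0.30)
  expect_equal(hip_joint_center(f, m, 0.24),
               c(1, 2, 3) + 0.24 * c(0.36, -0.19, -0.30))
  # left mirrors about the sagittal plane
  r <- hip_joint_center(f, m, 0.24, "right") - f$origin
  l <- hip_joint_center(f, m, 0.24, "left") - f$origin
  expect_equal(l, r * c(-1, 1, 1))
})

test_that("euler_joint_angles reports a pure flexion offset as (30, 0, 0)", {
  p <- segment_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  d <- segment_frame(c(0, 0, 0),
                     euler_compose(30, 0, 0)[, 1],
                     euler_compose(30, 0, 0)[, 2],
                     euler_compose(30, 0, 0)[, 3])
  a <- euler_joint_angles(p, d)
  expect_equal(c(a$flexion, a$adduction, a$rotation), c(30, 0, 0),
               tolerance = 1e-12)
  same <- euler_joint_angles(p, p)
  expect_equal(c(same$flexion, same$adduction, same$rotation), c(0, 0, 0))
})

test_that("marker pipeline recovers generated angles (noiseless round trip)", {
  rmse <- marker_roundtrip_rmse(tiny_cfg(n_cycles = 2))
  expect_lt(max(rmse), 0.1)
  # and exactly (to interpolation-free precision) without the filter
  rmse0 <- marker_roundtrip_rmse(tiny_cfg(n_cycles = 2), filter_cutoff = NULL)
  expect_lt(max(rmse0), 1e-9)
})

test_that("joint angles are invariant under a rigid lab-frame rotation", {
  cfg <- tiny_cfg(n_cycles = 1)
  truth <- generate_true_angles(cfg)
  mk <- forward_markers(truth, cfg)
  st <- synthetic_static_trial(cfg)
  a0 <- compute_marker_angles(mk, st, filter_cutoff = NULL)
  set.seed(21)
  R <- kinectgait:::random_rotation()
  rot <- function(s) { s$landmarks <- lapply(s$landmarks,
                                             function(m) m %*% t(R)); s }
  a1 <- compute_marker_angles(rot(mk), rot(st), filter_cutoff = NULL)
  expect_equal(a1$angles, a0$angles, tolerance = 1e-6)
})

test_that("a static pose fed as gait yields constant angles at the pose", {
  cfg <- tiny_cfg()
  st <- synthetic_static_trial(cfg)
  ang <- compute_marker_angles(st, st, filter_cutoff = NULL)
  expect_lt(max(apply(ang$angles, 2, sd)), 1e-9)
  expect_equal(unname(ang$angles[1, ]), c(5, 0, 0, 8, 0), tolerance = 1e-9)
})

test_that("missing markers are reported by name", {
  cfg <- tiny_cfg(n_cycles = 1)
  truth <- generate_true_angles(cfg)
  mk <- forward_markers(truth, cfg)
  st <- synthetic_static_trial(cfg)
  mk$landmarks$sacrum <- NULL
  expect_error(compute_marker_angles(mk, st), "sacrum")
})

test_that("all constructed frames stay orthonormal over a gait trial", {
  cfg <- tiny_cfg(n_cycles = 1)
  truth <- generate_true_angles(cfg)
  mk <- forward_markers(truth, cfg, include_medial = TRUE)
  lm <- mk$landmarks
  for (i in seq(1, length(mk$time), by = 10)) {
    pel <- pelvis_frame_marker(lm$asis_l[i, ], lm$asis_r[i, ], lm$sacrum[i, ])
    th <- thigh_frame_marker(lm$knee_lat[i, ], lm$knee_med[i, ],
                             hip_joint_center(pel, hip_center_model(),
                                              kinectgait:::norm3(lm$asis_r[i, ] - lm$asis_l[i, ])))
    for (f in list(pel, th)) {
      expect_equal(crossprod(f$R), diag(3), tolerance = 1e-9)
      expect_equal(det(f$R), 1, tolerance = 1e-9)
    }
  }
})
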