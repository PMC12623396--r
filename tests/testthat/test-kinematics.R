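make_series <- function(Rs, origins = NULL, tag = "X", side = "R") {
  n <- length(Rs)
  R <- array(0, c(3, 3, n))
  for (i in seq_len(n)) R[, , i] <- Rs[[i]]
  if (is.null(origins)) origins <- matrix(0, n, 3)
  frame_series(tag, side, R, origins, rep(TRUE, n))
}

test_that("identical frames give zero joint angles everywhere", {
  set.seed(71)
  Rs <- random_rotations(20)
  fs <- make_series(Rs)
  a <- joint_angles(list(name = "j", sequence = "zxy", flip = "1,1,1",
                         side = "R"), fs, fs)
  expect_lt(max(abs(a$angles)), 1e-10)
})

test_that("prosthetic knee off-axis angles are structurally zero", {
  set.seed(72)
  # arbitrary socket-clamp/foot-clamp y axes and knee marker motion
  n <- 100
  pk <- dk <- vector("list", n)
  for (i in seq_len(n)) {
    KL <- stats::rnorm(3, sd = 100)
    KM <- KL + 120 * unit3(stats::rnorm(3))
    kf <- knee_frames(KL, KM, unit3(stats::rnorm(3)),
                      unit3(stats::rnorm(3)), "R")
    pk[[i]] <- kf$PK$R; dk[[i]] <- kf$DK$R
  }
  a <- joint_angles(list(name = "rktf", sequence = "zxy", flip = "-1,1,1",
                         side = "R"), make_series(pk), make_series(dk))
  expect_lt(max(abs(a$angles[, 2:3])), 1e-8)
})

test_that("prescribed joint sinusoids are recovered from true frames", {
  n <- 120
  t <- seq_len(n) / 100
  want <- cbind(40 * sin(2 * pi * t), 8 * sin(4 * pi * t),
                5 * cos(2 * pi * t))
  prox <- make_series(random_rotations(1)[rep(1, n)])
  Rs <- lapply(seq_len(n), function(i) {
    prox$R[, , 1] %*% cardan_compose(want[i, ], "zxy")
  })
  a <- joint_angles(list(name = "rh", sequence = "zxy", flip = "1,1,1",
                         side = "R"), prox, make_series(Rs))
  expect_lt(max(abs(a$angles - want)), 1e-6)
})

test_that("virtual ankle reports blade deflection and non-zero statics", {
  fc <- make_series(list(diag(3)), tag = "RFC")
  fd0 <- make_series(list(diag(3)))
  expect_equal(as.numeric(virtual_ankle(fc, fd0, "R")$angles), c(0, 0, 0))
  fd20 <- make_series(list(cardan_compose(c(20, 0, 0), "zyx")))
  expect_equal(unname(virtual_ankle(fc, fd20, "R")$angles[1, 1]), 20,
               tolerance = 1e-10)
  # pre-angled blade: the static reference equals the pre-angle, not 0
  rig <- build_rig("TT", "L", blade_preangle_deg = 10)
  ses <- simulate_session(rig, duration = 0.3, rate = 100, noise_sd = 0)
  cfg <- configure_session("TT", "S", "2026-01-15", side = "L")
  ps <- process_static_trial(cfg, ses$static$trial, ses$wand,
                             ses$wand_geometry)
  sr <- static_reference(ps, cfg)
  expect_equal(unname(sr$latt[1]), 10, tolerance = 1e-8)
})

test_that("pylon misalignment appears as a static knee flexion offset", {
  rig <- build_rig("TF", "L", pylon_misalignment_deg = 5)
  ses <- simulate_session(rig, duration = 0.3, rate = 100, noise_sd = 0)
  cfg <- configure_session("TF", "S", "2026-01-15", side = "L")
  ps <- process_static_trial(cfg, ses$static$trial, ses$wand,
                             ses$wand_geometry)
  sr <- static_reference(ps, cfg)
  expect_equal(unname(sr$lktf[1]), 5, tolerance = 1e-8)
  # neutral joints read zero in the static pose
  expect_lt(max(abs(sr$lhtf)), 1e-8)
  expect_lt(max(abs(sr$rk)), 1e-8)
  # the static reference is reported, never subtracted: dynamic output of
  # the same static pose still carries the offset
  kin <- compute_kinematics(ps, cfg)
  expect_equal(stats::median(kin$lktf$angles[, 1]), 5, tolerance = 1e-8)
})

test_that("segment orientation decomposes pose against the ground", {
  fs <- make_series(list(diag(3), cardan_compose(c(15, 0, 0), "zxy")),
                    tag = "PL")
  a <- segment_orientation(fs)
  expect_equal(as.numeric(a$angles[1, ]), c(0, 0, 0))
  expect_equal(as.numeric(a$angles[2, ]), c(15, 0, 0), tolerance = 1e-10)
})

test_that("cycle normalization resamples onto the percent grid", {
  v <- rep(5, 200)
  nc <- normalize_cycle(v, c(20L, 60L, 120L), "stride")
  expect_length(nc$percent, 101)
  expect_true(all(nc$values == 5))
  expect_equal(nc$foot_off_pct, 40)
  # linear ramp 0..100 between the strikes: sample k reads k
  ramp <- rep(NA_real_, 200)
  ramp[20:120] <- seq(0, 100, length.out = 101)
  nc2 <- normalize_cycle(ramp, c(20L, 60L, 120L), "stride")
  expect_equal(as.numeric(nc2$values), 0:100, tolerance = 1e-9)
  # stance domain spans strike to foot-off
  nc3 <- normalize_cycle(ramp, c(20L, 60L, 120L), "stance")
  expect_equal(nc3$values[101, 1], ramp[60], tolerance = 1e-9)
  expect_equal(nc3$values[1, 1], ramp[20], tolerance = 1e-9)
  # long missing runs flag the cycle
  holey <- ramp
  holey[30:50] <- NA_real_
  expect_warning(nc4 <- normalize_cycle(holey, c(20L, 60L, 120L),
                                        "stride"), "flagged")
  expect_true(nc4$flagged)
})

test_that("blade compression is recovered exactly and is scene-invariant", {
  rig <- build_rig("TT", "L")
  n <- 60
  traj <- static_trajectories(n)
  traj$compression <- 30 * sin(seq(0, pi, length.out = n))^2
  fp_series <- function(trial) {
    nn <- n_frames(trial)
    Rs <- array(0, c(3, 3, nn)); org <- matrix(0, nn, 3)
    for (i in seq_len(nn)) {
      tf <- technical_fp_frame(trial$points$LFP1[i, ],
                               trial$points$LFP2[i, ],
                               trial$points$LFP3[i, ])
      Rs[, , i] <- tf$R; org[i, ] <- tf$origin
    }
    frame_series("LFP", "L", Rs, org, rep(TRUE, nn))
  }
  out <- simulate_trial(rig, traj, rate = 100, events = FALSE)
  comp <- rpf_compression(out$trial, fp_series(out$trial), "LFDA")
  expect_lt(max(abs(comp$compression - traj$compression)), 1e-9)
  # rigid whole-scene motion leaves compression unchanged
  traj2 <- traj
  traj2$forward_x <- seq(0, 3000, length.out = n)
  traj2$pelvis <- cbind(seq(0, 20, length.out = n), 0, 0)
  out2 <- simulate_trial(rig, traj2, rate = 100, events = FALSE)
  comp2 <- rpf_compression(out2$trial, fp_series(out2$trial), "LFDA")
  expect_lt(max(abs(comp2$compression - comp$compression)), 1e-9)
})

test_that("mean running speed is the forward displacement rate", {
  n <- 101
  pts <- list(P = cbind(seq(0, 6700, length.out = n), 1000, 0))
  tr <- new_trial(pts, rate = 100) # 1.0 s span
  expect_equal(mean_running_speed(tr, "P"), 6.7, tolerance = 1e-9)
  tr0 <- new_trial(list(P = matrix(c(5, 5, 5), n, 3, byrow = TRUE)),
                   rate = 100)
  expect_equal(mean_running_speed(tr0, "P"), 0)
})

test_that("mirrored scenes give identical angle traces", {
  # identical prescriptions on a left-prosthetic and a right-prosthetic
  # rig: under the side-harmonized sign conventions every joint and
  # orientation trace must match
  trajs <- default_trajectories(50, 100)
  kin <- list()
  for (side in c("L", "R")) {
    rig <- build_rig("TF", side)
    out <- simulate_trial(rig, trajs, rate = 100, events = FALSE)
    ses <- simulate_session(rig, duration = 0.2, rate = 100)
    cfg <- configure_session("TF", "S", "2026-01-15", side = side)
    ps <- process_static_trial(cfg, ses$static$trial, ses$wand,
                               ses$wand_geometry)
    res <- analyze_trial(cfg, ps, out$trial)
    kin[[side]] <- res$kinematics
  }
  for (nm in names(kin$L)) {
    # swap the side prefix only; the pelvis trace maps to itself
    nm_r <- if (nm == "PL.orient") nm else
      paste0(chartr("lrLR", "rlRL", substr(nm, 1, 1)), substring(nm, 2))
    expect_false(is.null(kin$R[[nm_r]]), label = paste("missing", nm_r))
    expect_lt(max(abs(kin$L[[nm]]$angles - kin$R[[nm_r]]$angles),
                  na.rm = TRUE), 1e-8)
  }
})
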