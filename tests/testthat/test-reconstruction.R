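test_that("rigid fit recovers exact transforms", {
  ref <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0), c(20, 30, 80))
  fit0 <- fit_rigid(ref, ref)
  expect_lt(tf_error(fit0$transform, rigid_transform()), 1e-12)
  expect_equal(fit0$rms, 0, tolerance = 1e-12)
  G <- rigid_transform(cardan_compose(c(90, 0, 0), "zxy"), c(10, 0, 0),
                       check = FALSE)
  cur <- transform_points(G, ref)
  fit <- fit_rigid(ref, cur)
  expect_lt(tf_error(fit$transform, G), 1e-9)
  expect_lt(fit$rms, 1e-9)
})

test_that("rigid fit equals the closed-form quaternion oracle on noisy sets", {
  set.seed(51)
  for (i in 1:200) {
    npts <- sample(3:5, 1)
    ref <- matrix(stats::rnorm(3 * npts, sd = 100), npts, 3)
    if (min(svd(sweep(ref, 2, colMeans(ref)))$d[2]) < 20) next
    G <- random_rigid()
    cur <- transform_points(G, ref) +
      matrix(stats::rnorm(3 * npts, sd = 1), npts, 3)
    fit <- fit_rigid(ref, cur)
    oracle <- horn_fit(ref, cur)
    expect_lt(tf_error(fit$transform, oracle$transform), 1e-9)
    expect_equal(fit$rms, oracle$rms, tolerance = 1e-9)
    expect_gt(det(fit$transform$R), 0)
  }
})

test_that("collinear reference clouds are refused, reflections never returned", {
  ref <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)) * 100
  expect_error(fit_rigid(ref, ref), "collinear")
  # near-planar cloud with noise that would favour a reflection
  set.seed(52)
  for (i in 1:50) {
    ref2 <- cbind(matrix(stats::rnorm(8, sd = 100), 4, 2), stats::rnorm(4, sd = 0.01))
    cur2 <- ref2[, c(2, 1, 3)] + matrix(stats::rnorm(12, sd = 5), 4, 3)
    f <- fit_rigid(ref2, cur2)
    expect_equal(det(f$transform$R), 1, tolerance = 1e-9)
  }
})

test_that("landmarks are reconstructed exactly on rigid synthetic data", {
  ss <- make_small_session("TF", "L")
  ps <- process_static_trial(ss$cfg, ss$ses$static$trial, ss$ses$wand,
                             ss$ses$wand_geometry)
  recon <- reconstruct_markers(ss$ses$dynamic$trial, ps, ss$cfg)
  truth <- ss$ses$dynamic$truth$landmarks
  for (lab in c("LWAM", "LWAL", "LWPM", "LWPL",
                "LCLAL", "LCLPL", "LCLAM", "LCLPM", "LHJC", "RHJC")) {
    ok <- marker_valid(recon, lab)
    expect_true(any(ok))
    expect_lt(max(abs(recon$points[[lab]][ok, ] - truth[[lab]][ok, ])),
              1e-6)
  }
  # static-only socket marker reconstructed against its own static pose
  expect_true("LMAD" %in% names(recon$points))
})

test_that("cluster fits tolerate one occluded marker, KL/KM pass through", {
  ss <- make_small_session("TT", "L")
  # occlude one of the four rpf cluster markers: remaining 3 suffice
  dyn <- ss$ses$dynamic$trial
  dyn$points$LFP1[5:9, ] <- NA_real_
  ps <- process_static_trial(ss$cfg, ss$ses$static$trial, ss$ses$wand,
                             ss$ses$wand_geometry)
  recon <- reconstruct_markers(dyn, ps, ss$cfg)
  truth <- ss$ses$dynamic$truth$landmarks
  expect_true(all(marker_valid(recon, "LWP")[5:9]))
  expect_lt(max(abs(recon$points$LWP[5:9, ] - truth$LWP[5:9, ])), 1e-6)

  # physically measured markers are never SVD-reconstructed
  ssf <- make_small_session("TF", "L")
  psf <- process_static_trial(ssf$cfg, ssf$ses$static$trial, ssf$ses$wand,
                              ssf$ses$wand_geometry)
  reconf <- reconstruct_markers(ssf$ses$dynamic$trial, psf, ssf$cfg)
  expect_identical(reconf$points$LKL, ssf$ses$dynamic$trial$points$LKL)
  expect_identical(reconf$points$LKM, ssf$ses$dynamic$trial$points$LKM)
})

test_that("FP triad backs up occluded foot-clamp markers", {
  ss <- make_small_session("TT", "L")
  ps <- process_static_trial(ss$cfg, ss$ses$static$trial, ss$ses$wand,
                             ss$ses$wand_geometry)
  dyn <- ss$ses$dynamic$trial
  truth_cla <- dyn$points$LCLPL
  dyn$points$LCLPL[11:20, ] <- NA_real_
  fixed <- fallback_fc_from_fp(dyn, ps, ss$cfg)
  expect_true(all(marker_valid(fixed, "LCLPL")[11:20]))
  expect_lt(max(abs(fixed$points$LCLPL[11:20, ] - truth_cla[11:20, ])),
            1e-6)
  # untouched where the primary source is valid
  expect_identical(fixed$points$LCLPL[1:10, ], truth_cla[1:10, ])

  # no occlusion: a no-op
  same <- fallback_fc_from_fp(ss$ses$dynamic$trial, ps, ss$cfg)
  expect_identical(same$points$LCLPL, ss$ses$dynamic$trial$points$LCLPL)

  # both sources out: frames stay invalid
  dyn2 <- ss$ses$dynamic$trial
  dyn2$points$LCLPL[11:20, ] <- NA_real_
  for (l in c("LFP1", "LFP2", "LFP3", "LFPA")) {
    dyn2$points[[l]][11:20, ] <- NA_real_
  }
  still <- fallback_fc_from_fp(dyn2, ps, ss$cfg)
  expect_true(all(!marker_valid(still, "LCLPL")[11:20]))
})
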