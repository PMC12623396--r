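# Frame constructions: neutral-pose identity on both sides, degenerate
# inputs, shared-axis structure of the functional knee, and rigid
# equivariance of every constructor.

test_that("neutral placements give identity triads on both sides", {
  ins <- neutral_frame_inputs()
  mirror <- function(p) p * c(1, 1, -1)
  expect_id <- function(tf, origin = c(0, 0, 0)) {
    expect_lt(max(abs(tf$R - diag(3))), 1e-12)
    expect_lt(max(abs(tf$origin - origin)), 1e-12)
  }
  with(ins$socket, {
    expect_id(socket_frame(LAP, LAD, MAD, FAP, FAD, "R"))
    expect_id(socket_frame(mirror(LAP), mirror(LAD), mirror(MAD),
                           mirror(FAP), mirror(FAD), "L"))
  })
  with(ins$socket_clamp, {
    expect_id(socket_clamp_frame(WAL, WAM, WPL, WPM, "R"))
    expect_id(socket_clamp_frame(mirror(WAL), mirror(WAM), mirror(WPL),
                                 mirror(WPM), "L"))
  })
  with(ins$foot_clamp_C, {
    expect_id(foot_clamp_frame_C(CLA, CLL, CLM, CLP, side = "R"))
    expect_id(foot_clamp_frame_C(mirror(CLA), mirror(CLL), mirror(CLM),
                                 mirror(CLP), side = "L"))
  })
  with(ins$foot_clamp_J, {
    expect_id(foot_clamp_frame_J(CLPL, CLDL, CLPM, CLDM, "R"),
              origin = c(0, 50, 0))
    expect_id(foot_clamp_frame_J(mirror(CLPL), mirror(CLDL), mirror(CLPM),
                                 mirror(CLDM), "L"), origin = c(0, 50, 0))
  })
  with(ins$distal_rpf, {
    expect_id(distal_rpf_frame(FDA, FDM, FDL, "R"), origin = c(100, 0, 0))
    expect_id(distal_rpf_frame(mirror(FDA), mirror(FDM), mirror(FDL), "L"),
              origin = c(100, 0, 0))
  })
  with(ins$technical_fp, {
    expect_id(technical_fp_frame(FP1, FP2, FP3))
  })
  with(ins$pelvis, {
    expect_id(pelvis_frame(RASI, LASI, RPSI, LPSI))
  })
  kf <- knee_frames(c(0, 0, 60), c(0, 0, -60), c(0, 1, 0), c(0, 1, 0), "R")
  expect_id(kf$PK); expect_id(kf$DK)
  kfl <- knee_frames(c(0, 0, -60), c(0, 0, 60), c(0, 1, 0), c(0, 1, 0), "L")
  expect_id(kfl$PK); expect_id(kfl$DK)
  el <- equivalent_leg_frames(c(0, 400, 0), c(0, 400, 80), c(0, 0, 60),
                              c(0, 0, -60), "R")
  expect_id(el$HJC_K)
  el2 <- equivalent_leg_frames(c(0, 400, 0), c(0, 400, 80), c(0, 0, 80),
                               c(0, 0, -60), "R")
  expect_id(el2$GT_KL, origin = c(0, 0, 80))
})

test_that("screw-derived foot-clamp midpoints match hand arithmetic", {
  mp <- foot_clamp_midpoints(CLAL = c(40, 0, 40), CLPL = c(-40, 0, 40),
                             CLAM = c(40, 0, -40), CLPM = c(-40, 0, -40))
  expect_equal(mp$CLA, c(40, 0, 0))
  expect_equal(mp$CLM, c(0, 0, -40))
  expect_equal(mp$CLL, c(0, 0, 40))
  expect_equal(mp$CLP, c(-40, 0, 0))
  tf <- foot_clamp_frame_C(CLAL = c(40, 0, 40), CLPL = c(-40, 0, 40),
                           CLAM = c(40, 0, -40), CLPM = c(-40, 0, -40),
                           side = "R")
  expect_lt(max(abs(tf$R - diag(3))), 1e-12)
})

test_that("degenerate inputs are refused by name", {
  ins <- neutral_frame_inputs()
  # LAP on the LAD-MAD line
  expect_error(socket_frame(c(0, 0, 0), c(0, 0, 50), c(0, 0, -50),
                            ins$socket$FAP, ins$socket$FAD, "R"),
               "degenerate")
  expect_error(socket_clamp_frame(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0),
                                  c(-30, 0, -30), "R"), "degenerate")
  expect_error(knee_frames(c(0, 0, 60), c(0, 0, 60), c(0, 1, 0),
                           c(0, 1, 0), "R"), "degenerate")
  expect_error(foot_clamp_frame_J(c(0, 1, 0), c(0, 2, 0), c(0, 3, 0),
                                  c(0, 4, 0), "R"), "degenerate")
  expect_error(distal_rpf_frame(c(100, 0, 0), c(50, 0, 0), c(200, 0, 0),
                                "R"), "degenerate")
  expect_error(technical_fp_frame(c(50, 0, 0), c(-50, 0, 0), c(0, 0, 0)),
               "degenerate")
  # GT vertically above KL has no sagittal-plane component after removing z
  expect_error(equivalent_leg_frames(c(0, 400, 0), c(0, 0, 100),
                                     c(0, 0, 80), c(0, 0, -60), "R"),
               "degenerate")
})

test_that("functional knee frames share the hinge axis exactly", {
  set.seed(31)
  for (i in 1:50) {
    KL <- stats::rnorm(3, sd = 100); KM <- KL + stats::rnorm(3, sd = 100)
    y1 <- unit3(stats::rnorm(3)); y2 <- unit3(stats::rnorm(3))
    kf <- try(knee_frames(KL, KM, y1, y2, "R"), silent = TRUE)
    if (inherits(kf, "try-error")) next
    expect_lt(max(abs(kf$PK$R[, 3L] - kf$DK$R[, 3L])), 1e-12)
  }
})

test_that("a foot-clamp y tilt appears as a pure-z knee rotation", {
  y_sc <- c(0, 1, 0)
  y_fc <- as.numeric(cardan_compose(c(15, 0, 0), "zxy") %*% y_sc)
  kf <- knee_frames(c(0, 0, 60), c(0, 0, -60), y_sc, y_fc, "R")
  rel <- relative_transform(kf$PK, kf$DK)
  a <- cardan_decompose(rel$R, "zxy")
  expect_equal(a, c(15, 0, 0), tolerance = 1e-10)
})

test_that("a bent blade appears on the first virtual-ankle angle", {
  ins <- neutral_frame_inputs()
  fc <- with(ins$foot_clamp_C, foot_clamp_frame_C(CLA, CLL, CLM, CLP,
                                                  side = "R"))
  bend <- cardan_compose(c(20, 0, 0), "zyx")
  fd_pts <- lapply(ins$distal_rpf, function(p) as.numeric(bend %*% p))
  fd <- distal_rpf_frame(fd_pts$FDA, fd_pts$FDM, fd_pts$FDL, "R")
  a <- cardan_decompose(relative_transform(fc, fd)$R, "zyx")
  expect_equal(a, c(20, 0, 0), tolerance = 1e-10)
})

test_that("every frame construction is equivariant under rigid motion", {
  set.seed(32)
  ins <- neutral_frame_inputs()
  check_equiv <- function(build, pts, n = 50) {
    base <- build(pts)
    for (i in seq_len(n)) {
      G <- random_rigid()
      moved <- build(apply_rigid_pts(G, pts))
      expect_lt(tf_error(moved, compose_transforms(G, base)), 1e-9)
    }
  }
  check_equiv(function(p) socket_frame(p$LAP, p$LAD, p$MAD, p$FAP, p$FAD,
                                       "R"), ins$socket)
  check_equiv(function(p) socket_clamp_frame(p$WAL, p$WAM, p$WPL, p$WPM,
                                             "R"), ins$socket_clamp)
  check_equiv(function(p) foot_clamp_frame_C(p$CLA, p$CLL, p$CLM, p$CLP,
                                             side = "R"), ins$foot_clamp_C)
  check_equiv(function(p) foot_clamp_frame_J(p$CLPL, p$CLDL, p$CLPM,
                                             p$CLDM, "R"), ins$foot_clamp_J)
  check_equiv(function(p) distal_rpf_frame(p$FDA, p$FDM, p$FDL, "R"),
              ins$distal_rpf)
  check_equiv(function(p) technical_fp_frame(p$FP1, p$FP2, p$FP3),
              ins$technical_fp)
  check_equiv(function(p) pelvis_frame(p$RASI, p$LASI, p$RPSI, p$LPSI),
              ins$pelvis)
  knee_pts <- list(KL = c(0, 0, 60), KM = c(0, 0, -60), Y = c(0, 300, 0))
  check_equiv(function(p) {
    y <- unit3(p$Y - (p$KL + p$KM) / 2)
    knee_frames(p$KL, p$KM, y, y, "R")$PK
  }, knee_pts)
  hjc_pts <- list(HJC = c(10, 400, 5), GT = c(0, 380, 90),
                  KL = c(0, 0, 60), KM = c(0, 0, -60))
  check_equiv(function(p) equivalent_leg_frames(p$HJC, p$GT, p$KL, p$KM,
                                                "R")$HJC_K, hjc_pts)
})

test_that("the 2D equivalent-leg frame is equivariant within its plane family", {
  # GT-KL projects onto the lab sagittal plane and pins z to the lab
  # lateral axis, so equivariance holds for transforms preserving that
  # structure: rotations about lab z plus translations.
  set.seed(33)
  pts <- list(HJC = c(10, 400, 5), GT = c(0, 380, 90),
              KL = c(0, 0, 80), KM = c(0, 0, -60))
  base <- equivalent_leg_frames(pts$HJC, pts$GT, pts$KL, pts$KM, "R")$GT_KL
  for (i in 1:50) {
    G <- rigid_transform(cardan_compose(c(stats::runif(1, -90, 90), 0, 0),
                                        "zxy"),
                         stats::runif(3, -500, 500), check = FALSE)
    moved <- equivalent_leg_frames(
      transform_points(G, pts$HJC), transform_points(G, pts$GT),
      transform_points(G, pts$KL), transform_points(G, pts$KM), "R")$GT_KL
    expect_lt(tf_error(moved, compose_transforms(G, base)), 1e-9)
    expect_equal(moved$R[, 3L], c(0, 0, 1))
  }
})
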