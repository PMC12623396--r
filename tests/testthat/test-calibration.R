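wand_trial_at <- function(G, geometry, n = 20, extra = list()) {
  pts <- lapply(rownames(geometry$markers), function(l) {
    p <- transform_points(G, geometry$markers[l, ])
    matrix(p, n, 3, byrow = TRUE)
  })
  names(pts) <- rownames(geometry$markers)
  new_trial(c(pts, extra), rate = 100)
}

test_that("wand tip is recovered at identity and rotated poses", {
  geom <- default_wand_geometry()
  tr <- wand_trial_at(rigid_transform(), geom)
  expect_equal(as.numeric(wand_tip(tr, geom)), c(0, -200, 0),
               tolerance = 1e-9)
  G <- rigid_transform(cardan_compose(c(90, 0, 0), "zxy"), c(100, 50, -20),
                       check = FALSE)
  tr2 <- wand_trial_at(G, geom)
  expect_equal(as.numeric(wand_tip(tr2, geom)),
               transform_points(G, c(0, -200, 0)), tolerance = 1e-9)
})

test_that("wand tip stays within noise amplitude under marker noise", {
  set.seed(41)
  geom <- default_wand_geometry()
  G <- random_rigid()
  truth <- transform_points(G, geom$tip)
  n <- 50
  pts <- lapply(rownames(geom$markers), function(l) {
    p <- transform_points(G, geom$markers[l, ])
    matrix(p, n, 3, byrow = TRUE) + matrix(stats::rnorm(3 * n, sd = 0.5),
                                           n, 3)
  })
  names(pts) <- rownames(geom$markers)
  tip <- wand_tip(new_trial(pts, rate = 100), geom)
  expect_lt(sqrt(sum((tip - truth)^2)), 0.5)
})

test_that("wand tip requires enough visible frames", {
  geom <- default_wand_geometry()
  tr <- wand_trial_at(rigid_transform(), geom, n = 5)
  expect_error(wand_tip(tr, geom), "frames")
})

test_that("cluster localization matches hand-computable cases", {
  cluster <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0), c(50, 50, 40))
  n <- 10
  pts <- list(C1 = matrix(cluster[1, ], n, 3, byrow = TRUE),
              C2 = matrix(cluster[2, ], n, 3, byrow = TRUE),
              C3 = matrix(cluster[3, ], n, 3, byrow = TRUE),
              C4 = matrix(cluster[4, ], n, 3, byrow = TRUE))
  tr <- new_trial(pts, rate = 100)
  # a landmark coinciding with a cluster marker has that marker's
  # cluster-frame coordinates
  lmk <- localize_in_cluster(tr, cluster[2, ], c("C1", "C2", "C3"))
  fr <- cluster_frame(cluster[1:3, ])
  expect_equal(lmk$local,
               transform_points(invert_transform(fr), cluster[2, ]),
               tolerance = 1e-12)
  # centroid of a 3-marker cluster maps to the cluster-frame centroid
  lmk2 <- localize_in_cluster(tr, colMeans(cluster[1:3, ]),
                              c("C1", "C2", "C3"))
  locals <- t(apply(cluster[1:3, ], 1,
                    function(p) transform_points(invert_transform(fr), p)))
  expect_equal(lmk2$local, colMeans(locals), tolerance = 1e-12)
})

test_that("wand and cluster calibration are rigid-motion invariant", {
  set.seed(42)
  geom <- default_wand_geometry()
  cluster <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0))
  target <- c(30, 40, 120)
  n <- 12
  mk_scene <- function(G) {
    pts <- list(C1 = NULL, C2 = NULL, C3 = NULL)
    for (k in 1:3) {
      pts[[k]] <- matrix(transform_points(G, cluster[k, ]), n, 3,
                         byrow = TRUE)
    }
    names(pts) <- c("C1", "C2", "C3")
    list(trial = new_trial(pts, rate = 100),
         landmark = transform_points(G, target))
  }
  base <- mk_scene(rigid_transform())
  lmk0 <- localize_in_cluster(base$trial, base$landmark, c("C1", "C2", "C3"))
  for (i in 1:20) {
    G <- random_rigid()
    sc <- mk_scene(G)
    lmk <- localize_in_cluster(sc$trial, sc$landmark, c("C1", "C2", "C3"))
    expect_lt(max(abs(lmk$local - lmk0$local)), 1e-9)
  }
})

test_that("hip joint centre regression scales the inter-ASIS width", {
  expect_equal(hjc_regression(240, "R"), c(-45.6, -72.0, 86.4))
  expect_equal(hjc_regression(240, "L"), c(-45.6, -72.0, -86.4))
  expect_error(hjc_regression(0, "R"), "positive")
  expect_error(hjc_regression(-10, "R"), "positive")
})

test_that("processed static embeds wand landmarks to machine precision", {
  ss <- make_small_session("TT", "L")
  ps <- process_static_trial(ss$cfg, ss$ses$static$trial, ss$ses$wand,
                             ss$ses$wand_geometry)
  expect_true(all(c("LWP", "LWD") %in% names(ps$points)))
  for (lab in ss$cfg$wand_landmarks) {
    truth <- ss$ses$static$truth$landmarks[[lab]][1, ]
    expect_lt(max(abs(ps$points[[lab]][1, ] - truth)), 1e-6)
  }
  # full reconstructed set: physical + wand + HJC
  expect_true(all(c("RHJC", names(ss$ses$static$trial$points)) %in%
                    names(ps$points)))
})

test_that("processed static without wand landmarks adds regression points only", {
  ss <- make_small_session("TT", "L")
  cfg <- ss$cfg
  cfg$wand_landmarks <- character()
  ps <- build_processed_static(ss$ses$static$trial, list(), cfg)
  expect_setequal(names(ps$points),
                  c(names(ss$ses$static$trial$points), "RHJC"))
})

test_that("reprocessing a processed static is idempotent", {
  ss <- make_small_session("TF", "L")
  ps <- process_static_trial(ss$cfg, ss$ses$static$trial, ss$ses$wand,
                             ss$ses$wand_geometry)
  wand_results <- lapply(ss$ses$wand, wand_tip,
                         geometry = ss$ses$wand_geometry)
  ps2 <- build_processed_static(ps, wand_results, ss$cfg)
  expect_identical(names(ps2$points), names(ps$points))
  for (lab in names(ps$points)) {
    expect_lt(max(abs(ps2$points[[lab]] - ps$points[[lab]])), 1e-9)
  }
})
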