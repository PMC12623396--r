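test_that("bundled models load, validate, and carry the expected chains", {
  tf <- load_model_definition("TF")
  tt <- load_model_definition("TT")
  expect_identical(tf$level, "TF")
  # TF chain includes a tf-tagged hip and a prosthetic knee joint
  expect_true(any(grepl("htf$", tf$chain$name)))
  expect_true(any(grepl("ktf$", tf$chain$name)))
  # TT chain has no prosthetic knee joint: clamp degenerates
  expect_false(any(grepl("ktt$|ktf$", tt$chain$name)))
  expect_true(any(grepl("htt$", tt$chain$name)))
})

test_that("a recipe referencing an unknown marker is rejected by name", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<model name="bad" level="TT" rpf_shapes="J">',
    '<markers><marker name="AAA" type="technical" class="permanent" segment="s"/>',
    '<marker name="BBB" type="technical" class="permanent" segment="s"/>',
    '<marker name="DDD" type="technical" class="permanent" segment="s"/></markers>',
    '<clusters/>',
    '<frames><frame tag="T" recipe="technical_fp" inputs="AAA,BBB,XXX" side="none"/></frames>',
    "<chain/><orientations tags=\"\"/>",
    "</model>"), path)
  expect_error(load_model_definition(path), "XXX")
})

test_that("configurations expand sides and honour level/shape constraints", {
  tf <- load_model_definition("TF")
  cfg_l <- build_configuration(tf, "S01", "2026-01-15", side = "L",
                               rpf_shape = "C")
  expect_true(all(c("LKL", "LKM", "LWAM", "LCLAL") %in% cfg_l$markers$name))
  expect_true("LSC" %in% cfg_l$frames$tag)
  expect_identical(sort(cfg_l$hjc_sides), c("L", "R"))
  cfg_r <- build_configuration(tf, "S01", "2026-01-15", side = "R",
                               rpf_shape = "C")
  expect_identical(nrow(cfg_r$markers), nrow(cfg_l$markers))
  # mirror-prefixed marker sets (swap only the side prefix character)
  swap <- paste0(chartr("LR", "RL", substr(cfg_l$markers$name, 1, 1)),
                 substring(cfg_l$markers$name, 2))
  expect_setequal(cfg_r$markers$name, swap)

  tt <- load_model_definition("TT")
  cfg_tt <- build_configuration(tt, "S02", "2026-01-15", side = "L",
                                rpf_shape = "J")
  expect_true(all(c("LCLPL", "LCLDL", "LCLPM", "LCLDM") %in%
                    cfg_tt$markers$name))
  expect_false("LSC" %in% cfg_tt$frames$tag)
  expect_error(build_configuration(tt, "S02", "2026-01-15", side = "L",
                                   rpf_shape = "C"), "shape")
})

test_that("updates preserve identity, bump revision, flag recalibration", {
  cfg <- configure_session("TF", "S01", "2026-01-15", side = "L")
  up <- update_configuration(cfg, "static_002")
  expect_identical(up$revision, 2L)
  expect_identical(up$subject_id, cfg$subject_id)
  expect_identical(up$session_date, cfg$session_date)
  expect_identical(up$static_ref, "static_002")
  # only the revision and static reference may differ
  same_fields <- setdiff(names(cfg), c("revision", "static_ref",
                                       "recalibrate"))
  expect_identical(up[same_fields], cfg[same_fields])

  # detached socket-cluster marker: socket-hosted wand landmarks flagged
  up2 <- update_configuration(cfg, "static_003", detached = "LLAD")
  expect_setequal(up2$recalibrate, c("LWAM", "LWAL", "LWPM", "LWPL"))
  # detached marker outside any wand-hosting cluster: nothing to redo
  up3 <- update_configuration(cfg, "static_004", detached = "LFDA")
  expect_identical(up3$recalibrate, character())

  expect_error(update_configuration(cfg, "s", side = "R"),
               "new configuration")
  expect_error(update_configuration(cfg, "s", level = "TT"),
               "new configuration")
})

test_that("configuration XML round-trips and JSON export is valid", {
  cfg <- configure_session("TT", "S09", "2026-02-02", side = "R")
  cfg <- update_configuration(cfg, "static_b", detached = "RFP1")
  path <- withr::local_tempfile(fileext = ".xml")
  write_configuration(cfg, path)
  cfg2 <- load_configuration(path)
  expect_identical(cfg2$subject_id, cfg$subject_id)
  expect_identical(cfg2$revision, cfg$revision)
  expect_identical(cfg2$recalibrate, cfg$recalibrate)
  expect_identical(cfg2$markers, cfg$markers)
  expect_identical(cfg2$chain, cfg$chain)
  jpath <- withr::local_tempfile(fileext = ".json")
  export_configuration_json(cfg, jpath)
  j <- jsonlite::read_json(jpath)
  expect_identical(j$subject, "S09")
  expect_identical(j$side, "R")
})

test_that("every chain joint's frames are constructible on the bundled rig", {
  for (lvl in c("TF", "TT")) {
    ss <- make_small_session(lvl, "L", duration = 0.3)
    ps <- process_static_trial(ss$cfg, ss$ses$static$trial, ss$ses$wand,
                               ss$ses$wand_geometry)
    frames <- compute_frames(ps, ss$cfg)
    for (i in seq_len(nrow(ss$cfg$chain))) {
      j <- ss$cfg$chain[i, ]
      expect_true(any(frames[[j$prox]]$valid), label = paste(lvl, j$prox))
      expect_true(any(frames[[j$dist]]$valid), label = paste(lvl, j$dist))
    }
  }
})
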