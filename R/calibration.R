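# Landmark calibration: wand-tip digitization, static (CAST) localization
# of landmarks in technical-cluster frames, regression-based hip joint
# centre, and assembly of the processed static trial.

#' Wand geometry descriptor
#'
#' A calibration wand carries >= 3 non-collinear markers at known positions
#' in its own frame, plus a tip offset: pointing the tip at a landmark and
#' fitting the wand geometry to the observed wand markers localizes the
#' landmark globally.
#'
#' @param markers Named list or n x 3 matrix (rownames = labels) of wand
#'   marker coordinates in the wand frame (mm).
#' @param tip Tip offset in the wand frame (mm).
#' @return Object of class `wand_geometry`.
#' @export
wand_geometry <- function(markers, tip) {
  if (is.list(markers)) {
    markers <- do.call(rbind, markers)
  }
  markers <- as.matrix(markers)
  stopifnot(ncol(markers) == 3L, nrow(markers) >= 3L,
            !is.null(rownames(markers)), all(is.finite(tip)))
  sv <- svd(sweep(markers, 2L, colMeans(markers)), nu = 0L, nv = 0L)$d
  if (sv[2L] <= 1e-9 * max(sv[1L], 1)) {
    stop("degenerate geometry: wand markers collinear")
  }
  structure(list(markers = markers, tip = as.numeric(tip)),
            class = "wand_geometry")
}

#' Default wand geometry
#'
#' Four markers on a T-bar with the tip 200 mm below the crossing; used by
#' the synthetic rig and as shipped default for the pipeline.
#' @return `wand_geometry`.
#' @export
default_wand_geometry <- function() {
  wand_geometry(
    markers = rbind(WND1 = c(0, 0, 0), WND2 = c(0, 120, 0),
                    WND3 = c(60, 0, 0), WND4 = c(-60, 0, 0)),
    tip = c(0, -200, 0)
  )
}

#' Localize the wand tip from a wand-pointing trial
#'
#' Per frame with >= 3 visible wand markers, the wand geometry is fitted to
#' the observed markers with [fit_rigid()] and the tip offset is mapped
#' through the fitted pose; the per-frame tips are then averaged with the
#' coordinate-wise median (robust to brief occlusions and outliers).
#'
#' @param trial `rsp_trial` containing the wand markers.
#' @param geometry `wand_geometry`.
#' @param min_frames Minimum number of usable frames (default 10).
#' @param rms_warn Warn when the mean fit rms exceeds this (mm, default 2).
#' @return Global tip position, numeric 3-vector (mm), with attribute
#'   `"rms"` (mean fit residual) and `"n_frames"` used.
#' @export
wand_tip <- function(trial, geometry, min_frames = 10L, rms_warn = 2) {
  labels <- rownames(geometry$markers)
  present <- intersect(labels, names(trial$points))
  if (length(present) < 3L) {
    stop("fewer than 3 wand markers present in trial")
  }
  nf <- n_frames(trial)
  tips <- matrix(NA_real_, nf, 3L)
  rms <- rep(NA_real_, nf)
  for (i in seq_len(nf)) {
    cur <- .frame_points(trial, present, i)
    ok <- stats::complete.cases(cur)
    if (sum(ok) < 3L) next
    fit <- fit_rigid(geometry$markers[present[ok], , drop = FALSE],
                     cur[ok, , drop = FALSE])
    tips[i, ] <- transform_points(fit$transform, geometry$tip)
    rms[i] <- fit$rms
  }
  used <- stats::complete.cases(tips)
  if (sum(used) < min_frames) {
    stop("wand markers visible in only ", sum(used), " frames (need ",
         min_frames, ")")
  }
  mean_rms <- mean(rms[used])
  if (mean_rms > rms_warn) {
    warning("wand fit rms ", format(mean_rms, digits = 3), " mm exceeds ",
            rms_warn, " mm")
  }
  out <- apply(tips[used, , drop = FALSE], 2L, stats::median)
  attr(out, "rms") <- mean_rms
  attr(out, "n_frames") <- sum(used)
  out
}

#' Orthonormal technical-cluster frame from its first three markers
#'
#' Any consistent frame convention cancels in the localize/reconstruct
#' round trip; this one uses origin = first marker, x toward the second,
#' xy-plane through the third.
#'
#' @param p n x 3 matrix of cluster marker positions (n >= 3, mm).
#' @return `rigid_transform`.
#' @export
cluster_frame <- function(p) {
  p <- as.matrix(p)
  stopifnot(nrow(p) >= 3L)
  x <- unit3(p[2L, ] - p[1L, ], "cluster x-axis")
  w <- p[3L, ] - p[1L, ]
  z <- unit3(cross3(x, w), "cluster plane normal")
  y <- cross3(z, x)
  .frame_from_axes(x, y, z, p[1L, ])
}

#' Localize a landmark in a technical-cluster frame (CAST)
#'
#' Expresses a globally known landmark in the frame of its host cluster,
#' averaged (coordinate-wise median) over the frames where the cluster and
#' the landmark are simultaneously valid. The stored local coordinates are
#' exactly invariant under rigid motion of the whole scene.
#'
#' @param static_trial `rsp_trial` with the cluster markers visible.
#' @param landmark_global Either a numeric 3-vector (constant global
#'   position, e.g. a wand-calibrated tip) or the label of a marker in
#'   `static_trial`.
#' @param cluster_labels Character vector (>= 3) of cluster marker labels.
#' @param label Name to give the landmark.
#' @param provenance One of "wand", "static_marker", "regression".
#' @return Object of class `local_landmark`: label, `segment` (filled by
#'   callers), `local` coordinates (mm) in the cluster frame, cluster
#'   labels, provenance.
#' @export
localize_in_cluster <- function(static_trial, landmark_global,
                                cluster_labels, label = "landmark",
                                provenance = "wand") {
  stopifnot(length(cluster_labels) >= 3L)
  nf <- n_frames(static_trial)
  if (is.character(landmark_global)) {
    lm <- static_trial$points[[landmark_global]]
    if (is.null(lm)) stop("no such marker: ", landmark_global)
    label <- landmark_global
  } else {
    lm <- matrix(as.numeric(landmark_global), nf, 3L, byrow = TRUE)
  }
  locals <- matrix(NA_real_, nf, 3L)
  for (i in seq_len(nf)) {
    cur <- .frame_points(static_trial, cluster_labels, i)
    if (anyNA(cur) || anyNA(lm[i, ])) next
    fr <- cluster_frame(cur)
    locals[i, ] <- transform_points(invert_transform(fr), lm[i, ])
  }
  ok <- stats::complete.cases(locals)
  if (!any(ok)) {
    stop("no frame where cluster [", paste(cluster_labels, collapse = ","),
         "] and landmark ", label, " are simultaneously valid")
  }
  structure(list(label = label, segment = NA_character_,
                 local = apply(locals[ok, , drop = FALSE], 2L,
                               stats::median),
                 cluster = cluster_labels, provenance = provenance),
            class = "local_landmark")
}

#' Express a local landmark globally in one frame of a trial
#' @param landmark `local_landmark`.
#' @param trial `rsp_trial` containing the cluster markers.
#' @param i Frame index.
#' @return Numeric 3-vector (mm), or NAs if the cluster is not valid.
#' @export
landmark_global_at <- function(landmark, trial, i) {
  cur <- .frame_points(trial, landmark$cluster, i)
  if (anyNA(cur)) return(rep(NA_real_, 3L))
  transform_points(cluster_frame(cur), landmark$local)
}

#' Regression-based hip joint centre in the pelvis frame
#'
#' Classic ASIS-width regression family: HJC coordinates in the pelvis
#' anatomical frame are fixed fractions of the inter-ASIS distance. The
#' shipped default coefficients (-0.19, -0.30, 0.36) are configurable and
#' follow the common literature defaults; the lateral (z) coefficient is
#' mirrored for the left side.
#'
#' @param inter_asis Inter-ASIS distance PW (mm, > 0).
#' @param side "L" or "R".
#' @param coefficients Numeric 3-vector of (x, y, z) fractions of PW for
#'   the right side.
#' @return Numeric 3-vector: HJC in pelvis-frame coordinates (mm).
#' @export
hjc_regression <- function(inter_asis, side = "R",
                           coefficients = c(-0.19, -0.30, 0.36)) {
  if (!is.numeric(inter_asis) || length(inter_asis) != 1L ||
      !is.finite(inter_asis) || inter_asis <= 0) {
    stop("inter-ASIS distance must be a positive number (mm)")
  }
  s <- .side_sign(side)
  stopifnot(length(coefficients) == 3L)
  coefficients * inter_asis * c(1, 1, s)
}

#' Build the processed static trial
#'
#' Assembles the full reconstructed marker set of a configuration into one
#' static trial: every physical marker of the static trial, plus every
#' wand-calibrated landmark (localized in its host cluster from the wand
#' trials and re-expressed globally), plus the regression-based hip joint
#' centres. Re-running on its own output is idempotent.
#'
#' @param static_trial `rsp_trial` of the standing calibration.
#' @param wand_results Named list (landmark label -> global 3-vector), e.g.
#'   from [wand_tip()] applied to each wand trial; may be empty.
#' @param config `rsp_configuration`.
#' @return `rsp_trial` with all markers, plus attribute `"landmarks"`: the
#'   list of `local_landmark` objects (for dynamic reconstruction).
#' @export
build_processed_static <- function(static_trial, wand_results, config) {
  nf <- n_frames(static_trial)
  pts <- static_trial$points
  landmarks <- list()
  problems <- character()

  add_landmark <- function(lmk) {
    glob <- t(vapply(seq_len(nf), function(i) {
      landmark_global_at(lmk, static_trial, i)
    }, numeric(3L)))
    if (all(!stats::complete.cases(glob))) {
      problems <<- c(problems, paste0(lmk$label, ": cluster never visible"))
      return(invisible(NULL))
    }
    pts[[lmk$label]] <<- glob
    landmarks[[lmk$label]] <<- lmk
  }

  # wand-calibrated landmarks
  for (lab in config$wand_landmarks) {
    seg <- config$hosted[[lab]]
    cluster <- config$clusters[[seg]]
    if (lab %in% names(pts)) next # already measured
    if (is.null(wand_results[[lab]])) {
      problems <- c(problems, paste0(lab, ": no wand calibration provided"))
      next
    }
    lmk <- localize_in_cluster(static_trial, wand_results[[lab]],
                               intersect(cluster, names(pts)),
                               label = lab, provenance = "wand")
    lmk$segment <- seg
    add_landmark(lmk)
  }

  # regression hip joint centres (virtual, pelvis-hosted)
  for (side in config$hjc_sides) {
    lab <- paste0(side, "HJC")
    if (lab %in% names(pts)) next
    pw <- config$anthropometrics[["inter_asis"]]
    if (is.null(pw)) {
      problems <- c(problems, paste0(lab, ": missing inter_asis"))
      next
    }
    local_hjc <- hjc_regression(pw, side, config$hjc_coefficients)
    # express HJC globally per frame via the pelvis anatomical frame,
    # then store relative to the pelvis technical cluster
    pel <- config$clusters[["pelvis"]]
    glob <- matrix(NA_real_, nf, 3L)
    for (i in seq_len(nf)) {
      p <- .frame_points(static_trial, c("RASI", "LASI", "RPSI", "LPSI"), i)
      if (anyNA(p)) next
      fr <- pelvis_frame(p[1L, ], p[2L, ], p[3L, ], p[4L, ])
      glob[i, ] <- transform_points(fr, local_hjc)
    }
    ok <- stats::complete.cases(glob)
    if (!any(ok)) {
      problems <- c(problems, paste0(lab, ": pelvis markers never visible"))
      next
    }
    tip <- apply(glob[ok, , drop = FALSE], 2L, stats::median)
    lmk <- localize_in_cluster(static_trial, tip, pel, label = lab,
                               provenance = "regression")
    lmk$segment <- "pelvis"
    add_landmark(lmk)
  }

  # static-only markers: present now, absent in dynamics; store their
  # cluster-local position so they can be SVD-reconstructed later
  for (lab in config$static_markers) {
    if (!lab %in% names(pts)) {
      problems <- c(problems, paste0(lab, ": static marker missing"))
      next
    }
    seg <- config$hosted[[lab]]
    cluster <- setdiff(config$clusters[[seg]], lab)
    lmk <- localize_in_cluster(static_trial, lab,
                               intersect(cluster, names(pts)),
                               provenance = "static_marker")
    lmk$segment <- seg
    landmarks[[lab]] <- lmk
  }

  if (length(problems)) {
    stop("unresolvable landmarks:\n  ", paste(problems, collapse = "\n  "))
  }
  out <- new_trial(pts, rate = static_trial$rate,
                   events = static_trial$events,
                   first_frame = static_trial$first_frame)
  attr(out, "landmarks") <- landmarks
  out
}
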