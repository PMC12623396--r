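# Frame-series construction and joint/segment kinematics: Cardan joint
# angles along the kinematic chain, roll-pitch-yaw segment orientations,
# static references, stride/stance normalization, RPF compression and mean
# running speed.

#' Per-frame pose series of one coordinate system
#'
#' @param tag CS tag (e.g. "LSK", "LFC", "PL").
#' @param side "L" or "R".
#' @param R 3 x 3 x n rotation array.
#' @param origin n x 3 origin matrix (mm).
#' @param valid Logical vector of length n.
#' @return Object of class `frame_series`.
#' @export
frame_series <- function(tag, side, R, origin, valid) {
  structure(list(tag = tag, side = side, R = R, origin = origin,
                 valid = valid), class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat("<frame_series> ", x$tag, " (side ", x$side, "): ",
      sum(x$valid), "/", length(x$valid), " valid frames\n", sep = "")
  invisible(x)
}

#' Transform at one frame of a series
#' @param fs `frame_series`.
#' @param i Frame index.
#' @return `rigid_transform`, or NULL if the frame is invalid.
#' @export
frame_at <- function(fs, i) {
  if (!fs$valid[i]) return(NULL)
  rigid_transform(fs$R[, , i], fs$origin[i, ], check = FALSE)
}

# Recipe dispatcher: points is a named list of 3-vectors (the recipe's
# inputs in order), dep the y-axis of the dependency frame (knee recipes).
.apply_recipe <- function(recipe, p, side, dep_y = NULL) {
  switch(recipe,
    pelvis = pelvis_frame(p[[1L]], p[[2L]], p[[3L]], p[[4L]]),
    socket = socket_frame(p[[1L]], p[[2L]], p[[3L]], p[[4L]], p[[5L]], side),
    socket_clamp = socket_clamp_frame(p[[1L]], p[[2L]], p[[3L]], p[[4L]],
                                      side),
    foot_clamp_C = foot_clamp_frame_C(CLAL = p[[1L]], CLPL = p[[2L]],
                                      CLAM = p[[3L]], CLPM = p[[4L]],
                                      side = side),
    foot_clamp_J = foot_clamp_frame_J(p[[1L]], p[[2L]], p[[3L]], p[[4L]],
                                      side),
    knee_pk = ,
    knee_dk = {
      kf <- knee_frames(p[[1L]], p[[2L]], dep_y, dep_y, side)
      if (recipe == "knee_pk") kf$PK else kf$DK
    },
    distal_rpf = distal_rpf_frame(p[[1L]], p[[2L]], p[[3L]], side),
    technical_fp = technical_fp_frame(p[[1L]], p[[2L]], p[[3L]]),
    hjc_k = equivalent_leg_frames(p[[1L]], p[[1L]], p[[2L]], p[[3L]],
                                  side)$HJC_K,
    gt_kl = {
      # GT and KL suffice for the 2D system
      y_tmp <- unit3(p[[1L]] - p[[2L]], "GT-to-KL axis")
      y <- unit3(c(y_tmp[1L], y_tmp[2L], 0), "GT-KL sagittal projection")
      z <- c(0, 0, 1)
      x <- unit3(cross3(y, z), "GT-KL forward axis")
      .frame_from_axes(x, y, z, p[[2L]])
    },
    thigh = thigh_frame(p[[1L]], p[[2L]], p[[3L]], side),
    shank = shank_frame((p[[1L]] + p[[2L]]) / 2, p[[3L]], p[[4L]], side),
    foot = foot_frame(p[[1L]], p[[2L]], p[[3L]], side),
    stop("unknown recipe: ", recipe)
  )
}

#' Construct all protocol coordinate systems of a configuration
#'
#' Evaluates every frame recipe of the configuration on each frame of the
#' trial (dependency frames such as the socket-clamp for the proximal
#' functional knee are computed first). Frames whose input markers are not
#' all valid in a sample are invalid in that sample.
#'
#' @param trial `rsp_trial` with all required (reconstructed) markers.
#' @param config `rsp_configuration`.
#' @return Named list of `frame_series`, keyed by CS tag.
#' @export
compute_frames <- function(trial, config) {
  nf <- n_frames(trial)
  fr <- config$frames
  # dependency-free recipes first
  fr <- fr[order(nzchar(fr$depends)), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(fr))) {
    row <- fr[i, ]
    inputs <- .split_csv(row$inputs)
    missing <- setdiff(inputs, names(trial$points))
    if (length(missing)) {
      stop("trial lacks marker(s) ", paste(missing, collapse = ", "),
           " required by frame ", row$tag)
    }
    dep <- NULL
    if (nzchar(row$depends)) {
      dep <- out[[row$depends]]
      if (is.null(dep)) stop("dependency ", row$depends, " of ", row$tag,
                             " not computed")
    }
    R <- array(NA_real_, c(3L, 3L, nf))
    origin <- matrix(NA_real_, nf, 3L)
    valid <- rep(FALSE, nf)
    for (k in seq_len(nf)) {
      pts <- lapply(inputs, function(l) trial$points[[l]][k, ])
      if (anyNA(unlist(pts))) next
      dep_y <- NULL
      if (!is.null(dep)) {
        if (!dep$valid[k]) next
        dep_y <- dep$R[, 2L, k]
      }
      tf <- .apply_recipe(row$recipe, pts, row$side, dep_y)
      R[, , k] <- tf$R
      origin[k, ] <- tf$origin
      valid[k] <- TRUE
    }
    out[[row$tag]] <- frame_series(row$tag, row$side, R, origin, valid)
  }
  out[config$frames$tag]
}

## ---------------------------------------------------------------------------
## angle series

#' Per-frame Cardan angle triplet of one joint or segment
#'
#' @param name Joint/segment name (e.g. "lhtf").
#' @param sequence Cardan sequence tag.
#' @param angles n x 3 matrix, degrees; NA rows for invalid frames, NaN
#'   first/third columns at gimbal lock.
#' @param side "L" or "R".
#' @param convention Free-text sign-convention tag.
#' @return Object of class `angle_series`.
#' @export
angle_series <- function(name, sequence, angles, side,
                         convention = "flexion/adduction/internal+") {
  colnames(angles) <- c("a1", "a2", "a3")
  structure(list(name = name, sequence = sequence, angles = angles,
                 side = side, convention = convention),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat("<angle_series> ", x$name, " [", x$sequence, "], ",
      nrow(x$angles), " frames\n", sep = "")
  invisible(x)
}

# unwrap one angle channel: remove 360-degree jumps between consecutive
# valid samples; NaN/NA frames break the continuity chain
.unwrap_deg <- function(a) {
  out <- a
  offset <- 0
  last <- NA_real_
  for (i in seq_along(a)) {
    if (!is.finite(a[i])) {
      offset <- 0
      last <- NA_real_
      next
    }
    if (is.finite(last)) {
      d <- a[i] + offset - last
      if (d > 180) offset <- offset - 360
      else if (d < -180) offset <- offset + 360
    }
    out[i] <- a[i] + offset
    last <- out[i]
  }
  out
}

# side/joint sign harmonization: positive = anterior leaning / flexion
# (dorsiflexion at the ankle), adduction, internal rotation on both sides.
# The per-joint flip handles flexion polarity; the left side additionally
# flips the 2nd and 3rd channels.
.sign_flips <- function(flip, side) {
  f <- as.numeric(.split_csv(flip))
  if (length(f) != 3L) f <- c(1, 1, 1)
  if (side == "L") f * c(1, -1, -1) else f
}

#' Joint angles from a kinematic-chain entry
#'
#' Per frame, decomposes the relative rotation of the distal frame with
#' respect to the proximal frame using the chain entry's Cardan sequence
#' (zx'y'' for all joints, zy'x'' for ankle-type joints), applies the sign
#' convention (left-side 2nd/3rd channels flipped so positive means
#' adduction / internal rotation bilaterally; per-joint flexion polarity
#' from the chain definition) and unwraps each channel for continuity.
#' Gimbal-locked frames yield NaN in the 1st/3rd channels and are not
#' interpolated.
#'
#' @param chain_entry One row of `config$chain` (or a list with `name`,
#'   `sequence`, `flip`, `side`).
#' @param prox_frames,dist_frames `frame_series` of the proximal and
#'   distal coordinate systems.
#' @return `angle_series`.
#' @export
joint_angles <- function(chain_entry, prox_frames, dist_frames) {
  nf <- length(prox_frames$valid)
  stopifnot(length(dist_frames$valid) == nf)
  ang <- matrix(NA_real_, nf, 3L)
  n_gimbal <- 0L
  for (i in seq_len(nf)) {
    if (!prox_frames$valid[i] || !dist_frames$valid[i]) next
    Rrel <- crossprod(prox_frames$R[, , i], dist_frames$R[, , i])
    a <- cardan_decompose(Rrel, chain_entry$sequence, warn = FALSE)
    if (anyNA(a) && any(is.nan(a))) n_gimbal <- n_gimbal + 1L
    ang[i, ] <- a
  }
  if (n_gimbal > 0L) {
    warning(chain_entry$name, ": ", n_gimbal, " gimbal-locked frame(s)")
  }
  f <- .sign_flips(chain_entry$flip, chain_entry$side)
  ang <- sweep(ang, 2L, f, `*`)
  ang <- apply(ang, 2L, .unwrap_deg)
  if (!is.matrix(ang)) ang <- matrix(ang, ncol = 3L)
  angle_series(chain_entry$name, chain_entry$sequence, ang,
               chain_entry$side)
}

#' Virtual-ankle angles of the running prosthetic foot
#'
#' The virtual ankle is the orientation of the distal RPF portion with
#' respect to the foot-clamp frame, decomposed with the ankle sequence
#' zy'x''. Its neutral (static) dorsi-plantar flexion is generally not
#' zero: the blade tip axis points up or down relative to the clamp
#' depending on the RPF model, so static values must be reported
#' alongside, never subtracted.
#'
#' @param fc_frames,fd_frames `frame_series` of the foot-clamp and distal
#'   RPF coordinate systems.
#' @param side "L" or "R".
#' @param name Joint name (default `<s>att`-style from side).
#' @return `angle_series`.
#' @export
virtual_ankle <- function(fc_frames, fd_frames, side = fc_frames$side,
                          name = paste0(tolower(side), "a.virtual")) {
  joint_angles(list(name = name, sequence = "zyx", flip = "1,1,1",
                    side = side), fc_frames, fd_frames)
}

#' Roll-pitch-yaw segment orientation
#'
#' Decomposes each frame of a segment's pose with respect to the ground
#' with the roll-pitch-yaw convention (see [rpy_decompose()]); channels
#' are (pitch, roll, yaw) reported as (a1, a2, a3) so that a1 is anterior
#' leaning, positive bilaterally, and the left side's lateral channels are
#' flipped like joint angles.
#'
#' @param frames `frame_series`.
#' @return `angle_series` with sequence tag "rpy".
#' @export
segment_orientation <- function(frames) {
  nf <- length(frames$valid)
  ang <- matrix(NA_real_, nf, 3L)
  for (i in seq_len(nf)) {
    if (!frames$valid[i]) next
    rpy <- rpy_decompose(frames$R[, , i], warn = FALSE)
    ang[i, ] <- c(rpy[2L], rpy[1L], rpy[3L]) # pitch, roll, yaw
  }
  f <- .sign_flips("1,1,1", frames$side)
  ang <- sweep(ang, 2L, f, `*`)
  ang <- apply(ang, 2L, .unwrap_deg)
  if (!is.matrix(ang)) ang <- matrix(ang, ncol = 3L)
  angle_series(paste0(frames$tag, ".orient"), "rpy", ang, frames$side,
               convention = "anterior-leaning+ (pitch, roll, yaw)")
}

#' Compute all chain joint angles and segment orientations
#'
#' @param trial `rsp_trial` with all reconstructed markers.
#' @param config `rsp_configuration`.
#' @param frames Optional precomputed [compute_frames()] result.
#' @return Named list of `angle_series` (joints first, then
#'   `<tag>.orient` segment orientations).
#' @export
compute_kinematics <- function(trial, config, frames = NULL) {
  if (is.null(frames)) frames <- compute_frames(trial, config)
  out <- list()
  for (i in seq_len(nrow(config$chain))) {
    entry <- config$chain[i, ]
    out[[entry$name]] <- joint_angles(entry, frames[[entry$prox]],
                                      frames[[entry$dist]])
  }
  for (tag in config$orientations) {
    a <- segment_orientation(frames[[tag]])
    out[[a$name]] <- a
  }
  out
}

#' Static reference angles
#'
#' Median joint and segment angles over the processed static trial. These
#' are reported alongside dynamic output (as the horizontal static lines
#' of protocol plots) and never subtracted from the dynamic curves: static
#' posture is subject- and set-up-specific (e.g. the virtual ankle's
#' neutral dorsiflexion and the prosthetic knee's pylon-misalignment
#' offset are genuinely non-zero).
#'
#' @param processed_static `rsp_trial`.
#' @param config `rsp_configuration`.
#' @return Named list: joint/segment name -> `(a1, a2, a3)` degrees.
#' @export
static_reference <- function(processed_static, config) {
  kin <- compute_kinematics(processed_static, config)
  lapply(kin, function(a) {
    ok <- stats::complete.cases(a$angles)
    if (!any(ok)) stop("no valid static frames for ", a$name)
    apply(a$angles[ok, , drop = FALSE], 2L, stats::median)
  })
}

#' Time-normalize a cycle to 101 samples
#'
#' Resamples an angle (or any per-frame) series to 0-100% of the stride
#' (foot-strike to next same-side foot-strike) or of the stance phase
#' (foot-strike to foot-off) by linear interpolation on a 101-point grid.
#'
#' @param series `angle_series`, or an n x k numeric matrix, or a numeric
#'   vector.
#' @param stride Integer triple `c(strike, foot_off, next_strike)` from
#'   [get_strides()].
#' @param domain "stride" or "stance".
#' @param nan_warn_frac Flag the cycle when any channel has more than this
#'   fraction of missing samples (default 0.1).
#' @return Object of class `normalized_cycle`: `percent` (0:100), `values`
#'   (101 x k), `domain`, `foot_off_pct` (stride domain), `flagged`.
#' @export
normalize_cycle <- function(series, stride, domain = c("stride", "stance"),
                            nan_warn_frac = 0.1) {
  domain <- match.arg(domain)
  values <- if (inherits(series, "angle_series")) series$angles
            else if (is.matrix(series)) series
            else matrix(series, ncol = 1L)
  s0 <- stride[1L]
  s1 <- if (domain == "stride") stride[3L] else stride[2L]
  stopifnot(s1 > s0, s1 <= nrow(values))
  grid <- seq(s0, s1, length.out = 101L)
  frames <- s0:s1
  resampled <- apply(values[frames, , drop = FALSE], 2L, function(v) {
    ok <- is.finite(v)
    if (sum(ok) < 2L) return(rep(NA_real_, 101L))
    stats::approx(frames[ok], v[ok], xout = grid, rule = 1L)$y
  })
  if (!is.matrix(resampled)) resampled <- matrix(resampled, nrow = 101L)
  miss_frac <- max(colMeans(!is.finite(values[frames, , drop = FALSE])))
  flagged <- miss_frac > nan_warn_frac
  if (flagged) {
    warning("cycle flagged: ", round(100 * miss_frac), "% missing samples")
  }
  foot_off_pct <- if (domain == "stride") {
    100 * (stride[2L] - s0) / (s1 - s0)
  } else NA_real_
  structure(list(percent = 0:100, values = resampled, domain = domain,
                 foot_off_pct = foot_off_pct, flagged = flagged),
            class = "normalized_cycle")
}

#' Running-prosthetic-foot compression
#'
#' Expresses the blade-tip marker FDA in the technical proximal-RPF (FP)
#' frame per frame; compression is the shortening of its distance from the
#' FP origin relative to the static (unloaded) reference, in mm, positive
#' when compressed.
#'
#' @param trial `rsp_trial` containing the FDA marker.
#' @param fp_frames `frame_series` of the FP coordinate system.
#' @param fda_label FDA marker label (e.g. "LFDA").
#' @param reference Static reference distance (mm). If NULL, taken from
#'   the first valid frame.
#' @return List: `local` (n x 3 FDA in FP coordinates, mm), `distance`
#'   (n), `compression` (n, mm), `reference` (mm).
#' @export
rpf_compression <- function(trial, fp_frames, fda_label,
                            reference = NULL) {
  fda <- trial$points[[fda_label]]
  if (is.null(fda)) stop("no marker ", fda_label, " in trial")
  nf <- n_frames(trial)
  local <- matrix(NA_real_, nf, 3L)
  for (i in seq_len(nf)) {
    if (!fp_frames$valid[i] || anyNA(fda[i, ])) next
    tf <- invert_transform(rigid_transform(fp_frames$R[, , i],
                                           fp_frames$origin[i, ],
                                           check = FALSE))
    local[i, ] <- transform_points(tf, fda[i, ])
  }
  distance <- sqrt(rowSums(local^2))
  if (is.null(reference)) {
    ok <- which(is.finite(distance))
    if (!length(ok)) stop("FDA never valid in FP frame")
    reference <- distance[ok[1L]]
  }
  list(local = local, distance = distance,
       compression = reference - distance, reference = reference)
}

#' Static RPF length reference for compression
#'
#' Convenience: FDA-to-FP-origin distance (median over valid frames) on
#' the processed static trial, for use as [rpf_compression()] reference.
#' @param processed_static `rsp_trial`.
#' @param config `rsp_configuration`.
#' @return Scalar distance (mm).
#' @export
rpf_static_length <- function(processed_static, config) {
  frames <- compute_frames(processed_static, config)
  fp_tag <- paste0(config$side, "FP")
  res <- rpf_compression(processed_static, frames[[fp_tag]],
                         paste0(config$side, "FDA"))
  stats::median(res$distance[is.finite(res$distance)])
}

#' Mean running speed
#'
#' Mean forward (lab x) velocity of a reference origin over the trial's
#' valid frames, estimated as the slope of a least-squares line fitted to
#' forward position versus time, converted to m/s.
#'
#' @param trial `rsp_trial`.
#' @param frames_tag `frame_series` to track (its origin), or a marker
#'   label present in the trial.
#' @param frames Optional precomputed frame list from [compute_frames()].
#' @return Speed in m/s.
#' @export
mean_running_speed <- function(trial, frames_tag, frames = NULL) {
  if (inherits(frames_tag, "frame_series")) {
    x <- frames_tag$origin[, 1L]
  } else if (!is.null(frames) && frames_tag %in% names(frames)) {
    x <- frames[[frames_tag]]$origin[, 1L]
  } else if (frames_tag %in% names(trial$points)) {
    x <- trial$points[[frames_tag]][, 1L]
  } else {
    stop("frames_tag must be a frame_series, a computed tag or a marker")
  }
  ok <- which(is.finite(x))
  if (length(ok) < 2L) stop("fewer than 2 valid frames for speed")
  t <- (ok - 1L) / trial$rate
  slope <- stats::coef(stats::lm.fit(cbind(1, t), x[ok]))[2L]
  as.numeric(slope) / 1000
}
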