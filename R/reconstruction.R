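# Rigid-pose estimation of technical clusters and frame-by-frame
# reconstruction of virtual and static-only markers in dynamic trials.

#' Least-squares rigid pose from point correspondences
#'
#' Singular-value-decomposition rigid fit: given n >= 3 non-collinear
#' reference points and their observed positions, finds the proper rotation
#' and translation minimizing the sum of squared residuals. A reflection
#' solution (det = -1) is corrected by flipping the sign of the last
#' singular axis, so the result is always a proper rotation.
#'
#' @param ref_points n x 3 matrix, reference configuration (mm).
#' @param cur_points n x 3 matrix, observed configuration (mm).
#' @return Object of class `pose_fit`: list with `transform`
#'   (`rigid_transform` mapping ref to cur), `rms` residual (mm) and
#'   `n_markers`. With exactly 3 markers the fit is exact-by-construction
#'   and flagged with `exact = TRUE`.
#' @export
fit_rigid <- function(ref_points, cur_points) {
  ref_points <- as.matrix(ref_points)
  cur_points <- as.matrix(cur_points)
  n <- nrow(ref_points)
  if (n < 3L || nrow(cur_points) != n) {
    stop("fit_rigid needs >= 3 corresponding point pairs")
  }
  mu_r <- colMeans(ref_points)
  mu_c <- colMeans(cur_points)
  A <- sweep(ref_points, 2L, mu_r)
  B <- sweep(cur_points, 2L, mu_c)
  # collinearity check on the reference cloud
  sv_ref <- svd(A, nu = 0L, nv = 0L)$d
  if (sv_ref[2L] <= 1e-9 * max(sv_ref[1L], 1)) {
    stop("degenerate geometry: collinear reference points in rigid fit")
  }
  H <- crossprod(A, B) # 3x3 correlation matrix
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  origin <- mu_c - as.numeric(R %*% mu_r)
  resid <- cur_points - (ref_points %*% t(R) +
                           matrix(origin, n, 3L, byrow = TRUE))
  rms <- sqrt(mean(rowSums(resid^2)))
  structure(list(transform = rigid_transform(R, origin, check = FALSE),
                 rms = rms, n_markers = n, exact = (n == 3L)),
            class = "pose_fit")
}

#' @export
print.pose_fit <- function(x, ...) {
  cat("<pose_fit> n =", x$n_markers, " rms =", format(x$rms, digits = 4),
      "mm", if (isTRUE(x$exact)) "(exact 3-point fit)" else "", "\n")
  invisible(x)
}

# Positions of `labels` in `trial` at frame i (rows may contain NA)
.frame_points <- function(trial, labels, i) {
  t(vapply(labels, function(l) trial$points[[l]][i, ], numeric(3L)))
}

# Median reference position of labels over the valid frames of a trial
.median_points <- function(trial, labels) {
  t(vapply(labels, function(l) {
    p <- trial$points[[l]]
    ok <- stats::complete.cases(p)
    if (!any(ok)) stop("marker ", l, " never valid")
    apply(p[ok, , drop = FALSE], 2L, stats::median)
  }, numeric(3L)))
}

#' Reconstruct hosted landmarks in a dynamic trial
#'
#' For each frame, the technical cluster of each host segment is fitted
#' (reference geometry from the processed static trial) with [fit_rigid()]
#' using whatever cluster markers are valid in that frame (minimum 3), and
#' the hosted landmarks are mapped through the fitted pose. Frames with
#' insufficient cluster visibility yield invalid samples; nothing is ever
#' extrapolated. Physically measured markers already present in the dynamic
#' trial (e.g. the knee-axis markers KL/KM, which must not be
#' SVD-reconstructed) are passed through untouched.
#'
#' @param dynamic_trial `rsp_trial` to enrich.
#' @param processed_static `rsp_trial` containing cluster markers and all
#'   landmarks (output of [build_processed_static()]).
#' @param config `rsp_configuration`; its `clusters` map (segment ->
#'   technical labels) and `hosted` map (landmark -> segment) drive the
#'   reconstruction.
#' @return `rsp_trial` with the reconstructed landmarks added (or, where
#'   already measured, passed through), plus attribute `"residuals"`:
#'   per-segment mean rms of the cluster fits (mm).
#' @export
reconstruct_markers <- function(dynamic_trial, processed_static, config) {
  nf <- n_frames(dynamic_trial)
  pts <- dynamic_trial$points
  residuals <- list()
  hosted_by_seg <- split(names(config$hosted), unlist(config$hosted))
  for (seg in names(hosted_by_seg)) {
    landmarks <- setdiff(hosted_by_seg[[seg]], names(pts))
    if (!length(landmarks)) next # all physically measured: pass through
    cluster <- config$clusters[[seg]]
    if (is.null(cluster)) stop("no cluster defined for segment ", seg)
    cluster <- intersect(cluster, names(dynamic_trial$points))
    cluster <- intersect(cluster, names(processed_static$points))
    if (length(cluster) < 3L) {
      warning("segment ", seg, ": fewer than 3 cluster markers; landmarks ",
              paste(landmarks, collapse = ", "), " not reconstructed")
      next
    }
    ref_cluster <- .median_points(processed_static, cluster)
    ref_marks <- .median_points(processed_static, landmarks)
    out <- lapply(landmarks, function(l) matrix(NA_real_, nf, 3L))
    names(out) <- landmarks
    rms_acc <- c()
    for (i in seq_len(nf)) {
      cur <- .frame_points(dynamic_trial, cluster, i)
      ok <- stats::complete.cases(cur)
      if (sum(ok) < 3L) next
      fit <- fit_rigid(ref_cluster[ok, , drop = FALSE],
                       cur[ok, , drop = FALSE])
      rms_acc <- c(rms_acc, fit$rms)
      mapped <- transform_points(fit$transform, ref_marks)
      for (k in seq_along(landmarks)) out[[k]][i, ] <- mapped[k, ]
    }
    if (!length(rms_acc)) {
      warning("segment ", seg, ": cluster never sufficiently visible; ",
              "landmarks ", paste(landmarks, collapse = ", "), " absent")
      next
    }
    residuals[[seg]] <- mean(rms_acc)
    pts <- c(pts, out)
  }
  out_trial <- new_trial(pts, rate = dynamic_trial$rate,
                         events = dynamic_trial$events,
                         first_frame = dynamic_trial$first_frame)
  attr(out_trial, "residuals") <- residuals
  out_trial
}

#' Backup reconstruction of foot-clamp markers from the FP triad
#'
#' The technical FP1/FP2/FP3 triad on the proximal blade backs up the
#' foot-clamp markers: in frames where a foot-clamp marker is invalid but
#' the triad is visible, the marker is reconstructed from the triad pose
#' (reference geometry from the processed static trial). Frames where the
#' primary source is valid are left untouched; frames where both sources
#' are invalid stay invalid.
#'
#' @param dynamic_trial `rsp_trial` (possibly already enriched).
#' @param processed_static `rsp_trial` with the static reference geometry.
#' @param config `rsp_configuration`; `config$fc_markers` lists the
#'   foot-clamp marker labels, `config$clusters$rpf_proximal` the triad.
#' @return `rsp_trial` with gap-filled foot-clamp markers.
#' @export
fallback_fc_from_fp <- function(dynamic_trial, processed_static, config) {
  triad <- intersect(config$clusters[["rpf_proximal"]],
                     names(dynamic_trial$points))
  fc <- intersect(config$fc_markers, names(dynamic_trial$points))
  fc <- intersect(fc, names(processed_static$points))
  if (length(triad) < 3L || !length(fc)) return(dynamic_trial)
  nf <- n_frames(dynamic_trial)
  need <- vapply(fc, function(l) !marker_valid(dynamic_trial, l),
                 logical(nf))
  if (!is.matrix(need)) need <- matrix(need, nrow = nf)
  frames_to_fix <- which(rowSums(need) > 0L)
  if (!length(frames_to_fix)) return(dynamic_trial)
  ref_triad <- .median_points(processed_static, triad)
  ref_fc <- .median_points(processed_static, fc)
  pts <- dynamic_trial$points
  for (i in frames_to_fix) {
    cur <- .frame_points(dynamic_trial, triad, i)
    ok <- stats::complete.cases(cur)
    if (sum(ok) < 3L) next
    fit <- fit_rigid(ref_triad[ok, , drop = FALSE], cur[ok, , drop = FALSE])
    mapped <- transform_points(fit$transform, ref_fc)
    for (k in seq_along(fc)) {
      if (need[i, k]) pts[[fc[k]]][i, ] <- mapped[k, ]
    }
  }
  out <- new_trial(pts, rate = dynamic_trial$rate,
                   events = dynamic_trial$events,
                   first_frame = dynamic_trial$first_frame)
  attr(out, "residuals") <- attr(dynamic_trial, "residuals")
  out
}
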