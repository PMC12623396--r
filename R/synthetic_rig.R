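# Forward-kinematics generator of protocol-compliant synthetic sessions:
# an articulated pelvis + prosthetic-limb + sound-limb chain with rigid
# marker clusters placed per the protocol marker set, prescribed joint
# trajectories, optional marker noise and occlusion gaps, and wand-pointing
# trials. Every emitted sample comes with exact ground truth (true frames,
# true joint angles, true landmark positions), so the whole pipeline can be
# verified without laboratory data.

# mirror a right-side local placement for the left side
.mz <- function(p, sgn) c(p[1L], p[2L], sgn * p[3L])

#' Build a synthetic prosthesis-and-body rig
#'
#' Constructs the segment tree and local marker placements for a
#' transfemoral (TF: socket, monocentric hinge knee, C-shape blade) or
#' transtibial (TT: socket with directly bolted J-shape blade, no
#' prosthetic knee) rig, plus pelvis and sound-side thigh/shank/foot.
#' Placements follow the protocol layouts (e.g. FDM/FDL 50 mm proximal to
#' the tip marker FDA); the blade has a revolute + prismatic degree of
#' freedom between its proximal (FP) and distal tip (FD) portions so that
#' virtual-ankle deflection and compression have exact ground truth.
#'
#' @param level "TF" or "TT".
#' @param side Prosthetic side, "L" or "R".
#' @param rpf_shape "C" (TF) or "J" (TT).
#' @param pylon_misalignment_deg Static flexion offset of the prosthetic
#'   knee mount (TF only; default 0). Appears as a constant offset on the
#'   prosthetic-knee flexion channel.
#' @param blade_preangle_deg Static orientation of the blade tip relative
#'   to the clamp (default 10): the virtual ankle's neutral dorsiflexion,
#'   deliberately non-zero.
#' @return Object of class `rsp_rig`.
#' @export
build_rig <- function(level = c("TF", "TT"), side = c("L", "R"),
                      rpf_shape = NULL, pylon_misalignment_deg = 0,
                      blade_preangle_deg = 10) {
  level <- match.arg(level)
  side <- match.arg(side)
  if (is.null(rpf_shape)) rpf_shape <- if (level == "TF") "C" else "J"
  if (level == "TF" && rpf_shape != "C") {
    stop("inconsistent rig spec: TF rig uses the C-shape RPF")
  }
  if (level == "TT" && rpf_shape != "J") {
    stop("inconsistent rig spec: TT rig uses the J-shape RPF")
  }
  s <- if (side == "R") 1 else -1   # prosthetic lateral sign
  cs <- -s                          # sound-side lateral sign
  S <- side
  C <- if (side == "L") "R" else "L"
  m <- function(p) .mz(p, s)
  mc <- function(p) .mz(p, cs)
  pre <- function(x) paste0(S, x)
  prc <- function(x) paste0(C, x)

  pelvis_markers <- list(RASI = c(0, 0, 120), LASI = c(0, 0, -120),
                         RPSI = c(-150, 0, 50), LPSI = c(-150, 0, -50))
  hjc_local <- function(sgn) c(-0.19, -0.30, 0.36 * sgn) * 240

  socket_markers <- stats::setNames(lapply(list(
    FAP = c(50, 300, 0), FAD = c(50, 0, 0),
    LAP = c(0, 300, 50), LAD = c(0, 0, 50), MAD = c(0, 0, -50)
  ), m), pre(c("FAP", "FAD", "LAP", "LAD", "MAD")))
  socket_landmarks <- list()
  if (level == "TF") {
    socket_markers[[pre("GT")]] <- m(c(0, 320, 90))
    socket_markers[[pre("KL")]] <- m(c(0, -180, 60))
    socket_markers[[pre("KM")]] <- m(c(0, -180, -60))
    socket_landmarks <- stats::setNames(lapply(list(
      WAL = c(30, -100, 30), WAM = c(30, -100, -30),
      WPL = c(-30, -100, 30), WPM = c(-30, -100, -30)
    ), m), pre(c("WAL", "WAM", "WPL", "WPM")))
  }

  if (level == "TF") {
    # distal knee body: pylon + foot-clamp + proximal blade; local origin
    # at the knee hinge centre
    shank_markers <- stats::setNames(lapply(list(
      FP1 = c(50, -300, 0), FP2 = c(-50, -300, 0), FP3 = c(0, -340, 0),
      FPA = c(60, -280, 0)
    ), m), pre(c("FP1", "FP2", "FP3", "FPA")))
    shank_landmarks <- stats::setNames(lapply(list(
      CLAL = c(40, -250, 40), CLPL = c(-40, -250, 40),
      CLAM = c(40, -250, -40), CLPM = c(-40, -250, -40)
    ), m), pre(c("CLAL", "CLPL", "CLAM", "CLPM")))
    flex_local <- c(0, -300, 0)    # blade flex point (= FP origin)
    fc_local <- c(0, -250, 0)      # foot-clamp frame origin
  } else {
    # TT: clamp, FP cluster and blade root all solid with the socket
    socket_markers <- c(socket_markers, stats::setNames(lapply(list(
      CLPL = c(-80, -150, 30), CLPM = c(-80, -150, -30),
      CLDL = c(-80, -250, 30), CLDM = c(-80, -250, -30),
      FP1 = c(50, -350, 0), FP2 = c(-50, -350, 0), FP3 = c(0, -390, 0),
      FPA = c(60, -330, 0)
    ), m), pre(c("CLPL", "CLPM", "CLDL", "CLDM",
                 "FP1", "FP2", "FP3", "FPA"))))
    socket_landmarks <- c(socket_landmarks, stats::setNames(lapply(list(
      WP = c(-100, -180, 0), WD = c(-100, -220, 0)
    ), m), pre(c("WP", "WD"))))
    shank_markers <- list()
    shank_landmarks <- list()
    flex_local <- c(0, -350, 0)
    fc_local <- c(-80, -200, 0)
  }

  blade_tip_q <- c(100, -150, 0)   # flex point -> tip, blade-local
  # FDM/FDL 50 mm proximal to the tip, at the blade edges (~60 mm width)
  blade_markers <- stats::setNames(lapply(list(
    FDA = c(0, 0, 0), FDM = c(-50, 0, -30), FDL = c(-50, 0, 30)
  ), m), pre(c("FDA", "FDM", "FDL")))

  thigh_markers <- stats::setNames(lapply(list(
    LEP = c(0, 0, 55), MEP = c(0, 0, -55)), mc), prc(c("LEP", "MEP")))
  shank_s_markers <- stats::setNames(lapply(list(
    LML = c(0, 0, 40), MML = c(0, 0, -40)), mc), prc(c("LML", "MML")))
  foot_markers <- stats::setNames(lapply(list(
    CAL = c(0, 0, 0), MT1 = c(180, 0, -40), MT5 = c(180, 0, 40)
  ), mc), prc(c("CAL", "MT1", "MT5")))

  structure(list(
    level = level, side = side, rpf_shape = rpf_shape,
    s = s, cs = cs, S = S, C = C,
    pelvis_height = 1000,
    hjc_p = hjc_local(s), hjc_s = hjc_local(cs),
    sk_from_hjc = c(0, -250, 0),
    knee_local = c(0, -180, 0),          # knee centre in socket frame (TF)
    flex_local = flex_local, fc_local = fc_local,
    blade_tip_q = blade_tip_q,
    blade_len = sqrt(sum(blade_tip_q^2)),
    preangle = blade_preangle_deg,
    misalignment = pylon_misalignment_deg,
    thigh_len = 400, shank_len = 380, ankle_to_cal = c(-60, -60, 0),
    markers = list(pelvis = pelvis_markers, socket = socket_markers,
                   shank_p = shank_markers, blade = blade_markers,
                   thigh_s = thigh_markers, shank_s = shank_s_markers,
                   foot_s = foot_markers),
    landmarks = list(socket = socket_landmarks,
                     shank_p = shank_landmarks),
    static_only = if (level == "TF") pre(c("MAD", "FPA")) else pre("MAD")
  ), class = "rsp_rig")
}

#' @export
print.rsp_rig <- function(x, ...) {
  cat("<rsp_rig> ", x$level, ", prosthetic side ", x$side, ", ",
      x$rpf_shape, "-shape RPF\n", sep = "")
  invisible(x)
}

# raw (geometric) joint rotation from clinically signed angles
.raw_joint <- function(clinical, flip, side) {
  clinical * .sign_flips(flip, side)
}

# segment poses of the rig at one frame, given clinically signed angles
.rig_poses <- function(rig, ang, forward_x = 0, bob = 0) {
  # pelvis attitude channels: (pitch = anterior leaning, roll, yaw)
  R_pl <- rpy_compose(c(ang$pelvis[2L], ang$pelvis[1L], ang$pelvis[3L]))
  o_pl <- c(forward_x, rig$pelvis_height + bob, 0)
  T_pl <- rigid_transform(R_pl, o_pl, check = FALSE)

  hjc_p <- transform_points(T_pl, rig$hjc_p)
  raw_h <- .raw_joint(ang$hip_p, "1,1,1", rig$side)
  R_sk <- R_pl %*% cardan_compose(raw_h, "zxy")
  o_sk <- hjc_p - as.numeric(R_sk %*% -rig$sk_from_hjc)
  T_sk <- rigid_transform(R_sk, o_sk, check = FALSE)

  poses <- list(pelvis = T_pl, socket = T_sk)
  if (rig$level == "TF") {
    kc <- transform_points(T_sk, rig$knee_local)
    raw_k <- .raw_joint(ang$knee_p, "-1,1,1", rig$side)
    R_sh <- R_sk %*% rot_z(-rig$misalignment * DEG2RAD) %*%
      cardan_compose(raw_k, "zxy")
    poses$shank_p <- rigid_transform(R_sh, kc, check = FALSE)
    blade_host <- poses$shank_p
  } else {
    blade_host <- T_sk
  }
  flex <- transform_points(blade_host, rig$flex_local)
  theta <- (rig$preangle + ang$blade_defl) * DEG2RAD
  R_fd <- blade_host$R %*% rot_z(theta)
  q <- rig$blade_tip_q * (1 - ang$compression / rig$blade_len)
  fda <- flex + as.numeric(R_fd %*% q)
  poses$blade <- rigid_transform(R_fd, fda, check = FALSE)

  hjc_s <- transform_points(T_pl, rig$hjc_s)
  raw_hs <- .raw_joint(ang$hip_s, "1,1,1", rig$C)
  R_th <- R_pl %*% cardan_compose(raw_hs, "zxy")
  kc_s <- hjc_s + as.numeric(R_th %*% c(0, -rig$thigh_len, 0))
  poses$thigh_s <- rigid_transform(R_th, kc_s, check = FALSE)

  raw_ks <- .raw_joint(ang$knee_s, "-1,1,1", rig$C)
  R_shs <- R_th %*% cardan_compose(raw_ks, "zxy")
  ankle <- kc_s + as.numeric(R_shs %*% c(0, -rig$shank_len, 0))
  poses$shank_s <- rigid_transform(R_shs, ankle, check = FALSE)

  raw_as <- .raw_joint(ang$ankle_s, "1,1,1", rig$C)
  R_ft <- R_shs %*% cardan_compose(raw_as, "zyx")
  cal <- ankle + as.numeric(R_ft %*% rig$ankle_to_cal)
  poses$foot_s <- rigid_transform(R_ft, cal, check = FALSE)
  poses
}

# true protocol frame poses from the segment poses
.rig_true_frames <- function(rig, poses) {
  S <- rig$S
  tf <- list(PL = poses$pelvis)
  tf[[paste0(S, "SK")]] <- poses$socket
  if (rig$level == "TF") {
    kc <- transform_points(poses$socket, rig$knee_local)
    tf[[paste0(S, "SC")]] <- rigid_transform(
      poses$socket$R, transform_points(poses$socket, c(0, -100, 0)),
      check = FALSE)
    tf[[paste0(S, "PK")]] <- rigid_transform(poses$socket$R, kc,
                                             check = FALSE)
    tf[[paste0(S, "DK")]] <- rigid_transform(poses$shank_p$R, kc,
                                             check = FALSE)
    tf[[paste0(S, "FC")]] <- rigid_transform(
      poses$shank_p$R, transform_points(poses$shank_p, rig$fc_local),
      check = FALSE)
    tf[[paste0(S, "FP")]] <- rigid_transform(
      poses$shank_p$R, transform_points(poses$shank_p, rig$flex_local),
      check = FALSE)
    tf[[paste0(S, "HJCK")]] <- tf[[paste0(S, "PK")]]
  } else {
    tf[[paste0(S, "FC")]] <- rigid_transform(
      poses$socket$R, transform_points(poses$socket, rig$fc_local),
      check = FALSE)
    tf[[paste0(S, "FP")]] <- rigid_transform(
      poses$socket$R, transform_points(poses$socket, rig$flex_local),
      check = FALSE)
  }
  tf[[paste0(S, "FD")]] <- poses$blade
  tf[[paste0(rig$C, "TH")]] <- poses$thigh_s
  tf[[paste0(rig$C, "SH")]] <- poses$shank_s
  tf[[paste0(rig$C, "FT")]] <- poses$foot_s
  tf
}

#' Default running trajectory prescription
#'
#' Smooth periodic clinically signed joint trajectories emulating steady
#' sprinting: hip flexion sinusoid (+-40 deg), prosthetic-knee flexion
#' raised sinusoid (0-90 deg, TF), blade deflection and compression bumps
#' during stance, sound-side hip/knee/ankle in counter-phase, constant
#' forward speed and a vertical pelvis bob that drives the contact events.
#'
#' @param n_frames Number of frames.
#' @param rate Sampling rate (Hz).
#' @param speed Forward speed (m/s).
#' @param stride_hz Stride frequency (Hz, default 1.5).
#' @param hip_amp,knee_amp,defl_amp,comp_amp Amplitudes (deg, deg, deg,
#'   mm).
#' @return List of per-frame trajectory components for [simulate_trial()].
#' @export
default_trajectories <- function(n_frames, rate, speed = 6.7,
                                 stride_hz = 1.5, hip_amp = 40,
                                 knee_amp = 45, defl_amp = 12,
                                 comp_amp = 25) {
  t <- (seq_len(n_frames) - 1L) / rate
  ph <- 2 * pi * stride_hz * t
  zero <- matrix(0, n_frames, 3L)
  tri <- function(a1, a2 = 0, a3 = 0) cbind(a1, a2 + zero[, 1L],
                                            a3 + zero[, 1L])
  # stance window: cos(ph) near 1; bumps restricted there
  stance <- pmax(0, cos(ph))^2
  list(
    pelvis = tri(2 * sin(ph)),            # small anterior-lean wobble
    hip_p = tri(hip_amp * sin(ph), 3 * sin(2 * ph), 2 * cos(ph)),
    knee_p = tri(knee_amp * (1 - cos(ph))), # 0 at strike, peak in swing
    blade_defl = defl_amp * stance,
    compression = comp_amp * stance,
    hip_s = tri(hip_amp * sin(ph + pi), 3 * sin(2 * ph + 1), 0),
    knee_s = tri(knee_amp * (1 - cos(ph + pi))),
    ankle_s = tri(15 * sin(ph + pi), 4 * sin(ph), 0),
    forward_x = speed * 1000 * t,
    bob = 40 * cos(ph)
  )
}

#' Zero (static standing) trajectory prescription
#' @param n_frames Number of frames.
#' @return Trajectory list with all angles zero and no forward motion.
#' @export
static_trajectories <- function(n_frames) {
  zero <- matrix(0, n_frames, 3L)
  list(pelvis = zero, hip_p = zero, knee_p = zero,
       blade_defl = rep(0, n_frames), compression = rep(0, n_frames),
       hip_s = zero, knee_s = zero, ankle_s = zero,
       forward_x = rep(0, n_frames), bob = rep(0, n_frames))
}

.traj_at <- function(traj, i) {
  list(pelvis = traj$pelvis[i, ], hip_p = traj$hip_p[i, ],
       knee_p = traj$knee_p[i, ], blade_defl = traj$blade_defl[i],
       compression = traj$compression[i], hip_s = traj$hip_s[i, ],
       knee_s = traj$knee_s[i, ], ankle_s = traj$ankle_s[i, ])
}

#' Simulate a trial from the rig
#'
#' Forward kinematics of the prescribed trajectories, emitting all
#' physical markers (plus, in the ground truth, wand landmarks, virtual
#' points and true frame poses), optional i.i.d. Gaussian marker noise and
#' occlusion gaps, and foot-strike/foot-off events from a contact model
#' (threshold on blade-tip / sound-heel height).
#'
#' @param rig `rsp_rig`.
#' @param trajectories Trajectory list (see [default_trajectories()]).
#' @param rate Sampling rate (Hz).
#' @param noise_sd Marker noise standard deviation (mm, default 0).
#' @param gaps List of `list(marker =, frames =)` occlusions.
#' @param seed Random seed (fixed noise); default 1.
#' @param include_static_only Emit static-only markers (default FALSE; use
#'   TRUE for the static calibration trial).
#' @param events Write contact events (default TRUE for moving trials).
#' @return List: `trial` (`rsp_trial`), `truth` (list with `frames`:
#'   per-tag list of true pose lists, `angles`: clinically signed true
#'   joint angle matrices keyed by chain joint name, `landmarks`: true
#'   global landmark trajectories, `speed`: prescribed mean speed m/s).
#' @export
simulate_trial <- function(rig, trajectories, rate = 200, noise_sd = 0,
                           gaps = list(), seed = 1L,
                           include_static_only = FALSE, events = TRUE) {
  n <- length(trajectories$forward_x)
  needed <- c("pelvis", "hip_p", "knee_p", "hip_s", "knee_s", "ankle_s")
  for (nm in needed) {
    if (nrow(trajectories[[nm]]) < n) {
      stop("trajectory ", nm, " shorter than duration")
    }
  }
  seg_names <- names(rig$markers)
  all_pts <- list()
  truth_frames <- list()
  truth_landmarks <- list()
  for (i in seq_len(n)) {
    poses <- .rig_poses(rig, .traj_at(trajectories, i),
                        trajectories$forward_x[i], trajectories$bob[i])
    for (seg in seg_names) {
      for (lab in names(rig$markers[[seg]])) {
        p <- transform_points(poses[[seg]], rig$markers[[seg]][[lab]])
        if (is.null(all_pts[[lab]])) all_pts[[lab]] <- matrix(NA_real_, n, 3L)
        all_pts[[lab]][i, ] <- p
      }
      for (lab in names(rig$landmarks[[seg]])) {
        p <- transform_points(poses[[seg]], rig$landmarks[[seg]][[lab]])
        if (is.null(truth_landmarks[[lab]])) {
          truth_landmarks[[lab]] <- matrix(NA_real_, n, 3L)
        }
        truth_landmarks[[lab]][i, ] <- p
      }
    }
    # virtual ground truth: hip joint centres
    for (lab in c(paste0(rig$S, "HJC"), paste0(rig$C, "HJC"))) {
      loc <- if (startsWith(lab, rig$S)) rig$hjc_p else rig$hjc_s
      if (is.null(truth_landmarks[[lab]])) {
        truth_landmarks[[lab]] <- matrix(NA_real_, n, 3L)
      }
      truth_landmarks[[lab]][i, ] <- transform_points(poses$pelvis, loc)
    }
    tfr <- .rig_true_frames(rig, poses)
    for (tag in names(tfr)) {
      if (is.null(truth_frames[[tag]])) truth_frames[[tag]] <- vector("list", n)
      truth_frames[[tag]][[i]] <- tfr[[tag]]
    }
  }

  # true clinically signed joint angles
  p <- rig$S; q <- tolower(rig$C)
  ang <- list()
  if (rig$level == "TF") {
    ang[[paste0(tolower(p), "htf")]] <- trajectories$hip_p
    ang[[paste0(tolower(p), "ktf")]] <-
      cbind(trajectories$knee_p[, 1L] + rig$misalignment, 0, 0)
    ang[[paste0(tolower(p), "atf")]] <-
      cbind(rig$preangle + trajectories$blade_defl, 0, 0)
  } else {
    ang[[paste0(tolower(p), "htt")]] <- trajectories$hip_p
    ang[[paste0(tolower(p), "att")]] <-
      cbind(rig$preangle + trajectories$blade_defl, 0, 0)
  }
  ang[[paste0(q, "h")]] <- trajectories$hip_s
  ang[[paste0(q, "k")]] <- trajectories$knee_s
  ang[[paste0(q, "a")]] <- trajectories$ankle_s

  if (!include_static_only) {
    all_pts <- all_pts[setdiff(names(all_pts), rig$static_only)]
  }

  ev <- empty_events()
  if (events) {
    ev <- rbind(
      .contact_events(all_pts[[paste0(rig$S, "FDA")]][, 2L], rate,
                      if (rig$side == "L") "Left" else "Right"),
      .contact_events(all_pts[[paste0(rig$C, "CAL")]][, 2L], rate,
                      if (rig$C == "L") "Left" else "Right"))
  }

  if (noise_sd > 0) {
    set.seed(seed)
    for (lab in names(all_pts)) {
      all_pts[[lab]] <- all_pts[[lab]] +
        matrix(stats::rnorm(3L * n, sd = noise_sd), n, 3L)
    }
  }
  for (g in gaps) {
    if (is.null(all_pts[[g$marker]])) stop("gap for unknown marker ",
                                           g$marker)
    all_pts[[g$marker]][g$frames, ] <- NA_real_
  }

  trial <- new_trial(all_pts, rate = rate, events = ev)
  truth <- list(frames = truth_frames, angles = ang,
                landmarks = truth_landmarks,
                speed = if (n > 1)
                  (trajectories$forward_x[n] - trajectories$forward_x[1L]) /
                    ((n - 1L) / rate) / 1000 else 0)
  list(trial = trial, truth = truth)
}

# threshold contact model: strike at downward crossings, off at upward
.contact_events <- function(height, rate, context, clearance = 5) {
  thr <- min(height) + clearance
  below <- height < thr
  n <- length(below)
  ev <- empty_events()
  for (i in seq_len(n - 1L)) {
    if (!below[i] && below[i + 1L]) {
      ev <- rbind(ev, data.frame(context = context, label = "foot_strike",
                                 time = i / rate))
    } else if (below[i] && !below[i + 1L]) {
      ev <- rbind(ev, data.frame(context = context, label = "foot_off",
                                 time = i / rate))
    }
  }
  ev
}

#' Emit wand-pointing trials for rig landmarks
#'
#' One short trial per landmark: the wand is posed (deterministically from
#' the seed) with its tip exactly on the true landmark position of the
#' neutral rig, wand markers and all rig markers are emitted, with
#' optional noise.
#'
#' @param rig `rsp_rig`.
#' @param geometry `wand_geometry`.
#' @param landmarks Landmark labels (default: all wand landmarks of the
#'   rig).
#' @param n_frames Frames per wand trial (default 20).
#' @param rate Sampling rate (Hz).
#' @param noise_sd Marker noise (mm).
#' @param seed Random seed.
#' @return Named list of `rsp_trial`, keyed by landmark label.
#' @export
emit_wand_trials <- function(rig, geometry = default_wand_geometry(),
                             landmarks = NULL, n_frames = 200L, rate = 100,
                             noise_sd = 0, seed = 1L) {
  all_lmk <- unlist(lapply(rig$landmarks, names))
  if (is.null(landmarks)) landmarks <- all_lmk
  unknown <- setdiff(landmarks, all_lmk)
  if (length(unknown)) stop("unknown landmark(s): ",
                            paste(unknown, collapse = ", "))
  if (!length(landmarks)) return(list())
  static <- simulate_trial(rig, static_trajectories(n_frames), rate = rate,
                           noise_sd = 0, seed = seed,
                           include_static_only = TRUE, events = FALSE)
  out <- list()
  set.seed(seed)
  k <- 0L
  for (lab in landmarks) {
    k <- k + 1L
    seg <- names(rig$landmarks)[vapply(rig$landmarks, function(l)
      lab %in% names(l), TRUE)][1L]
    # neutral-pose true landmark position
    poses <- .rig_poses(rig, .traj_at(static_trajectories(1L), 1L), 0, 0)
    target <- transform_points(poses[[seg]], rig$landmarks[[seg]][[lab]])
    # deterministic wand attitude per landmark
    Rw <- rot_z(0.4 * k) %*% rot_x(0.3 * k) %*% rot_y(0.2 * k)
    ow <- target - as.numeric(Rw %*% geometry$tip)
    pts <- static$trial$points
    for (wm in rownames(geometry$markers)) {
      wp <- ow + as.numeric(Rw %*% geometry$markers[wm, ])
      pts[[wm]] <- matrix(wp, n_frames, 3L, byrow = TRUE)
    }
    if (noise_sd > 0) {
      for (l2 in names(pts)) {
        pts[[l2]] <- pts[[l2]] +
          matrix(stats::rnorm(3L * n_frames, sd = noise_sd), n_frames, 3L)
      }
    }
    out[[lab]] <- new_trial(pts, rate = rate)
  }
  out
}

#' Simulate a full synthetic session
#'
#' Static calibration trial (static-only markers included), wand trials
#' for every wand landmark, and one dynamic running trial, with shared
#' noise level and seed: the inputs of the full processing pipeline.
#'
#' @param rig `rsp_rig`.
#' @param duration Dynamic trial duration (s, default 2).
#' @param rate Sampling rate (Hz, default 200).
#' @param speed Forward speed (m/s, default 6.7).
#' @param noise_sd Marker noise (mm, default 0).
#' @param seed Random seed.
#' @param ... Passed to [default_trajectories()].
#' @return List: `static`, `wand` (named list), `dynamic` (simulate_trial
#'   result), `wand_geometry`.
#' @export
simulate_session <- function(rig, duration = 2, rate = 200, speed = 6.7,
                             noise_sd = 0, seed = 1L, ...) {
  n <- as.integer(duration * rate)
  geom <- default_wand_geometry()
  static <- simulate_trial(rig, static_trajectories(as.integer(2 * rate)),
                           rate = rate, noise_sd = noise_sd,
                           seed = seed + 1L,
                           include_static_only = TRUE, events = FALSE)
  wand <- emit_wand_trials(rig, geom, noise_sd = noise_sd,
                           seed = seed + 2L)
  traj <- default_trajectories(n, rate, speed = speed, ...)
  dynamic <- simulate_trial(rig, traj, rate = rate, noise_sd = noise_sd,
                            seed = seed + 3L)
  list(static = static, wand = wand, dynamic = dynamic,
       wand_geometry = geom)
}
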