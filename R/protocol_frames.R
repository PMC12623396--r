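# Protocol coordinate systems of the prosthetic limb, one constructor per
# frame. Every frame is a right-handed orthonormal triad with x pointing
# forward, y upward (anti-parallel to gravity in the standing posture) and z
# to the subject's right. The published construction formulas are written
# for the right side; for the left side the operand order of the defining
# cross product is swapped (equivalently, the plane-normal axis is negated)
# so that the z-axis keeps pointing to the subject's right on both sides.
# Sign harmonization of the resulting joint angles is handled downstream in
# the kinematics module, not here.

.side_sign <- function(side) {
  switch(side, R = 1, L = -1, stop("side must be 'L' or 'R'"))
}

.v <- function(p) {
  p <- as.numeric(p)
  stopifnot(length(p) == 3L, all(is.finite(p)))
  p
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.frame_from_axes <- function(x, y, z, origin) {
  rigid_transform(cbind(x, y, z), origin, check = TRUE)
}

#' Socket coordinate system (SK)
#'
#' Built from the socket technical markers: origin at the midpoint of the
#' distal lateral/medial axis markers; x perpendicular to the quasi-frontal
#' plane through LAP, LAD, MAD, pointing forward; z perpendicular to the
#' quasi-sagittal plane through x and the frontal-axis line FAD-FAP; y
#' completes the right-handed triad.
#'
#' @param LAP,LAD Proximal/distal markers on the socket lateral axis (mm).
#' @param MAD Distal marker on the socket medial axis (mm).
#' @param FAP,FAD Proximal/distal markers on the socket frontal axis (mm).
#' @param side "L" or "R".
#' @return `rigid_transform` (socket pose in lab coordinates).
#' @export
socket_frame <- function(LAP, LAD, MAD, FAP, FAD, side = "R") {
  s <- .side_sign(side)
  LAP <- .v(LAP); LAD <- .v(LAD); MAD <- .v(MAD)
  FAP <- .v(FAP); FAD <- .v(FAD)
  origin <- (LAD + MAD) / 2
  x <- unit3(s * cross3(LAP - LAD, LAD - MAD), "socket frontal-plane normal")
  z <- unit3(cross3(x, FAP - FAD), "socket sagittal-plane normal")
  y <- cross3(z, x)
  .frame_from_axes(x, y, z, origin)
}

#' Socket-clamp coordinate system (SC) - transfemoral only
#'
#' Built from the four wand-calibrated screws of the socket's distal
#' 4-screw adapter: origin at their centroid; y normal to the
#' WAL-WAM-WPM plane, pointing upward; x perpendicular to y and the
#' WAM-WAL line, pointing forward; z completes the triad.
#'
#' @param WAL,WAM,WPL,WPM Anterior-lateral/-medial and posterior-lateral/
#'   -medial screw positions (mm).
#' @param side "L" or "R".
#' @return `rigid_transform`.
#' @export
socket_clamp_frame <- function(WAL, WAM, WPL, WPM, side = "R") {
  s <- .side_sign(side)
  WAL <- .v(WAL); WAM <- .v(WAM); WPL <- .v(WPL); WPM <- .v(WPM)
  origin <- (WAL + WAM + WPL + WPM) / 4
  y <- unit3(s * cross3(WAL - WPM, WAM - WPM), "socket-clamp plane normal")
  # WAL-WAM is a lateral-minus-medial line: side-adapted like the normal
  x <- unit3(cross3(y, s * (WAL - WAM)), "socket-clamp forward axis")
  z <- cross3(x, y)
  .frame_from_axes(x, y, z, origin)
}

#' Functional prosthetic-knee coordinate systems (PK and DK)
#'
#' The monocentric prosthetic knee is a pure hinge: KL and KM sit on its
#' centre of rotation and define the shared flexion axis. Both frames have
#' origin at the KL-KM midpoint and z exactly along the hinge axis
#' (pointing to the subject's right); the proximal frame (PK) takes its
#' forward axis from the socket-clamp pseudo-vertical axis, the distal
#' frame (DK) from the foot-clamp one. By construction the PK-to-DK
#' relative rotation is a pure z rotation, so abduction-adduction and
#' axial rotation of the prosthetic knee are structurally zero.
#'
#' @param KL,KM Lateral/medial knee-axis markers (mm).
#' @param y_SC Socket-clamp y-axis unit vector (lab coordinates).
#' @param y_FC Foot-clamp y-axis unit vector (lab coordinates).
#' @param side "L" or "R".
#' @return List with `rigid_transform` elements `PK` and `DK` sharing z.
#' @export
knee_frames <- function(KL, KM, y_SC, y_FC, side = "R") {
  s <- .side_sign(side)
  KL <- .v(KL); KM <- .v(KM)
  origin <- (KL + KM) / 2
  z <- unit3(s * (KL - KM), "knee hinge axis")
  x_pk <- unit3(cross3(.v(y_SC), z), "proximal knee forward axis")
  y_pk <- cross3(z, x_pk)
  x_dk <- unit3(cross3(.v(y_FC), z), "distal knee forward axis")
  y_dk <- cross3(z, x_dk)
  list(PK = .frame_from_axes(x_pk, y_pk, z, origin),
       DK = .frame_from_axes(x_dk, y_dk, z, origin))
}

#' Foot-clamp midpoints from the 4-hole adapter screws (C-shape)
#'
#' For 4-hole pyramid adapter foot-clamps the four wand-calibrated screws
#' are averaged pairwise into anterior/medial/lateral/posterior clamp
#' points: CLA = (CLAL+CLAM)/2, CLM = (CLAM+CLPM)/2, CLL = (CLAL+CLPL)/2,
#' CLP = (CLPL+CLPM)/2.
#'
#' @param CLAL,CLPL,CLAM,CLPM Screw positions (mm).
#' @return Named list with `CLA`, `CLL`, `CLM`, `CLP`.
#' @export
foot_clamp_midpoints <- function(CLAL, CLPL, CLAM, CLPM) {
  CLAL <- .v(CLAL); CLPL <- .v(CLPL); CLAM <- .v(CLAM); CLPM <- .v(CLPM)
  list(CLA = (CLAL + CLAM) / 2, CLL = (CLAL + CLPL) / 2,
       CLM = (CLAM + CLPM) / 2, CLP = (CLPL + CLPM) / 2)
}

#' Foot-clamp coordinate system, C-shaped RPF (FC)
#'
#' Origin at the centre of mass of the four clamp points; y normal to the
#' plane of the CLM-CLL and CLP-CLA lines, pointing upward; x perpendicular
#' to y and the CLM-CLL line, forward; z completes the triad. Give either
#' the four clamp points directly, or the four screws (`CLAL`, `CLPL`,
#' `CLAM`, `CLPM`), from which the clamp points are derived with
#' [foot_clamp_midpoints()].
#'
#' @param CLA,CLL,CLM,CLP Clamp anterior/lateral/medial/posterior points
#'   (mm), or NULL if screws are given.
#' @param CLAL,CLPL,CLAM,CLPM Screw positions (mm), or NULL.
#' @param side "L" or "R".
#' @return `rigid_transform`.
#' @export
foot_clamp_frame_C <- function(CLA = NULL, CLL = NULL, CLM = NULL,
                               CLP = NULL, CLAL = NULL, CLPL = NULL,
                               CLAM = NULL, CLPM = NULL, side = "R") {
  if (is.null(CLA)) {
    mp <- foot_clamp_midpoints(CLAL, CLPL, CLAM, CLPM)
    CLA <- mp$CLA; CLL <- mp$CLL; CLM <- mp$CLM; CLP <- mp$CLP
  }
  s <- .side_sign(side)
  CLA <- .v(CLA); CLL <- .v(CLL); CLM <- .v(CLM); CLP <- .v(CLP)
  origin <- (CLA + CLL + CLM + CLP) / 4
  y <- unit3(s * cross3(CLL - CLM, CLA - CLP), "foot-clamp plane normal")
  # CLL-CLM is a lateral-minus-medial line: side-adapted like the normal
  x <- unit3(cross3(y, s * (CLL - CLM)), "foot-clamp forward axis")
  z <- cross3(x, y)
  .frame_from_axes(x, y, z, origin)
}

#' Foot-clamp coordinate system, J-shaped RPF (FC)
#'
#' For transtibial prostheses the J-shaped blade bolts to the socket
#' posterior box and four markers on its proximal part define the clamp:
#' origin at their centroid; x normal to the marker plane, forward; z
#' perpendicular to x and the line joining the distal-pair midpoint to the
#' proximal-pair midpoint, pointing rightward; y completes the triad.
#'
#' @param CLPL,CLDL Proximal/distal lateral clamp markers (mm).
#' @param CLPM,CLDM Proximal/distal medial clamp markers (mm).
#' @param side "L" or "R".
#' @return `rigid_transform`.
#' @export
foot_clamp_frame_J <- function(CLPL, CLDL, CLPM, CLDM, side = "R") {
  s <- .side_sign(side)
  CLPL <- .v(CLPL); CLDL <- .v(CLDL); CLPM <- .v(CLPM); CLDM <- .v(CLDM)
  origin <- (CLPL + CLDL + CLPM + CLDM) / 4
  x <- unit3(s * cross3(CLPM - CLDL, CLPL - CLDM), "foot-clamp plane normal")
  p1 <- (CLPL + CLPM) / 2
  p2 <- (CLDL + CLDM) / 2
  z <- unit3(cross3(x, p1 - p2), "foot-clamp lateral axis")
  y <- cross3(z, x)
  .frame_from_axes(x, y, z, origin)
}

#' Distal running-prosthetic-foot coordinate system (FD)
#'
#' The distal tip portion of the blade: origin at the tip marker FDA; x
#' along the line from the FDM-FDL midpoint to FDA ("forward" along the
#' blade tangent); y normal to the FDA-FDM-FDL plane; z completes the
#' triad.
#'
#' @param FDA Blade tip marker (mm).
#' @param FDM,FDL Medial/lateral markers 50 mm proximal to the tip (mm).
#' @param side "L" or "R".
#' @return `rigid_transform`.
#' @export
distal_rpf_frame <- function(FDA, FDM, FDL, side = "R") {
  s <- .side_sign(side)
  FDA <- .v(FDA); FDM <- .v(FDM); FDL <- .v(FDL)
  o1 <- (FDM + FDL) / 2
  x <- unit3(FDA - o1, "distal RPF long axis")
  y <- unit3(s * cross3(x, FDM - FDL), "distal RPF plane normal")
  z <- cross3(x, y)
  .frame_from_axes(x, y, z, FDA)
}

#' Technical proximal-RPF coordinate system (FP)
#'
#' Built on the T-shaped technical cluster attached laterally to the blade,
#' posterior to the foot-clamp: origin at the FP1-FP2 midpoint; x along
#' FP2-to-FP1, forward; z normal to the FP1-FP2-FP3 plane (FP3 sits
#' perpendicularly below the FP1-FP2 line); y completes the triad. Not used
#' for joint kinematics, but it tracks the blade across alignment changes
#' and backs up occluded foot-clamp markers.
#'
#' @param FP1,FP2,FP3 Cluster markers (mm).
#' @return `rigid_transform`.
#' @export
technical_fp_frame <- function(FP1, FP2, FP3) {
  FP1 <- .v(FP1); FP2 <- .v(FP2); FP3 <- .v(FP3)
  origin <- (FP1 + FP2) / 2
  x <- unit3(FP1 - FP2, "technical RPF long axis")
  z <- unit3(cross3(x, origin - FP3), "technical RPF plane normal")
  y <- cross3(z, x)
  .frame_from_axes(x, y, z, origin)
}

#' Equivalent-leg coordinate systems (HJC-K and GT-KL)
#'
#' Two auxiliary systems modelling the thigh-plus-prosthesis as one
#' equivalent segment. HJC-K (3D): origin at the knee centre (KL-KM
#' midpoint), y toward the hip joint centre, x normal to the plane of y and
#' the hinge axis, z completes the triad. GT-KL (2D, for comparison with
#' sagittal video): origin at KL, y the projection of the KL-to-GT
#' direction onto the lab sagittal plane, z fixed to the lab lateral axis
#' (0,0,1), x completes the triad. GT-KL is lab-referenced by construction.
#'
#' @param HJC Hip joint centre (mm).
#' @param GT Greater trochanter marker (mm).
#' @param KL,KM Lateral/medial knee-axis markers (mm).
#' @param side "L" or "R".
#' @return List with `rigid_transform` elements `HJC_K` and `GT_KL`.
#' @export
equivalent_leg_frames <- function(HJC, GT, KL, KM, side = "R") {
  s <- .side_sign(side)
  HJC <- .v(HJC); GT <- .v(GT); KL <- .v(KL); KM <- .v(KM)
  o_hk <- (KM + KL) / 2
  y_hk <- unit3(HJC - o_hk, "HJC-to-knee axis")
  x_hk <- unit3(s * cross3(y_hk, KL - KM), "HJC-K forward axis")
  z_hk <- cross3(x_hk, y_hk)
  hjc_k <- .frame_from_axes(x_hk, y_hk, z_hk, o_hk)

  y_tmp <- unit3(GT - KL, "GT-to-KL axis")
  y_sag <- c(y_tmp[1L], y_tmp[2L], 0)
  y_gk <- unit3(y_sag, "GT-KL sagittal projection")
  z_gk <- c(0, 0, 1)
  x_gk <- unit3(cross3(y_gk, z_gk), "GT-KL forward axis")
  gt_kl <- .frame_from_axes(x_gk, y_gk, z_gk, KL)
  list(HJC_K = hjc_k, GT_KL = gt_kl)
}

## ---------------------------------------------------------------------------
## Sound-side segment frames (ISB-default recipes; the protocol delegates
## sound-side definitions to the ISB recommendations).

#' Pelvis coordinate system (ISB-default)
#'
#' Origin at the mid-ASIS point; z along the ASIS line to the right; x
#' forward, perpendicular to z in the plane through the ASIS markers and
#' the mid-PSIS point; y upward.
#'
#' @param RASI,LASI Right/left anterior superior iliac spine (mm).
#' @param RPSI,LPSI Right/left posterior superior iliac spine (mm).
#' @return `rigid_transform`.
#' @export
pelvis_frame <- function(RASI, LASI, RPSI, LPSI) {
  RASI <- .v(RASI); LASI <- .v(LASI); RPSI <- .v(RPSI); LPSI <- .v(LPSI)
  origin <- (RASI + LASI) / 2
  mid_psis <- (RPSI + LPSI) / 2
  z <- unit3(RASI - LASI, "pelvis lateral axis")
  y <- unit3(cross3(z, origin - mid_psis), "pelvis vertical axis")
  x <- cross3(y, z)
  .frame_from_axes(x, y, z, origin)
}

#' Sound-side thigh coordinate system (ISB-default)
#'
#' Origin at the mid-epicondyle point; y toward the hip joint centre; x
#' normal to the plane of y and the epicondyle line, forward; z completes.
#'
#' @param HJC Hip joint centre (mm).
#' @param LEP,MEP Lateral/medial femoral epicondyle markers (mm).
#' @param side "L" or "R".
#' @return `rigid_transform`.
#' @export
thigh_frame <- function(HJC, LEP, MEP, side = "R") {
  s <- .side_sign(side)
  HJC <- .v(HJC); LEP <- .v(LEP); MEP <- .v(MEP)
  origin <- (LEP + MEP) / 2
  y <- unit3(HJC - origin, "thigh long axis")
  x <- unit3(s * cross3(y, LEP - MEP), "thigh forward axis")
  z <- cross3(x, y)
  .frame_from_axes(x, y, z, origin)
}

#' Sound-side shank coordinate system (ISB-default)
#'
#' Origin at the mid-malleolus point; y toward the knee centre
#' (mid-epicondyle); x normal to the plane of y and the malleolus line;
#' z completes.
#'
#' @param KJC Knee centre (mid-epicondyle point, mm).
#' @param LML,MML Lateral/medial malleolus markers (mm).
#' @param side "L" or "R".
#' @return `rigid_transform`.
#' @export
shank_frame <- function(KJC, LML, MML, side = "R") {
  s <- .side_sign(side)
  KJC <- .v(KJC); LML <- .v(LML); MML <- .v(MML)
  origin <- (LML + MML) / 2
  y <- unit3(KJC - origin, "shank long axis")
  x <- unit3(s * cross3(y, LML - MML), "shank forward axis")
  z <- cross3(x, y)
  .frame_from_axes(x, y, z, origin)
}

#' Sound-side foot coordinate system (ISB-default)
#'
#' Origin at the heel marker; x toward the mid-forefoot point (forward
#' along the foot long axis); y normal to the plane of x and the
#' metatarsal line, upward; z completes.
#'
#' @param CAL Calcaneus (heel) marker (mm).
#' @param MT1,MT5 First/fifth metatarsal-head markers (mm).
#' @param side "L" or "R".
#' @return `rigid_transform`.
#' @export
foot_frame <- function(CAL, MT1, MT5, side = "R") {
  s <- .side_sign(side)
  CAL <- .v(CAL); MT1 <- .v(MT1); MT5 <- .v(MT5)
  fore <- (MT1 + MT5) / 2
  x <- unit3(fore - CAL, "foot long axis")
  y <- unit3(s * cross3(MT5 - MT1, x), "foot vertical axis")
  z <- cross3(x, y)
  .frame_from_axes(x, y, z, CAL)
}
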