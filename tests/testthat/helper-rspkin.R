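# shared test utilities: random rigid transforms and scene helpers

random_rigid <- function() {
  R <- random_rotations(1L)[[1L]]
  rigid_transform(R, stats::runif(3, -500, 500), check = FALSE)
}

# apply a rigid transform to every 3-vector argument of a frame op
apply_rigid_pts <- function(G, pts) lapply(pts, function(p) transform_points(G, p))

# orientation + origin discrepancy between two transforms
tf_error <- function(a, b) {
  max(max(abs(a$R - b$R)), max(abs(a$origin - b$origin)))
}

# independent rigid-fit oracle: Horn's closed-form absolute orientation
# (unit quaternion from the eigendecomposition of the 4x4 cross-covariance
# form), algebraically unrelated to the SVD route it checks
horn_fit <- function(ref, cur) {
  mu_r <- colMeans(ref); mu_c <- colMeans(cur)
  A <- sweep(ref, 2, mu_r); B <- sweep(cur, 2, mu_c)
  M <- crossprod(A, B)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  N <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,     -Sxx-Syy+Szz), 4, 4)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y+w*z), 2*(x*z-w*y),
    2*(x*y-w*z), 1-2*(x^2+z^2), 2*(y*z+w*x),
    2*(x*z+w*y), 2*(y*z-w*x), 1-2*(x^2+y^2)), 3, 3)
  origin <- mu_c - as.numeric(R %*% mu_r)
  resid <- cur - (ref %*% t(R) + matrix(origin, nrow(ref), 3, byrow = TRUE))
  list(transform = rigid_transform(R, origin, check = FALSE),
       rms = sqrt(mean(rowSums(resid^2))))
}

# neutral right-side frame-op inputs used by equivariance tests
neutral_frame_inputs <- function() {
  list(
    socket = list(LAP = c(0,300,50), LAD = c(0,0,50), MAD = c(0,0,-50),
                  FAP = c(50,300,0), FAD = c(50,0,0)),
    socket_clamp = list(WAL = c(30,0,30), WAM = c(30,0,-30),
                        WPL = c(-30,0,30), WPM = c(-30,0,-30)),
    foot_clamp_C = list(CLA = c(40,0,0), CLL = c(0,0,40),
                        CLM = c(0,0,-40), CLP = c(-40,0,0)),
    foot_clamp_J = list(CLPL = c(0,100,30), CLDL = c(0,0,30),
                        CLPM = c(0,100,-30), CLDM = c(0,0,-30)),
    distal_rpf = list(FDA = c(100,0,0), FDM = c(50,0,-30),
                      FDL = c(50,0,30)),
    technical_fp = list(FP1 = c(50,0,0), FP2 = c(-50,0,0),
                        FP3 = c(0,-40,0)),
    pelvis = list(RASI = c(0,0,120), LASI = c(0,0,-120),
                  RPSI = c(-150,0,50), LPSI = c(-150,0,-50))
  )
}

make_small_session <- function(level = "TF", side = "L", noise_sd = 0,
                               seed = 1, duration = 1, rate = 100,
                               speed = 6.7) {
  rig <- build_rig(level, side)
  ses <- simulate_session(rig, duration = duration, rate = rate,
                          speed = speed, noise_sd = noise_sd, seed = seed)
  cfg <- configure_session(level, "TST", "2026-01-15", side = side)
  list(rig = rig, ses = ses, cfg = cfg)
}
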