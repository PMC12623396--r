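# Trajectory smoothing. In the acquisition workflow marker trajectories
# are reconstructed, labelled, gap-filled and low-pass smoothed inside the
# optoelectronic system's software before entering this pipeline; this
# utility reproduces that upstream step for synthetic (or raw) data so
# that noisy inputs match what the pipeline is designed to receive. The
# pipeline itself applies no temporal smoothing.

#' Low-pass smooth marker trajectories
#'
#' Zero-lag 4th-order Butterworth low-pass filter (applied forward and
#' backward) on each coordinate of each marker, run separately over each
#' contiguous run of valid samples; invalid samples stay invalid, runs
#' shorter than the filter warm-up are left untouched.
#'
#' @param trial `rsp_trial`.
#' @param cutoff Cutoff frequency (Hz, default 10: above the harmonic
#'   content of sprinting kinematics at protocol sampling rates).
#' @return Smoothed `rsp_trial`.
#' @export
smooth_trial <- function(trial, cutoff = 10) {
  wn <- cutoff / (trial$rate / 2)
  if (wn >= 1) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(4, wn, type = "low")
  pad <- 20L # reflection padding against filtfilt edge transients
  pts <- lapply(trial$points, function(p) {
    ok <- stats::complete.cases(p)
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values & runs$lengths > 3L * pad)) {
      idx <- starts[r]:ends[r]
      for (k in 1:3) {
        v <- p[idx, k]
        n <- length(v)
        padded <- c(2 * v[1L] - rev(v[2L:(pad + 1L)]), v,
                    2 * v[n] - rev(v[(n - pad):(n - 1L)]))
        sm <- signal::filtfilt(bf, padded)
        p[idx, k] <- sm[(pad + 1L):(pad + n)]
      }
    }
    p
  })
  out <- new_trial(pts, rate = trial$rate, events = trial$events,
                   first_frame = trial$first_frame)
  attr(out, "residuals") <- attr(trial, "residuals")
  out
}
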