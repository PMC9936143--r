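# Stimulus synthesis and head-tracked dynamic binaural rendering.
#
# Rendering is block-based: the stimulus is cut into 50%-overlapping
# raised-cosine frames (constant overlap-add, so a static head reproduces
# plain convolution exactly), each frame is convolved with the HRTF for the
# head-relative source direction at that frame's time (minus the tracking
# latency), and the output is gated off with a short ramp once the head has
# rotated past the gating threshold about the instructed axis.

#' Band-limited white-noise burst
#'
#' Seeded white noise, brick-wall band-limited, peak-normalised, and gated
#' on/off with raised-cosine ramps.
#'
#' @param fs sampling rate in Hz.
#' @param duration_ms burst duration.
#' @param band_hz two-element band in Hz; intersected with `[0, fs/2]`.
#' @param ramp_ms raised-cosine ramp length at both ends.
#' @param seed integer seed.
#' @param peak peak amplitude after normalisation.
#' @return an object of class `stimulus`: list with `fs`, `samples`,
#'   `band_hz`, `ramp_ms`.
#' @export
make_noise_burst <- function(fs, duration_ms = 2000, band_hz = c(20, 20000),
                             ramp_ms = 5, seed = 1, peak = 0.95) {
  if (length(band_hz) != 2 || band_hz[1] < 0 || band_hz[2] <= band_hz[1])
    stop("invalid band")
  if (duration_ms < 2 * ramp_ms) stop("duration shorter than the two ramps")
  if (fs <= 2 * band_hz[1]) stop("sampling rate too low for the band")
  n <- round(fs * duration_ms / 1000)
  set.seed(seed)
  x <- stats::rnorm(n)
  f <- hrtf_freqs(n, fs)
  folded <- pmin(f, fs - f)
  keep <- folded >= band_hz[1] & folded <= min(band_hz[2], fs / 2)
  X <- stats::fft(x)
  X[!keep] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x <- x / max(abs(x)) * peak
  nr <- round(fs * ramp_ms / 1000)
  ramp <- 0.5 * (1 - cos(pi * (0:(nr - 1)) / nr))
  x[1:nr] <- x[1:nr] * ramp
  x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(ramp)
  structure(list(fs = fs, samples = x, band_hz = band_hz, ramp_ms = ramp_ms),
            class = "stimulus")
}

#' Construct a head trajectory
#'
#' @param t time in seconds, strictly increasing, starting at 0.
#' @param orientation a `head_orientation` with one row per time point.
#' @param latency_s rendering latency applied when the renderer looks up the
#'   orientation (head tracking latency).
#' @return an object of class `head_trajectory`.
#' @export
head_trajectory <- function(t, orientation, latency_s = 0) {
  stopifnot(length(t) == nrow(orientation), latency_s >= 0)
  if (any(diff(t) <= 0)) stop("trajectory times must be strictly increasing")
  structure(list(t = t, orientation = orientation, latency_s = latency_s),
            class = "head_trajectory")
}

# linearly interpolated orientation at times tt (clamped to the trajectory)
trajectory_orientation <- function(traj, tt) {
  tt <- pmin(max(traj$t), pmax(min(traj$t), tt))
  head_orientation(
    stats::approx(traj$t, traj$orientation$yaw_deg, tt)$y,
    stats::approx(traj$t, traj$orientation$pitch_deg, tt)$y,
    stats::approx(traj$t, traj$orientation$roll_deg, tt)$y)
}

#' Gate-off time from head rotation
#'
#' First time at which the unsigned rotation about the instructed axis,
#' measured from the trial-start orientation, reaches the threshold
#' (linear interpolation between tracker samples; a sample landing exactly
#' on the threshold counts as the crossing). Returns `t_end` if the
#' threshold is never reached (the stimulus then runs to its own end).
#'
#' @param traj a `head_trajectory`.
#' @param axis `"yaw"` or `"pitch"`.
#' @param threshold_deg gating threshold in degrees.
#' @param t_end time returned when the rotation never reaches threshold.
#' @return gate-off time in seconds.
#' @export
gate_at_rotation <- function(traj, axis = c("yaw", "pitch"),
                             threshold_deg = 10, t_end = max(traj$t)) {
  axis <- match.arg(axis)
  ang <- if (axis == "yaw") traj$orientation$yaw_deg
         else traj$orientation$pitch_deg
  rot <- abs(ang - ang[1])
  hit <- which(rot >= threshold_deg)
  if (length(hit) == 0) return(t_end)
  i <- hit[1]
  if (rot[i] == threshold_deg || i == 1) return(traj$t[i])
  frac <- (threshold_deg - rot[i - 1]) / (rot[i] - rot[i - 1])
  traj$t[i - 1] + frac * (traj$t[i] - traj$t[i - 1])
}

# single-channel FFT convolution
conv_fft <- function(x, h) {
  n <- length(x) + length(h) - 1
  nf <- stats::nextn(n, 2)
  Re(stats::fft(stats::fft(c(x, numeric(nf - length(x)))) *
                stats::fft(c(h, numeric(nf - length(h)))),
                inverse = TRUE))[1:n] / nf
}

#' Head-tracked dynamic binaural rendering
#'
#' Renders a stimulus from a world-fixed source direction through a dense
#' HRTF set while the head follows a trajectory. Overlap-add block
#' convolution with raised-cosine crossfades; per block the head-relative
#' source direction (with tracking latency applied) selects the
#' nearest-neighbour dense-grid HRTF. The `flat` condition flattens the set
#' first; the `frozen` condition freezes it to the head-relative source
#' direction at stimulus onset, so spectral cues stop following the head
#' while ITD cues continue to. With a gating axis, the output is ramped to
#' silence once the head has rotated 10 degrees (see [gate_at_rotation()]);
#' after the ramp the output is exactly zero.
#'
#' @param stim a [make_noise_burst()] stimulus; its `fs` must equal the
#'   set's.
#' @param source a single world-fixed `dir_sph` direction.
#' @param traj a `head_trajectory`.
#' @param set a dense `hrtf_set` (>= 42 directions).
#' @param condition `"full"`, `"flat"`, or `"frozen"`.
#' @param gate_axis `NULL` (no gating) or `"yaw"`/`"pitch"`.
#' @param gate_threshold_deg,gate_ramp_ms gating parameters.
#' @param block_ms block hop length in milliseconds.
#' @return a numeric matrix `[n_samples, 2]` (left, right) with attribute
#'   `fs`.
#' @export
render_dynamic <- function(stim, source, traj, set,
                           condition = c("full", "flat", "frozen"),
                           gate_axis = NULL, gate_threshold_deg = 10,
                           gate_ramp_ms = 5, block_ms = 5) {
  condition <- match.arg(condition)
  if (stim$fs != set$fs) stop("stimulus and HRTF sampling rates differ")
  if (nrow(set$directions) < 42)
    stop("dense HRTF set required (got ", nrow(set$directions),
         " directions); interpolate_to_dense() first")
  if (condition == "flat") set <- flatten_spectrum(set)
  if (condition == "frozen") {
    onset <- head_relative_direction(source, trajectory_orientation(traj, 0))
    set <- freeze_spectrum(set, onset, interpolate = TRUE)
  }
  x <- stim$samples
  L <- length(x)
  nir <- dim(set$ir)[1]
  h <- max(8L, round(set$fs * block_ms / 1000))
  w <- sin(pi * (0:(2 * h - 1) + 0.5) / (2 * h))^2  # COLA at hop h
  V <- sph_to_cart(set$directions)
  offsets <- seq(-h, L - 1, by = h)
  y <- matrix(0, L + nir - 1 + h, 2)
  for (o in offsets) {
    idx <- (o + 1):(o + 2 * h)
    valid <- idx >= 1 & idx <= L
    if (!any(valid)) next
    frame <- numeric(2 * h)
    frame[valid] <- x[idx[valid]]
    frame <- frame * w
    tc <- (o + h) / set$fs - traj$latency_s
    hr <- head_relative_direction(source, trajectory_orientation(traj, tc))
    j <- which.max(V %*% drop(sph_to_cart(hr)[1, ]))
    for (ear in 1:2) {
      seg <- conv_fft(frame, set$ir[, j, ear])
      lo <- o + 1
      keep <- which(lo:(lo + length(seg) - 1) >= 1)
      y[(lo:(lo + length(seg) - 1))[keep], ear] <-
        y[(lo:(lo + length(seg) - 1))[keep], ear] + seg[keep]
    }
  }
  y <- y[1:(L + nir - 1), , drop = FALSE]
  if (!is.null(gate_axis)) {
    gt <- gate_at_rotation(traj, gate_axis, gate_threshold_deg,
                           t_end = L / set$fs)
    env <- rep(1, nrow(y))
    i0 <- floor(gt * set$fs) + 1
    nr <- round(set$fs * gate_ramp_ms / 1000)
    if (i0 <= nrow(y)) {
      ramp_idx <- i0:min(nrow(y), i0 + nr - 1)
      env[ramp_idx] <- 0.5 * (1 + cos(pi * (seq_along(ramp_idx) - 1) / nr))
      if (i0 + nr <= nrow(y)) env[(i0 + nr):nrow(y)] <- 0
    }
    y <- y * env
  }
  attr(y, "fs") <- set$fs
  y
}
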