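# HRTF container and signal primitives: minimum-phase reconstruction,
# time-of-arrival (TOA) estimation, the spherical-head TOA model, and
# exact band-limited fractional delay.

EARS <- c("left", "right")

#' Construct an HRTF set
#'
#' Per-direction, per-ear head-related impulse responses with sampling rate
#' and (optionally) per-ear times of arrival.
#'
#' @param directions a `dir_sph` object, one row per direction (unique).
#' @param fs sampling rate in Hz.
#' @param ir numeric array `[n_samples, n_directions, 2]`; ear 1 = left,
#'   ear 2 = right.
#' @param toa optional matrix `[n_directions, 2]` of per-ear TOA in seconds.
#' @return an object of class `hrtf_set`.
#' @export
hrtf_set <- function(directions, fs, ir, toa = NULL) {
  stopifnot(fs > 0, length(dim(ir)) == 3, dim(ir)[3] == 2)
  if (dim(ir)[2] != nrow(directions))
    stop("ir has ", dim(ir)[2], " directions but ", nrow(directions),
         " direction rows given")
  if (any(!is.finite(ir))) stop("impulse responses must be finite")
  v <- sph_to_cart(directions)
  if (nrow(v) > 1) {
    dots <- tcrossprod(v); diag(dots) <- -1
    if (any(dots > 1 - 1e-12)) stop("duplicate directions in HRTF set")
  }
  if (!is.null(toa)) {
    toa <- matrix(toa, nrow(directions), 2)
    if (any(toa < 0)) stop("TOA must be nonnegative")
    if (any(abs(toa[, 1] - toa[, 2]) > 1.1e-3))
      warning("|ITD| exceeds 1.1 ms; implausible for human head sizes")
  }
  structure(list(directions = directions, fs = fs, ir = ir, toa = toa),
            class = "hrtf_set")
}

#' @export
print.hrtf_set <- function(x, ...) {
  cat("hrtf_set:", nrow(x$directions), "directions,",
      dim(x$ir)[1], "samples @", x$fs, "Hz,",
      if (is.null(x$toa)) "TOA not set\n" else "TOA set\n")
  invisible(x)
}

# cepstral folding weights for a length-N real cepstrum
cepstrum_fold <- function(n) {
  w <- numeric(n)
  w[1] <- 1
  if (n %% 2 == 0) {
    w[2:(n / 2)] <- 2
    w[n / 2 + 1] <- 1
  } else {
    w[2:((n + 1) / 2)] <- 2
  }
  w
}

# minimum-phase signals from full (length-N, Hermitian-consistent) linear
# magnitude spectra; columns are channels
min_phase_from_full_mag <- function(mag) {
  mag <- as.matrix(mag)
  n <- nrow(mag)
  peak <- apply(mag, 2, max)
  if (any(peak <= 0)) stop("degenerate (all-zero) magnitude spectrum")
  mag <- pmax(mag, rep(peak, each = n) * 1e-12)  # floor guards log of ~0 bins
  cep <- Re(stats::mvfft(log(mag), inverse = TRUE)) / n
  cep <- cep * cepstrum_fold(n)
  h <- exp(stats::mvfft(cep))
  Re(stats::mvfft(h, inverse = TRUE)) / n
}

# exact minimum phase of one FIR: reflect the z-plane zeros lying outside
# the unit circle (computed as roots of the coefficient polynomial), expand
# back to coefficients, then impose the input's exact FFT magnitude on the
# resulting phase. Pure-delay factors (leading zero samples) are dropped.
min_phase_roots <- function(h) {
  n <- length(h)
  nz <- which(h != 0)
  hh <- h[nz[1]:nz[length(nz)]]
  if (length(hh) == 1) return(c(abs(hh), numeric(n - 1)))
  r <- polyroot(hh)
  gain <- hh[length(hh)]
  inside <- Mod(r) < 1         # roots of P(1/z): inside <=> non-min-phase
  scale <- prod(Mod(r[inside]))
  r[inside] <- 1 / Conj(r[inside])
  p <- complex(real = 1)
  for (ri in r) p <- c(0, p) - c(ri * p, 0)
  p <- Re(p * gain * scale)
  p <- c(p, numeric(n - length(p)))
  H <- exp(1i * Arg(stats::fft(p))) * Mod(stats::fft(h))
  Re(stats::fft(H, inverse = TRUE)) / n
}

#' Minimum-phase version of impulse responses
#'
#' Returns the impulse response with the same magnitude spectrum but minimum
#' group delay. The default method reflects the non-minimum-phase zeros of
#' each FIR across the unit circle and re-imposes the exact input magnitude,
#' so the magnitude is preserved to machine precision and the
#' cumulative-energy curve of the result dominates that of the input at
#' every sample (minimum energy delay). The `"cepstrum"` method is the
#' faster folded-real-cepstrum approximation (magnitude equally exact;
#' energy-delay dominance only approximate when the spectrum has deep
#' dips).
#'
#' @param ir numeric vector, or matrix with one signal per column.
#' @param method `"exact"` (zero reflection) or `"cepstrum"`.
#' @return same shape as `ir`.
#' @examples
#' minimum_phase(c(0, 0, 1))  # pure delay removed -> impulse at sample 1
#' @export
minimum_phase <- function(ir, method = c("exact", "cepstrum")) {
  method <- match.arg(method)
  vec <- is.null(dim(ir))
  x <- as.matrix(ir)
  if (any(colSums(abs(x)) == 0)) stop("degenerate (all-zero) impulse response")
  out <- if (method == "cepstrum") {
    min_phase_from_full_mag(Mod(stats::mvfft(x)))
  } else {
    apply(x, 2, min_phase_roots)
  }
  if (vec) drop(out) else out
}

# exact linear-phase (band-limited, circular) fractional delay;
# columns of x delayed by d[i] samples
frac_delay <- function(x, d) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- rep_len(d, ncol(x))
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)  # signed bin frequencies
  X <- stats::mvfft(x)
  for (j in seq_len(ncol(x))) {
    ph <- exp(-2i * pi * k * d[j] / n)
    if (n %% 2 == 0) ph[n / 2 + 1] <- cos(pi * d[j])  # keep output real
    X[, j] <- X[, j] * ph
  }
  Re(stats::mvfft(X, inverse = TRUE)) / n
}

#' Estimate per-ear times of arrival
#'
#' The TOA of each impulse response is the lag maximising its
#' cross-correlation with its own minimum-phase version (the minimum-phase
#' version is the zero-delay reference with identical magnitude). A
#' parabolic refinement around the peak gives sub-sample resolution.
#'
#' @param set an `hrtf_set`.
#' @return the set with `$toa` filled (seconds, >= 0).
#' @export
estimate_toa <- function(set) {
  n <- dim(set$ir)[1]
  nd <- dim(set$ir)[2]
  toa <- matrix(0, nd, 2)
  for (ear in 1:2) {
    x <- set$ir[, , ear, drop = TRUE]
    x <- matrix(x, nrow = n)
    if (any(colSums(abs(x)) == 0)) stop("degenerate impulse response")
    mp <- minimum_phase(x, method = "cepstrum")  # zero-delay reference
    # circular cross-correlation via FFT; lag 0..n-1
    r <- Re(stats::mvfft(stats::mvfft(x) * Conj(stats::mvfft(mp)),
                         inverse = TRUE)) / n
    for (j in seq_len(nd)) {
      pk <- which.max(r[, j])
      lag <- pk - 1
      # parabolic peak interpolation (guard the circular edges)
      if (pk > 1 && pk < n) {
        y0 <- r[pk - 1, j]; y1 <- r[pk, j]; y2 <- r[pk + 1, j]
        den <- y0 - 2 * y1 + y2
        if (abs(den) > .Machine$double.eps * abs(y1))
          lag <- lag + 0.5 * (y0 - y2) / den
      }
      toa[j, ear] <- max(0, lag) / set$fs
    }
  }
  set$toa <- toa
  set
}

#' Spherical-head TOA model
#'
#' Single-ear time-of-arrival on a rigid spherical head: with `gamma` the
#' angle between the source direction and the ear axis,
#' `tau = (r/c) (1 - cos gamma)` on the ipsilateral side
#' (`gamma <= 90` deg) and `tau = (r/c) (1 + gamma_rad - pi/2)` in the
#' shadow zone, continuous at 90 deg and zero at the ear axis.
#'
#' @param radius_m head radius in metres.
#' @param speed_of_sound in m/s.
#' @param ear_azimuth_deg azimuth of the left ear (right ear mirrored).
#' @return an object of class `spherical_head_model`.
#' @export
spherical_head_model <- function(radius_m = 0.0875, speed_of_sound = 343,
                                 ear_azimuth_deg = 90) {
  stopifnot(radius_m > 0, speed_of_sound > 0)
  structure(list(radius_m = radius_m, speed_of_sound = speed_of_sound,
                 ear_azimuth_deg = ear_azimuth_deg),
            class = "spherical_head_model")
}

#' Modelled TOA for directions and an ear
#'
#' @param model a [spherical_head_model()].
#' @param d a `dir_sph` object (vectorised).
#' @param ear `"left"` or `"right"`.
#' @return TOA in seconds, one per direction.
#' @examples
#' m <- spherical_head_model()
#' model_toa(m, dir_sph(90, 0), "left")   # source at the left ear: 0
#' @export
model_toa <- function(model, d, ear = c("left", "right")) {
  ear <- match.arg(ear)
  ear_dir <- dir_sph(if (ear == "left") model$ear_azimuth_deg
                     else -model$ear_azimuth_deg, 0)
  gamma <- deg2rad(angular_distance(d, ear_dir))
  rc <- model$radius_m / model$speed_of_sound
  ifelse(gamma <= pi / 2, rc * (1 - cos(gamma)), rc * (1 + gamma - pi / 2))
}

#' Interaural time differences of an HRTF set
#'
#' @param set an `hrtf_set` with TOA present (use [estimate_toa()] first
#'   otherwise).
#' @return ITD in seconds per direction, positive when the sound reaches the
#'   left ear first (source on the left).
#' @export
itd <- function(set) {
  if (is.null(set$toa)) stop("TOA not set; call estimate_toa() first")
  set$toa[, 2] - set$toa[, 1]
}

# linear magnitude spectra of a set: array [n_bins(full N), n_dir, 2]
hrtf_magnitude <- function(set) {
  n <- dim(set$ir)[1]
  out <- array(0, dim(set$ir))
  for (ear in 1:2)
    out[, , ear] <- Mod(stats::mvfft(matrix(set$ir[, , ear], nrow = n)))
  out
}

# FFT bin frequencies (full spectrum) in Hz for a set
hrtf_freqs <- function(n, fs) (0:(n - 1)) * fs / n
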