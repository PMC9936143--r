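# The HRTF processing chain for the cue conditions:
#   dense-grid interpolation (minimum phase + VBAP spectral blending +
#   spherical-head TOA), spectral flattening (removes monaural spectral
#   shape, keeps ITD/ILD), and frozen-spectrum synthesis (keeps per-direction
#   ITD, freezes magnitude -- hence MSS and ILD -- to one reference
#   direction).

#' Dense direction grid by mesh subdivision
#'
#' Triangulates a sparse direction set and subdivides it, returning the
#' dense vertex directions (the rendering grid).
#'
#' @param directions sparse `dir_sph` directions (>= 4, non-coplanar).
#' @param iterations subdivision passes (default 3).
#' @return a `dir_sph` object of dense directions.
#' @export
dense_grid <- function(directions, iterations = 3) {
  mesh_directions(subdivide(triangulate(directions), iterations))
}

#' Interpolate a sparse HRTF set to a dense grid
#'
#' Per dense direction and ear: the log-magnitude spectrum is the
#' VBAP-gain-weighted blend of the sparse (minimum-phase) log-magnitudes
#' over the containing mesh face; the phase is the minimum phase of the
#' blended magnitude; the TOA is re-introduced from the spherical-head
#' model as an exact band-limited fractional delay. A dense direction that
#' coincides with a sparse one reproduces its magnitude exactly.
#'
#' @param sparse an `hrtf_set` (>= 4 directions).
#' @param dense_directions a `dir_sph` object of target directions
#'   (default: 3 subdivision passes over the sparse grid).
#' @param model a [spherical_head_model()] supplying the dense TOA.
#' @return an `hrtf_set` on the dense grid with model TOA filled in.
#' @export
interpolate_to_dense <- function(sparse,
                                 dense_directions = dense_grid(sparse$directions),
                                 model = spherical_head_model()) {
  n <- dim(sparse$ir)[1]
  mesh <- triangulate(sparse$directions)
  solvers <- vbap_face_solvers(mesh)
  logmag <- hrtf_magnitude(sparse)
  peak <- max(logmag)
  logmag <- 20 * log10(pmax(logmag, peak * 1e-12))
  nd <- nrow(dense_directions)
  ir <- array(0, c(n, nd, 2))
  dense_mag <- array(0, c(n, nd, 2))
  n_clamped <- 0L
  for (j in seq_len(nd)) {
    g <- withCallingHandlers(
      vbap_gains(mesh, dense_directions[j, , drop = FALSE], solvers),
      warning = function(w) {
        n_clamped <<- n_clamped + 1L
        invokeRestart("muffleWarning")
      })
    w <- g$gains / sum(g$gains)
    for (ear in 1:2)
      dense_mag[, j, ear] <-
        logmag[, g$vertices, ear, drop = TRUE] %*% w
  }
  if (n_clamped > 0)
    warning(n_clamped, " dense directions fell outside the sparse mesh; ",
            "their VBAP gains were clamped")
  toa <- cbind(model_toa(model, dense_directions, "left"),
               model_toa(model, dense_directions, "right"))
  for (ear in 1:2) {
    mp <- min_phase_from_full_mag(10^(dense_mag[, , ear, drop = TRUE] / 20))
    ir[, , ear] <- frac_delay(mp, toa[, ear] * sparse$fs)
  }
  hrtf_set(dense_directions, sparse$fs, ir, toa)
}

# in-band bin mask over the full FFT grid (covers the mirrored
# negative-frequency bins symmetrically)
band_mask <- function(n, fs, f_lo, f_hi) {
  f <- hrtf_freqs(n, fs)
  folded <- pmin(f, fs - f)
  folded >= f_lo & folded <= f_hi
}

#' Flatten the spectral contrast of an HRTF set
#'
#' Within the band `[f_lo, f_hi]` the per-direction, per-ear log-magnitude
#' `m` is replaced by `mbar + C * (m - mbar)`, where `mbar` is the in-band
#' RMS level in dB (the level of the band's power mean), so the per-ear
#' broadband level -- and therefore the ILD -- is preserved. `C = 0` removes
#' all spectral contrast in the band (flat spectrum); `C = 1` is the
#' identity. Phase is rebuilt as minimum phase and the original TOA is
#' re-applied, leaving ITD (and its head-rotation dynamics) untouched.
#'
#' @param set an `hrtf_set`; TOA is estimated first if absent.
#' @param f_lo,f_hi band edges in Hz (`f_hi` is clipped to Nyquist with a
#'   warning if needed).
#' @param C contrast factor in `[0, 1]`.
#' @return an `hrtf_set`.
#' @export
flatten_spectrum <- function(set, f_lo = 1000, f_hi = 16000, C = 0) {
  if (f_lo >= f_hi) stop("f_lo must be below f_hi")
  if (set$fs < 2 * f_hi) {
    warning("sampling rate too low for the requested band; flattening up to ",
            "Nyquist (", set$fs / 2, " Hz)")
    f_hi <- set$fs / 2
  }
  if (is.null(set$toa)) set <- estimate_toa(set)
  n <- dim(set$ir)[1]
  mask <- band_mask(n, set$fs, f_lo, f_hi)
  mag <- hrtf_magnitude(set)
  ir <- array(0, dim(set$ir))
  for (ear in 1:2) {
    m <- 20 * log10(pmax(mag[, , ear, drop = TRUE], max(mag) * 1e-12))
    m <- matrix(m, nrow = n)
    pow_bar <- colMeans(10^(m[mask, , drop = FALSE] / 10))
    mbar <- 10 * log10(pow_bar)
    m[mask, ] <- rep(mbar, each = sum(mask)) +
      C * (m[mask, , drop = FALSE] - rep(mbar, each = sum(mask)))
    mp <- min_phase_from_full_mag(10^(m / 20))
    ir[, , ear] <- frac_delay(mp, set$toa[, ear] * set$fs)
  }
  hrtf_set(set$directions, set$fs, ir, set$toa)
}

#' Freeze the magnitude spectra of an HRTF set to one reference direction
#'
#' Every direction receives the reference direction's per-ear magnitude
#' spectrum (so MSS and ILD are identical everywhere -- "frozen"), while
#' each direction keeps its own TOA, so the ITD and its dynamics are those
#' of the unfrozen set. This is the stimulus manipulation that leaves ITD
#' as the only direction-dependent cue while preserving a natural spectrum.
#'
#' @param set an `hrtf_set`; TOA is estimated first if absent.
#' @param reference a single `dir_sph` direction; must be one of the set's
#'   directions unless `interpolate = TRUE`.
#' @param interpolate if `TRUE`, an off-grid reference magnitude is blended
#'   by VBAP over the set's own triangulation.
#' @return an `hrtf_set`.
#' @export
freeze_spectrum <- function(set, reference = dir_sph(0, 0),
                            interpolate = FALSE) {
  if (is.null(set$toa)) set <- estimate_toa(set)
  n <- dim(set$ir)[1]
  dist <- angular_distance(set$directions, reference)
  ref_idx <- which.min(dist)
  mag <- hrtf_magnitude(set)
  if (dist[ref_idx] < 1e-6) {
    ref_mag <- mag[, ref_idx, , drop = TRUE]
  } else if (interpolate) {
    mesh <- triangulate(set$directions)
    g <- vbap_gains(mesh, reference)
    w <- g$gains / sum(g$gains)
    peak <- max(mag)
    ref_mag <- sapply(1:2, function(ear)
      10^((20 * log10(pmax(mag[, g$vertices, ear, drop = TRUE],
                           peak * 1e-12)) %*% w) / 20))
  } else {
    stop("reference direction is not in the set (nearest is ",
         round(dist[ref_idx], 3), " deg away); use interpolate = TRUE")
  }
  ir <- array(0, dim(set$ir))
  for (ear in 1:2) {
    mp <- min_phase_from_full_mag(matrix(ref_mag[, ear], n, 1))
    block <- matrix(rep(mp, nrow(set$directions)), nrow = n)
    ir[, , ear] <- frac_delay(block, set$toa[, ear] * set$fs)
  }
  hrtf_set(set$directions, set$fs, ir, set$toa)
}
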