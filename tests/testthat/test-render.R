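static_traj <- function(dur = 0.6, fs_track = 90) {
  t <- seq(0, dur, by = 1 / fs_track)
  head_trajectory(t, head_orientation(rep(0, length(t))))
}

yaw_traj <- function(rate = 30, dur = 1, fs_track = 90, latency_s = 0) {
  t <- seq(0, dur, by = 1 / fs_track)
  head_trajectory(t, head_orientation(yaw_deg = rate * t),
                  latency_s = latency_s)
}

test_that("noise bursts have the requested length, ramps, and determinism", {
  s <- make_noise_burst(48000, 2000, seed = 5)
  expect_equal(length(s$samples), 96000)
  expect_equal(s$samples[1], 0)
  expect_lt(abs(s$samples[96000]), 1e-6)
  expect_lte(max(abs(s$samples)), 1)
  expect_identical(s$samples, make_noise_burst(48000, 2000, seed = 5)$samples)
  expect_false(identical(s$samples,
                         make_noise_burst(48000, 2000, seed = 6)$samples))
  expect_error(make_noise_burst(48000, 2000, band_hz = c(100, 50)), "band")
  expect_error(make_noise_burst(48000, 5, ramp_ms = 5), "duration")
})

test_that("gating fires at the first threshold crossing about the instructed axis", {
  expect_equal(gate_at_rotation(yaw_traj(30), "yaw"), 1 / 3,
               tolerance = 1e-9)
  # never reached: falls back to the supplied end-of-signal time
  expect_equal(gate_at_rotation(static_traj(), "yaw", t_end = 2.0), 2.0)
  # crossing exactly at a tracker sample returns that sample's time
  t <- seq(0, 1, by = 0.1)
  tr <- head_trajectory(t, head_orientation(yaw_deg = 20 * t))
  expect_equal(gate_at_rotation(tr, "yaw"), 0.5)
  # only the instructed axis counts
  expect_equal(gate_at_rotation(yaw_traj(30), "pitch", t_end = 1.0), 1.0)
})

test_that("a static head reproduces direct convolution in all conditions", {
  dense <- dense_hrtf()
  stim <- make_noise_burst(48000, 250, seed = 2)
  j <- 100
  src <- dense$directions[j, , drop = FALSE]
  traj <- static_traj(0.3)
  y <- render_dynamic(stim, src, traj, dense, "full")
  ref <- cbind(dynloc:::conv_fft(stim$samples, dense$ir[, j, 1]),
               dynloc:::conv_fft(stim$samples, dense$ir[, j, 2]))
  expect_lt(max(abs(y - ref)), 1e-9)
  # with no rotation the frozen condition is indistinguishable from full
  # (agreement limited only by the Nyquist-bin factor of the real-output
  # fractional delay used when rebuilding the frozen responses)
  y_frozen <- render_dynamic(stim, src, traj, dense, "frozen")
  expect_lt(max(abs(y - y_frozen)), 0.01)
  expect_lt(sqrt(mean((y - y_frozen)^2)) / stats::sd(y[, 1]), 0.01)
})

test_that("renderer rejects mismatched rates and sparse sets", {
  dense <- dense_hrtf()
  sparse <- ico_hrtf()
  stim <- make_noise_burst(44100, 100, seed = 1)
  traj <- static_traj(0.2)
  src <- dir_sph(0, 0)
  expect_error(render_dynamic(stim, src, traj, dense), "rates")
  stim48 <- make_noise_burst(48000, 100, seed = 1)
  expect_error(render_dynamic(stim48, src, traj, sparse), "dense")
})

test_that("output energy after gate-off plus ramp is exactly zero", {
  dense <- dense_hrtf()
  stim <- make_noise_burst(48000, 600, seed = 3)
  traj <- yaw_traj(30)
  y <- render_dynamic(stim, dense$directions[50, , drop = FALSE], traj, dense,
                      gate_axis = "yaw")
  gate_t <- 1 / 3
  i_end <- floor(gate_t * 48000) + 1 + round(0.005 * 48000)
  expect_true(i_end < nrow(y))
  expect_identical(sum(y[(i_end + 1):nrow(y), ]^2), 0)
  expect_gt(sum(y[1:i_end, ]^2), 0)
})

test_that("block crossfading leaves no level steps while the head turns", {
  dense <- dense_hrtf()
  # deterministic stationary carrier: a 1 kHz tone isolates crossfade level
  # steps from the noise's own short-window RMS fluctuation
  n <- round(48000 * 0.4)
  tone <- structure(list(fs = 48000,
                         samples = 0.5 * sin(2 * pi * 1000 * (0:(n - 1)) / 48000),
                         band_hz = c(1000, 1000), ramp_ms = 0),
                    class = "stimulus")
  y <- render_dynamic(tone, dense$directions[10, , drop = FALSE],
                      yaw_traj(20, dur = 0.5), dense)
  h <- round(48000 * 0.005)
  blocks <- seq(4 * h, 0.35 * 48000, by = h)
  rms <- sapply(blocks, function(b) sqrt(mean(y[(b + 1):(b + h), 1]^2)))
  ratio_db <- 20 * abs(diff(log10(rms)))
  expect_lt(max(ratio_db), 1)
})

test_that("tracking latency delays the orientation lookup by one latency", {
  dense <- dense_hrtf()
  stim <- make_noise_burst(48000, 300, seed = 9)
  src <- dense$directions[80, , drop = FALSE]
  lat <- 0.05
  y_lat <- render_dynamic(stim, src, yaw_traj(40, latency_s = lat), dense)
  # same trajectory shifted later by the latency, rendered without latency
  t <- seq(0, 1, by = 1 / 90)
  shifted <- head_trajectory(t, head_orientation(yaw_deg = 40 * pmax(0, t - lat)))
  y_ref <- render_dynamic(stim, src, shifted, dense)
  # agreement within one block of worst-case selection difference
  expect_lt(mean(abs(y_lat - y_ref)), 0.05 * stats::sd(y_ref[, 1]))
})

test_that("frozen rendering keeps the spectral envelope while the ITD develops", {
  dense <- dense_hrtf()
  stim <- make_noise_burst(48000, 500, seed = 12)
  src <- dir_sph(0, 0)
  y <- render_dynamic(stim, src, yaw_traj(40, dur = 0.6), dense, "frozen")
  fs <- 48000
  win <- function(sig, from, to) sig[(from * fs):(to * fs), ]
  early <- win(y, 0.02, 0.12); late <- win(y, 0.38, 0.48)
  # interaural lag: initially near zero, later the right ear leads
  lag_of <- function(w) {
    cc <- stats::ccf(w[, 1], w[, 2], lag.max = 40, plot = FALSE)
    cc$lag[which.max(cc$acf)]
  }
  expect_lte(abs(lag_of(early)), 2)
  lag_late <- lag_of(late)
  expect_gt(abs(lag_late), 3)
  # head yawed left => source moves right in head frame => right ear first,
  # left channel delayed
  expect_gt(lag_late, 0)
  # smoothed spectral envelope of the left channel barely moves (frozen MSS)
  env_db <- function(w) {
    sp <- stats::spec.pgram(w[, 1], spans = 51, plot = FALSE, taper = 0)
    10 * log10(sp$spec)
  }
  d_env <- env_db(early) - env_db(late)
  expect_lt(stats::sd(d_env), 3.5)
})
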