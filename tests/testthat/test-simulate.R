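test_that("the synthetic listener carries ITD, ILD and monotone notch cues", {
  dirs <- dir_sph(c(0, 60, -60, 0, 0, 180), c(0, 0, 0, 45, -30, 0))
  set <- make_synthetic_hrtf(directions = dirs, n_samples = 128, seed = 2)
  # symmetry: median-plane sources have zero ITD
  expect_lt(abs(itd(set)[1]) * set$fs, 1)
  # a source on the left reaches the left ear first
  expect_gt(itd(set)[2], 1e-4)
  expect_lt(itd(set)[3], -1e-4)
  # high-frequency level favours the ipsilateral ear (ILD)
  m <- dynloc:::hrtf_magnitude(set)
  f <- dynloc:::hrtf_freqs(128, set$fs)
  hi <- f >= 4000 & f <= 16000
  ild <- 10 * log10(colSums(m[hi, , 1]^2) / colSums(m[hi, , 2]^2))
  expect_gt(ild[2], 3)
  expect_lt(ild[3], -3)
  expect_lt(abs(ild[1]), 1)
  # notch centre frequency strictly increases with polar angle in range
  cfg <- synthetic_hrtf_config()
  pol <- seq(-45, 90, by = 5)
  fc <- synthetic_notch_center(cfg, pol)
  expect_true(all(diff(fc) > 0))
  # the spectral minimum of a median-plane HRTF tracks the notch
  j <- 4  # (0, 45): polar 45
  band <- f >= 3000 & f <= 16000
  f_min <- f[band][which.min(m[band, j, 1])]
  expect_lt(abs(log2(f_min / synthetic_notch_center(cfg, 45))), 0.2)
  # determinism
  set2 <- make_synthetic_hrtf(directions = dirs, n_samples = 128, seed = 2)
  expect_identical(set$ir, set2$ir)
})

test_that("flattening the synthetic set removes its notch", {
  set <- ico_hrtf()
  flat <- flatten_spectrum(set, C = 0)
  f <- dynloc:::hrtf_freqs(dim(set$ir)[1], set$fs)
  mask <- f >= 1000 & f <= 16000
  sd_before <- max(apply(20 * log10(dynloc:::hrtf_magnitude(set)[mask, , 1]),
                         2, stats::sd))
  sd_after <- max(apply(20 * log10(dynloc:::hrtf_magnitude(flat)[mask, , 1]),
                        2, stats::sd))
  expect_gt(sd_before, 1)
  expect_lt(sd_after, 1e-9)
})

test_that("simulated trajectories hit the configured kinematics", {
  params <- listener_params()
  tr <- simulate_trajectory("left", params, seed = 8)
  expect_identical(tr$t, simulate_trajectory("left", params, seed = 8)$t)
  expect_identical(tr$orientation$yaw_deg,
                   simulate_trajectory("left", params, seed = 8)$orientation$yaw_deg)
  # excursion reaches the instructed amplitude (>= 12 deg required)
  expect_gte(max(abs(tr$orientation$yaw_deg)), 12)
  expect_equal(max(abs(tr$orientation$yaw_deg)), params$excursion_deg,
               tolerance = 1e-6)
  # a rightward arrow rotates the other way; up/down drive pitch
  tr_r <- simulate_trajectory("right", params, seed = 8)
  expect_lt(min(tr_r$orientation$yaw_deg), -12)
  tr_u <- simulate_trajectory("up", params, seed = 8)
  expect_gt(max(tr_u$orientation$pitch_deg), 12)
  # no orthogonal movement without jitter
  quiet <- listener_params(jitter_sd_deg = 0)
  tr_q <- simulate_trajectory("left", quiet, seed = 8)
  expect_identical(max(abs(tr_q$orientation$pitch_deg)), 0)
})

test_that("peak-velocity draws reproduce the population mean", {
  params <- listener_params()
  v <- vapply(1:5000, function(s)
    attr(simulate_trajectory("left", params, seed = s),
         "peak_velocity_deg_s"), numeric(1))
  expect_lt(abs(mean(v) - 36.41), 1)
  expect_lt(abs(stats::sd(v) - 23.03), 2)
  vp <- vapply(1:2000, function(s)
    attr(simulate_trajectory("up", params, seed = s),
         "peak_velocity_deg_s"), numeric(1))
  expect_lt(abs(mean(vp) - 28.54), 1.5)
  r <- vapply(1:2000, function(s)
    attr(simulate_trajectory("left", params, seed = s), "reaction_s"),
    numeric(1))
  expect_gt(mean(r), 0.1)
  expect_lt(mean(r), 0.2)
})

test_that("noise-free responses are exact and reversals follow the mirror rule", {
  grid <- recovery_grid()
  plan <- make_static_session(grid, conditions = "full", reps = 1, seed = 1)
  exact <- listener_params(
    cells = data.frame(condition = "full", rotation = "static",
                       sigma_lat = 0, sigma_pol = 0, p_fbc = 0),
    subject_sd_lat = 0, subject_sd_pol = 0, subject_sd_fbc = 0)
  rt <- simulate_responses(plan, exact, seed = 2)
  expect_equal(rt$response_lateral_deg, rt$target_lateral_deg)
  expect_equal(rt$response_polar_deg, rt$target_polar_deg)
  mirror <- listener_params(
    cells = data.frame(condition = "full", rotation = "static",
                       sigma_lat = 0, sigma_pol = 0, p_fbc = 1),
    subject_sd_lat = 0, subject_sd_pol = 0, subject_sd_fbc = 0)
  rt2 <- simulate_responses(plan, mirror, seed = 2)
  front <- which(abs(rt2$target_polar_deg) < 1e-9 &
                   abs(rt2$target_lateral_deg) < 1e-9)
  expect_true(length(front) > 0)
  expect_equal(rt2$response_polar_deg[front],
               rep(180, length(front)))
  expect_equal(rt2$response_lateral_deg[front],
               rep(0, length(front)))
})

test_that("response scatter matches the generating sigma at large n", {
  grid <- recovery_grid()
  plan <- make_static_session(grid, conditions = "full",
                              reps = ceiling(5000 / 16), seed = 3)
  params <- listener_params(
    cells = data.frame(condition = "full", rotation = "static",
                       sigma_lat = 10, sigma_pol = 20, p_fbc = 0),
    subject_sd_lat = 0, subject_sd_pol = 0, subject_sd_fbc = 0)
  rt <- simulate_responses(plan, params, seed = 4)
  lat_err <- rt$response_lateral_deg - rt$target_lateral_deg
  expect_gt(stats::sd(lat_err), 9.7)
  expect_lt(stats::sd(lat_err), 10.3)
  expect_identical(
    simulate_responses(plan, params, seed = 4)$response_polar_deg,
    rt$response_polar_deg)
})

test_that("ground truth is carried and serialisable", {
  grid <- recovery_grid()
  plan <- make_static_session(grid, conditions = "full", reps = 1, seed = 1,
                              subjects = c("S1", "S2"))
  rt <- simulate_responses(plan, listener_params(
    cells = data.frame(condition = "full", rotation = "static",
                       sigma_lat = 5, sigma_pol = 10, p_fbc = 0.1)), seed = 5)
  gt <- attr(rt, "ground_truth")
  expect_equal(nrow(gt$subject_effects), 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(rt, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(length(parsed$subject_effects), 2)
  # unknown condition/rotation pairs are refused
  bad <- plan; bad$cue_condition <- "nonsense"
  expect_error(simulate_responses(bad, listener_params(), seed = 1),
               "no cell parameters")
})
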