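# Synthetic data with known ground truth: parametric HRTFs (ITD, ILD and
# elevation-dependent spectral-notch cues), head-rotation trajectories with
# reaction delay and population-scale peak velocities, and localization
# responses with cell-dependent lateral/polar scatter and front-back
# reversal probability.

# log-normal draws with given arithmetic mean and SD (positive quantities
# such as peak velocity and reaction time are right-skewed; moment matching
# keeps the population mean at the configured value)
rlnorm_ms <- function(n, mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
}

#' Per-cell and population parameters of the simulated listener
#'
#' `cells` carries, per cue condition x rotation type, the lateral scatter
#' `sigma_lat` (deg), polar scatter `sigma_pol` (deg) and front-back
#' reversal probability `p_fbc`. The defaults encode the population-level
#' pattern the experiment is designed to detect: yaw rotations strongly
#' reduce reversals when spectral cues are absent, pitch rotations do not,
#' and precision differs little across rotations; static free-field scatter
#' sits near 9.3 deg lateral, 20.4 deg polar, 15.4% reversals.
#'
#' Between-subject heterogeneity enters the scatters multiplicatively
#' (log-normal) and the reversal probability additively on the log-odds
#' scale. Peak head-rotation velocities average 36.41 +/- 23.03 deg/s (yaw)
#' and 28.54 +/- 17.50 deg/s (pitch); reaction times average 150 ms.
#'
#' @param cells data.frame with columns `condition`, `rotation`,
#'   `sigma_lat`, `sigma_pol`, `p_fbc`.
#' @param subject_sd_lat,subject_sd_pol between-subject SD of the scatters,
#'   in degrees (converted internally to a log-normal CV).
#' @param subject_sd_fbc between-subject SD of the reversal log-odds.
#' @param vmax_mean,vmax_sd named vectors (yaw, pitch), deg/s.
#' @param reaction_mean,reaction_sd seconds.
#' @param excursion_deg instructed rotation amplitude (must exceed the
#'   10 deg gating threshold plus the 5 deg screening minimum).
#' @param jitter_sd_deg orthogonal-axis wobble SD.
#' @param p_undershoot probability of a lapsed trial whose rotation stays
#'   below the screening minimum.
#' @param p_restless probability of a static trial with head movement
#'   beyond the screening threshold.
#' @return an object of class `listener_params`.
#' @export
listener_params <- function(
    cells = default_cell_params(),
    subject_sd_lat = 2, subject_sd_pol = 4, subject_sd_fbc = 0.5,
    vmax_mean = c(yaw = 36.41, pitch = 28.54),
    vmax_sd = c(yaw = 23.03, pitch = 17.50),
    reaction_mean = 0.15, reaction_sd = 0.025,
    excursion_deg = 20, jitter_sd_deg = 0.6,
    p_undershoot = 0.12, p_restless = 0.02) {
  stopifnot(all(cells$sigma_lat >= 0), all(cells$sigma_pol >= 0),
            all(cells$p_fbc >= 0 & cells$p_fbc <= 1),
            subject_sd_lat >= 0, subject_sd_pol >= 0, subject_sd_fbc >= 0,
            all(vmax_mean > 0), all(vmax_sd >= 0),
            reaction_mean > 0, excursion_deg > 0)
  structure(list(cells = cells,
                 subject_sd_lat = subject_sd_lat,
                 subject_sd_pol = subject_sd_pol,
                 subject_sd_fbc = subject_sd_fbc,
                 vmax_mean = vmax_mean, vmax_sd = vmax_sd,
                 reaction_mean = reaction_mean, reaction_sd = reaction_sd,
                 excursion_deg = excursion_deg,
                 jitter_sd_deg = jitter_sd_deg,
                 p_undershoot = p_undershoot, p_restless = p_restless),
            class = "listener_params")
}

#' @rdname listener_params
#' @export
default_cell_params <- function() {
  rbind(
    data.frame(condition = "full", rotation = c("static", "yaw", "pitch"),
               sigma_lat = c(12.0, 14.0, 12.0), sigma_pol = 25.7,
               p_fbc = c(0.151, 0.10, 0.20)),
    data.frame(condition = "flat", rotation = c("static", "yaw", "pitch"),
               sigma_lat = c(13.0, 16.0, 13.0), sigma_pol = 38.0,
               p_fbc = c(0.40, 0.15, 0.38)),
    data.frame(condition = "frozen", rotation = c("static", "yaw", "pitch"),
               sigma_lat = c(12.0, 14.0, 12.0), sigma_pol = c(25.7, 26.0, 26.0),
               p_fbc = c(0.151, 0.15, 0.20)),
    data.frame(condition = "free_field", rotation = c("static", "yaw", "pitch"),
               sigma_lat = c(9.3, 9.5, 9.5), sigma_pol = c(20.4, 21.0, 21.0),
               p_fbc = c(0.154, 0.05, 0.11)))
}

#' Synthetic HRTF configuration
#'
#' Parameters of the parametric listener: spherical-head model (ITD),
#' lateral-dependent high-frequency head shadow (ILD), an
#' elevation-dependent pinna notch whose centre frequency rises with the
#' polar angle (MSS), a rear spectral tilt distinguishing back from front,
#' and a small seeded spectral ripple.
#'
#' @param model a [spherical_head_model()].
#' @param notch_f0,notch_f1 notch centre frequency (Hz) at the low and high
#'   end of `notch_pol_range` (polar angle, degrees).
#' @param notch_depth_db,notch_width_oct notch depth and width.
#' @param shadow_db maximum broadband head-shadow attenuation.
#' @param rear_tilt_db extra high-frequency attenuation for rear directions.
#' @param ripple_db amplitude of the seeded per-direction spectral ripple.
#' @return an object of class `synthetic_hrtf_config`.
#' @export
synthetic_hrtf_config <- function(model = spherical_head_model(),
                                  notch_f0 = 6000, notch_f1 = 12000,
                                  notch_pol_range = c(-45, 90),
                                  notch_depth_db = 15, notch_width_oct = 0.35,
                                  shadow_db = 8, rear_tilt_db = 3,
                                  ripple_db = 1) {
  stopifnot(notch_f0 > 0, notch_f1 > notch_f0)
  structure(list(model = model, notch_f0 = notch_f0, notch_f1 = notch_f1,
                 notch_pol_range = notch_pol_range,
                 notch_depth_db = notch_depth_db,
                 notch_width_oct = notch_width_oct,
                 shadow_db = shadow_db, rear_tilt_db = rear_tilt_db,
                 ripple_db = ripple_db),
            class = "synthetic_hrtf_config")
}

#' Notch centre frequency of the synthetic listener
#'
#' Strictly increasing in the polar angle over `notch_pol_range`; rear
#' directions mirror through the overhead point with a slight downshift so
#' front and back remain spectrally distinguishable.
#'
#' @param cfg a [synthetic_hrtf_config()].
#' @param polar_deg polar angles in degrees.
#' @return centre frequencies in Hz.
#' @export
synthetic_notch_center <- function(cfg, polar_deg) {
  pol <- wrap_angle(polar_deg, -90)
  rear <- pol > 90
  eff <- ifelse(rear, 180 - pol, pol)
  eff <- pmin(cfg$notch_pol_range[2], pmax(cfg$notch_pol_range[1], eff))
  frac <- (eff - cfg$notch_pol_range[1]) /
    diff(cfg$notch_pol_range)
  fc <- cfg$notch_f0 + frac * (cfg$notch_f1 - cfg$notch_f0)
  ifelse(rear, fc * 0.85, fc)
}

#' Default 91-direction measurement grid
#'
#' Azimuth rings between elevations -47 and 90 deg, denser toward the
#' horizon, totalling 91 directions (a full-sphere loudspeaker layout
#' truncated below -47 deg).
#'
#' @return a `dir_sph` object with 91 rows.
#' @export
synthetic_grid_91 <- function() {
  rings <- list(c(-47, 12), c(-30, 12), c(-15, 12), c(0, 12), c(15, 12),
                c(30, 10), c(45, 8), c(60, 6), c(75, 4), c(82, 2), c(90, 1))
  az <- unlist(lapply(seq_along(rings), function(i) {
    n <- rings[[i]][2]
    seq(0, 360, length.out = n + 1)[1:n] + 7 * i  # stagger rings
  }))
  el <- unlist(lapply(rings, function(r) rep(r[1], r[2])))
  dir_sph(az, el)
}

#' Generate a synthetic HRTF set
#'
#' Builds minimum-phase HRIRs from the parametric magnitude model of
#' [synthetic_hrtf_config()] and applies the spherical-head TOA, yielding a
#' listener-like set with ITD, ILD and monaural spectral-shape cues and
#' exactly reproducible under the seed.
#'
#' @param cfg a [synthetic_hrtf_config()].
#' @param directions grid of measurement directions.
#' @param fs sampling rate in Hz.
#' @param n_samples impulse-response length.
#' @param seed integer seed (drives only the small spectral ripple).
#' @return an `hrtf_set` with TOA filled in.
#' @export
make_synthetic_hrtf <- function(cfg = synthetic_hrtf_config(),
                                directions = synthetic_grid_91(),
                                fs = 48000, n_samples = 256, seed = 1) {
  if (cfg$notch_f1 >= fs / 2) stop("notch frequencies must lie below Nyquist")
  set.seed(seed)
  nd <- nrow(directions)
  ip <- sph_to_interaural(directions)
  f <- hrtf_freqs(n_samples, fs)
  fpos <- pmin(f, fs - f)                     # folded (mirror-symmetric)
  shelf <- fpos^2 / (fpos^2 + 4000^2)
  fc <- synthetic_notch_center(cfg, ip$polar_deg)
  rear <- wrap_angle(ip$polar_deg, -90) > 90
  ir <- array(0, c(n_samples, nd, 2))
  toa <- cbind(model_toa(cfg$model, directions, "left"),
               model_toa(cfg$model, directions, "right"))
  for (ear in 1:2) {
    lat_toward <- if (ear == 1) ip$lateral_deg else -ip$lateral_deg
    mag_db <- matrix(0, n_samples, nd)
    for (j in seq_len(nd)) {
      shadow <- cfg$shadow_db * (sin(deg2rad(lat_toward[j])) - 1) / 2 * shelf
      notch <- -cfg$notch_depth_db *
        exp(-0.5 * (log2(pmax(fpos, 1) / fc[j]) / cfg$notch_width_oct)^2)
      tilt <- if (rear[j]) -cfg$rear_tilt_db * shelf else 0
      ph <- stats::runif(2, 0, 2 * pi)
      ripple <- cfg$ripple_db *
        (sin(2 * pi * log2(pmax(fpos, 1) / 1000) / 3 + ph[1]) +
           0.5 * sin(2 * pi * log2(pmax(fpos, 1) / 1000) / 1.3 + ph[2])) / 1.5
      mag_db[, j] <- shadow + notch + tilt + ripple
    }
    mp <- min_phase_from_full_mag(10^(mag_db / 20))
    ir[, , ear] <- frac_delay(mp, toa[, ear] * fs)
  }
  hrtf_set(directions, fs, ir, toa)
}

#' Simulate one instructed head-rotation trajectory
#'
#' Zero motion during a sampled reaction delay, then a raised-cosine
#' velocity profile about the instructed axis reaching a sampled peak
#' velocity and covering the configured excursion, plus smoothed Gaussian
#' wobble on the orthogonal axis. Peak velocity and reaction time are drawn
#' log-normal with the population moments in `params`.
#'
#' @param arrow `"left"`, `"right"`, `"up"`, or `"down"`.
#' @param params a [listener_params()].
#' @param fs_track tracker sampling rate in Hz.
#' @param seed integer seed.
#' @return a `head_trajectory` with attributes `peak_velocity_deg_s` and
#'   `reaction_s`.
#' @export
simulate_trajectory <- function(arrow = c("left", "right", "up", "down"),
                                params = listener_params(), fs_track = 90,
                                seed = 1) {
  arrow <- match.arg(arrow)
  axis <- if (arrow %in% c("left", "right")) "yaw" else "pitch"
  sgn <- if (arrow %in% c("left", "up")) 1 else -1
  set.seed(seed)
  vmax <- rlnorm_ms(1, params$vmax_mean[[axis]], params$vmax_sd[[axis]])
  reaction <- rlnorm_ms(1, params$reaction_mean, params$reaction_sd)
  exc <- params$excursion_deg
  Tm <- 2 * exc / vmax
  t <- seq(0, reaction + Tm + 0.25, by = 1 / fs_track)
  u <- pmin(Tm, pmax(0, t - reaction))
  ang <- sgn * (vmax / 2) * (u - Tm * sin(2 * pi * u / Tm) / (2 * pi))
  jit <- stats::rnorm(length(t), 0, params$jitter_sd_deg)
  if (params$jitter_sd_deg > 0) {
    jit <- stats::filter(jit, rep(1 / 5, 5), sides = 2)
    jit[is.na(jit)] <- 0
    jit <- jit * params$jitter_sd_deg / max(stats::sd(jit), 1e-12)
  }
  ori <- if (axis == "yaw") head_orientation(ang, as.numeric(jit), 0)
         else head_orientation(as.numeric(jit), ang, 0)
  traj <- head_trajectory(t, ori)
  attr(traj, "peak_velocity_deg_s") <- vmax
  attr(traj, "reaction_s") <- reaction
  traj
}

# row-wise max of |N(0, sd)| over m draws (vectorised)
max_abs_noise <- function(n, m, sd) {
  if (sd == 0 || n == 0) return(numeric(n))
  do.call(pmax, as.data.frame(matrix(abs(stats::rnorm(n * m, 0, sd)), n, m)))
}

#' Simulate localization responses for a trial plan
#'
#' Response model: the target's interaural-polar coordinates receive
#' Gaussian lateral scatter and wrapped Gaussian polar scatter; with the
#' cell's reversal probability the (noiseless) polar angle is first
#' mirrored across the frontal plane (`pol -> 180 - pol`), i.e. the
#' response lands on the same cone of confusion in the wrong hemifield.
#' Per-subject random effects scale the scatters (log-normal) and shift the
#' reversal log-odds. Dynamic trials carry head-rotation summaries (max
#' on-axis and off-axis rotation, peak velocity, reaction time) drawn from
#' the trajectory model, including occasional lapsed trials that the
#' screening stage is meant to remove.
#'
#' @param plan a `trial_plan`.
#' @param params a [listener_params()].
#' @param seed integer seed.
#' @return a data.frame of class `response_table` with the plan columns
#'   plus response coordinates and rotation summaries; the generating
#'   subject effects are attached as `attr(, "ground_truth")`.
#' @export
simulate_responses <- function(plan, params = listener_params(), seed = 1) {
  stopifnot(is.data.frame(plan), nrow(plan) > 0)
  set.seed(seed)
  n <- nrow(plan)
  subjects <- unique(plan$subject_id)
  key <- paste(params$cells$condition, params$cells$rotation)
  row_key <- paste(plan$cue_condition, plan$rotation)
  cell <- match(row_key, key)
  if (any(is.na(cell)))
    stop("no cell parameters for: ",
         paste(unique(row_key[is.na(cell)]), collapse = ", "))

  safe_cv <- function(sd, mu) if (sd == 0 || mu == 0) 0 else sd / mu
  cv_lat <- safe_cv(params$subject_sd_lat, mean(params$cells$sigma_lat))
  cv_pol <- safe_cv(params$subject_sd_pol, mean(params$cells$sigma_pol))
  eff <- data.frame(
    subject_id = subjects,
    lat_factor = exp(stats::rnorm(length(subjects), -cv_lat^2 / 2, cv_lat)),
    pol_factor = exp(stats::rnorm(length(subjects), -cv_pol^2 / 2, cv_pol)),
    fbc_shift = stats::rnorm(length(subjects), 0, params$subject_sd_fbc))
  si <- match(plan$subject_id, subjects)

  sigma_lat <- params$cells$sigma_lat[cell] * eff$lat_factor[si]
  sigma_pol <- params$cells$sigma_pol[cell] * eff$pol_factor[si]
  p0 <- params$cells$p_fbc[cell]
  p_fbc <- ifelse(p0 <= 0, 0, ifelse(p0 >= 1, 1,
                  stats::plogis(stats::qlogis(p0) + eff$fbc_shift[si])))

  fbc <- stats::rbinom(n, 1, p_fbc)
  base_pol <- ifelse(fbc == 1, 180 - plan$target_polar_deg,
                     plan$target_polar_deg)
  resp_pol <- wrap_angle(base_pol + stats::rnorm(n, 0, sigma_pol), -90)
  resp_lat <- pmin(90, pmax(-90,
                            plan$target_lateral_deg +
                              stats::rnorm(n, 0, sigma_lat)))
  resp_sph <- interaural_to_sph(dir_ip(resp_lat, resp_pol))

  rt <- as.data.frame(plan)
  rt$response_azimuth_deg <- resp_sph$azimuth_deg
  rt$response_elevation_deg <- resp_sph$elevation_deg
  rt$response_lateral_deg <- resp_lat
  rt$response_polar_deg <- resp_pol
  rt$fbc_true <- fbc

  dyn <- rt$rotation %in% c("yaw", "pitch")
  rt$on_axis_rotation_deg <- NA_real_
  rt$off_axis_rotation_deg <- NA_real_
  rt$peak_velocity_deg_s <- NA_real_
  rt$reaction_s <- NA_real_
  nd <- sum(dyn)
  if (nd > 0) {
    axis <- rt$rotation[dyn]
    on_axis <- params$excursion_deg + stats::rnorm(nd, 0, 0.5)
    lapse <- stats::runif(nd) < params$p_undershoot
    on_axis[lapse] <- stats::runif(sum(lapse), 0, 5)
    rt$on_axis_rotation_deg[dyn] <- pmax(0, on_axis)
    rt$off_axis_rotation_deg[dyn] <-
      max_abs_noise(nd, 64, params$jitter_sd_deg)
    rt$peak_velocity_deg_s[dyn] <-
      ifelse(axis == "yaw",
             rlnorm_ms(nd, params$vmax_mean[["yaw"]], params$vmax_sd[["yaw"]]),
             rlnorm_ms(nd, params$vmax_mean[["pitch"]],
                       params$vmax_sd[["pitch"]]))
    rt$reaction_s[dyn] <- rlnorm_ms(nd, params$reaction_mean,
                                    params$reaction_sd)
  }
  stat <- !dyn
  ns <- sum(stat)
  if (ns > 0) {
    tot <- max_abs_noise(ns, 16, 0.5)
    restless <- stats::runif(ns) < params$p_restless
    tot[restless] <- stats::runif(sum(restless), 2, 8)
    rt$on_axis_rotation_deg[stat] <- 0
    rt$off_axis_rotation_deg[stat] <- 0
    rt$total_rotation_deg <- NA_real_
    rt$total_rotation_deg[stat] <- tot
  }
  if (!"total_rotation_deg" %in% names(rt)) rt$total_rotation_deg <- NA_real_

  class(rt) <- c("response_table", "data.frame")
  attr(rt, "ground_truth") <- list(params = params, subject_effects = eff,
                                   seed = seed)
  rt
}

#' Write the simulator's ground truth as JSON
#'
#' @param rt a `response_table` from [simulate_responses()].
#' @param path output path.
#' @export
write_ground_truth <- function(rt, path) {
  gt <- attr(rt, "ground_truth")
  if (is.null(gt)) stop("response table carries no ground truth")
  jsonlite::write_json(
    list(cells = gt$params$cells, subject_effects = gt$subject_effects,
         seed = gt$seed),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
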