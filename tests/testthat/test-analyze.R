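make_rt <- function(df) {
  base <- data.frame(subject_id = "S1", cue_condition = "full",
                     rotation = "static", arrow = "none",
                     target_lateral_deg = 0, target_polar_deg = 0,
                     response_lateral_deg = 0, response_polar_deg = 0,
                     on_axis_rotation_deg = 0, off_axis_rotation_deg = 0,
                     total_rotation_deg = NA_real_)
  out <- base[rep(1, nrow(df)), ]
  out[names(df)] <- df
  rownames(out) <- NULL
  class(out) <- c("response_table", "data.frame")
  out
}

test_that("screening applies the 5-degree / 2-degree rules with inclusive boundaries", {
  rt <- make_rt(data.frame(
    rotation = "yaw",
    on_axis_rotation_deg = c(3, 5, 12, 10, 4.9, 30),
    off_axis_rotation_deg = c(0, 2, 1, 2.5, 0, 0)))
  res <- qc_filter(rt)
  expect_equal(nrow(res$responses), 3)
  expect_equal(res$report$excluded_rotation_too_small, 2)
  expect_equal(res$report$excluded_wrong_axis, 1)
  # kept rows are exactly the compliant ones
  expect_equal(res$responses$on_axis_rotation_deg, c(5, 12, 30))
})

test_that("static trials are screened on total movement and missing summaries fail", {
  rt <- make_rt(data.frame(rotation = "static",
                           total_rotation_deg = c(0.5, 2.0, 2.1, 7)))
  res <- qc_filter(rt)
  expect_equal(nrow(res$responses), 2)
  expect_equal(res$report$excluded_static_movement, 2)
  bad <- make_rt(data.frame(rotation = "yaw",
                            on_axis_rotation_deg = NA_real_))
  expect_error(qc_filter(bad), "trajectory summaries")
})

test_that("the FBC classifier implements the lateral limit and crossing allowance", {
  expect_equal(classify_fbc(0, 0, 170), 1L)     # 80 deg past the boundary
  expect_true(is.na(classify_fbc(70, 0, 180)))  # |lateral| > 60: excluded
  expect_equal(classify_fbc(0, 85, 95), 0L)     # within the 10 deg allowance
  expect_equal(classify_fbc(0, 85, 101), 1L)
  expect_equal(classify_fbc(0, 180, 0), 1L)     # back target, front response
  expect_equal(classify_fbc(0, 180, 100.5), 0L)
  expect_equal(classify_fbc(0, -30, -85), 0L)   # below, same hemifield
  expect_equal(classify_fbc(60, 0, 180), 1L)    # limit itself is eligible
})

test_that("the FBC rule is symmetric under the front-back mirror", {
  set.seed(61)
  tp <- stats::runif(500, -90, 270)
  rp <- stats::runif(500, -90, 270)
  tl <- stats::runif(500, -90, 90)
  a <- classify_fbc(tl, tp, rp)
  b <- classify_fbc(tl, 180 - tp, 180 - rp)
  expect_identical(a, b)
})

test_that("alternative FBC presets change eligibility and allowance only", {
  expect_equal(alt_fbc_definition(0, 85, 95, "middlebrooks"), 1L)
  expect_equal(alt_fbc_definition(0, 85, 95, "default"), 0L)
  expect_true(is.na(alt_fbc_definition(40, 0, 180, "middlebrooks")))
  expect_equal(alt_fbc_definition(40, 0, 180, "default"), 1L)
  expect_equal(alt_fbc_definition(0, 0, 0, "middlebrooks"), 0L)
  expect_equal(alt_fbc_definition(0, 0, 0, "default"), 0L)
  expect_error(match.arg("bogus", c("default", "middlebrooks")))
})

test_that("localization errors wrap the polar difference circularly", {
  e <- localization_errors(dir_ip(0, 0), dir_ip(0, 0))
  expect_equal(unlist(e), c(lateral_error_deg = 0, polar_error_deg = 0))
  e2 <- localization_errors(dir_ip(0, 260), dir_ip(0, -80))
  expect_equal(e2$polar_error_deg, 20)
  e3 <- localization_errors(dir_ip(-30, 0), dir_ip(30, 0))
  expect_equal(e3$lateral_error_deg, 60)
  e4 <- localization_errors(dir_ip(0, -80), dir_ip(0, 260))
  expect_equal(e4$polar_error_deg, -20)
})

test_that("metrics compute SDs and rates per the screening rules", {
  perfect <- make_rt(data.frame(target_polar_deg = c(0, 30, 150, 180),
                                response_polar_deg = c(0, 30, 150, 180)))
  m <- compute_metrics(perfect)
  expect_equal(m$lpe_deg, 0)
  expect_equal(m$ppe_deg, 0)
  expect_equal(m$fbc_rate_pct, 0)
  spread <- make_rt(data.frame(response_lateral_deg = c(-5, 5, -5, 5)))
  expect_equal(compute_metrics(spread)$lpe_deg, 5.773503, tolerance = 1e-6)
  # 2 confusions among 10 eligible: 20% rate, and PPE drops those trials
  mixed <- make_rt(data.frame(
    target_polar_deg = rep(0, 10),
    response_polar_deg = c(rep(5, 8), 180, 185)))
  mm <- compute_metrics(mixed)
  expect_equal(mm$fbc_rate_pct, 20)
  expect_equal(mm$n_fbc_eligible, 10)
  expect_equal(mm$ppe_deg, stats::sd(rep(5, 8)))
  single <- make_rt(data.frame(response_lateral_deg = 1))
  expect_true(is.na(compute_metrics(single)$lpe_deg))
})

test_that("removing confusions can only reduce the polar precision error", {
  set.seed(71)
  for (i in 1:20) {
    n <- 40
    tp <- sample(c(0, 30, 180), n, replace = TRUE)
    flip <- stats::runif(n) < 0.2
    rp <- ifelse(flip, 180 - tp, tp) + stats::rnorm(n, 0, 15)
    rt <- make_rt(data.frame(target_polar_deg = tp,
                             response_polar_deg = dynloc:::wrap_angle(rp, -90)))
    fbc <- classify_fbc(rt$target_lateral_deg, rt$target_polar_deg,
                        rt$response_polar_deg)
    if (!any(fbc == 1, na.rm = TRUE)) next
    ppe_excl <- compute_metrics(rt)$ppe_deg
    err <- localization_errors(dir_ip(rt$target_lateral_deg, rt$target_polar_deg),
                               dir_ip(rt$response_lateral_deg, rt$response_polar_deg))
    ppe_incl <- stats::sd(err$polar_error_deg)
    expect_lte(ppe_excl, ppe_incl + 1e-9)
  }
})

test_that("swapping the FBC classifier never changes the LPE", {
  set.seed(81)
  rt <- make_rt(data.frame(
    target_polar_deg = stats::runif(60, -90, 270),
    target_lateral_deg = stats::runif(60, -90, 90),
    response_polar_deg = stats::runif(60, -90, 270),
    response_lateral_deg = stats::runif(60, -90, 90)))
  m1 <- compute_metrics(rt, classify_fbc)
  m2 <- compute_metrics(rt, function(tl, tp, rp)
    alt_fbc_definition(tl, tp, rp, "middlebrooks"))
  expect_identical(m1$lpe_deg, m2$lpe_deg)
  expect_false(identical(m1$fbc_rate_pct, m2$fbc_rate_pct))
})
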