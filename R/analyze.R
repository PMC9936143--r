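# Response screening and localization-performance metrics.
#
# Screening: dynamic trials must show at least 5 deg of rotation about the
# instructed axis and at most 2 deg about the orthogonal axis; static
# trials must stay within a (configurable) movement threshold. Metrics per
# subject x condition x rotation: lateral precision error (LPE, SD of
# lateral errors), polar precision error (PPE, SD of polar errors with
# front-back-confused trials removed first, keeping the metrics
# independent), and front-back confusion (FBC) rate in percent.

#' Screen responses for head-movement outliers
#'
#' Dynamic rows are kept iff the on-axis rotation is at least `min_on_axis`
#' degrees and the off-axis rotation at most `max_off_axis` degrees (both
#' boundaries inclusive). Static rows are kept iff their total rotation is
#' within `static_threshold` (or carries no movement record).
#'
#' @param rt a `response_table`.
#' @param min_on_axis,max_off_axis dynamic screening thresholds, degrees.
#' @param static_threshold static screening threshold, degrees.
#' @return a list with `responses` (the surviving rows) and `report`
#'   (counts per exclusion reason).
#' @export
qc_filter <- function(rt, min_on_axis = 5, max_off_axis = 2,
                      static_threshold = 2) {
  stopifnot(is.data.frame(rt))
  dyn <- rt$rotation %in% c("yaw", "pitch")
  if (any(dyn & (is.na(rt$on_axis_rotation_deg) |
                 is.na(rt$off_axis_rotation_deg))))
    stop("dynamic rows without trajectory summaries cannot be screened")
  too_small <- dyn & rt$on_axis_rotation_deg < min_on_axis
  wrong_axis <- dyn & !too_small & rt$off_axis_rotation_deg > max_off_axis
  static_moved <- !dyn & !is.na(rt$total_rotation_deg) &
    rt$total_rotation_deg > static_threshold
  keep <- !(too_small | wrong_axis | static_moved)
  out <- rt[keep, , drop = FALSE]
  class(out) <- class(rt)
  attr(out, "ground_truth") <- attr(rt, "ground_truth")
  list(responses = out,
       report = list(n_input = nrow(rt), n_kept = sum(keep),
                     excluded_rotation_too_small = sum(too_small),
                     excluded_wrong_axis = sum(wrong_axis),
                     excluded_static_movement = sum(static_moved),
                     min_on_axis = min_on_axis, max_off_axis = max_off_axis,
                     static_threshold = static_threshold))
}

#' Classify a response as front-back confused
#'
#' Targets with `|lateral| > lat_limit` degrees are excluded from
#' classification (`NA`). Otherwise the target hemifield is front for polar
#' angles in `[-90, 90]` and back beyond; the response counts as a
#' confusion (1) iff its polar angle lies more than `cross_allow` degrees
#' past the front/back boundary (polar 90 and 270 deg) into the opposite
#' hemifield, and 0 otherwise. The rule is symmetric under mirroring both
#' target and response through the frontal plane.
#'
#' @param target_lateral_deg,target_polar_deg target interaural-polar
#'   coordinates (vectorised).
#' @param response_polar_deg response polar angle.
#' @param lat_limit lateral exclusion limit, degrees.
#' @param cross_allow allowed crossing past the boundary, degrees.
#' @return integer vector: 0, 1, or `NA` (excluded).
#' @export
classify_fbc <- function(target_lateral_deg, target_polar_deg,
                         response_polar_deg, lat_limit = 60,
                         cross_allow = 10) {
  tp <- wrap_angle(target_polar_deg, -90)
  rp <- wrap_angle(response_polar_deg, -90)
  front <- tp <= 90
  # response deep in the back hemifield / deep in the front hemifield
  in_back <- rp > 90 + cross_allow & rp < 270 - cross_allow
  in_front <- rp < 90 - cross_allow & rp > -90 + cross_allow
  fbc <- ifelse(front, as.integer(in_back), as.integer(in_front))
  fbc[abs(target_lateral_deg) > lat_limit] <- NA_integer_
  fbc
}

#' Alternative front-back-confusion definitions
#'
#' Pluggable rule presets for sensitivity analyses. `"default"` is the
#' 60-degree lateral exclusion with a 10-degree crossing allowance;
#' `"middlebrooks"` uses a 30-degree lateral exclusion and no allowance
#' (hemifield by polar quadrant).
#'
#' @inheritParams classify_fbc
#' @param preset `"default"` or `"middlebrooks"`.
#' @return as [classify_fbc()].
#' @export
alt_fbc_definition <- function(target_lateral_deg, target_polar_deg,
                               response_polar_deg,
                               preset = c("default", "middlebrooks")) {
  preset <- match.arg(preset)
  switch(preset,
         default = classify_fbc(target_lateral_deg, target_polar_deg,
                                response_polar_deg, 60, 10),
         middlebrooks = classify_fbc(target_lateral_deg, target_polar_deg,
                                     response_polar_deg, 30, 0))
}

#' Lateral and polar localization errors
#'
#' Lateral error is the plain difference of lateral angles; polar error is
#' the circular difference wrapped to `(-180, 180]`.
#'
#' @param target,response `dir_ip` objects (or data.frames with
#'   `lateral_deg`, `polar_deg`).
#' @return a data.frame with `lateral_error_deg`, `polar_error_deg`.
#' @export
localization_errors <- function(target, response) {
  data.frame(
    lateral_error_deg = response$lateral_deg - target$lateral_deg,
    polar_error_deg = -wrap_angle(-(response$polar_deg - target$polar_deg),
                                  -180))
}

#' Localization-performance metrics per cell
#'
#' Per subject x cue condition x rotation type: LPE (SD of lateral errors
#' about the cell mean, n-1 denominator), FBC rate (percent of confusions
#' among FBC-eligible trials), and PPE (SD of polar errors over trials that
#' are not classified as confusions; FBC-ineligible trials have no label
#' and stay in the PPE sample). Cells with fewer than two usable trials get
#' `NA` for the affected metric.
#'
#' @param rt a screened `response_table` (see [qc_filter()]).
#' @param fbc_classifier function with the [classify_fbc()] interface.
#' @return a data.frame of class `metrics_table` with columns `subject`,
#'   `condition`, `rotation`, `lpe_deg`, `ppe_deg`, `fbc_rate_pct`,
#'   `n_trials`, `n_fbc_eligible`.
#' @export
compute_metrics <- function(rt, fbc_classifier = classify_fbc) {
  stopifnot(is.data.frame(rt), nrow(rt) > 0)
  err <- localization_errors(
    dir_ip(rt$target_lateral_deg, rt$target_polar_deg),
    dir_ip(rt$response_lateral_deg, rt$response_polar_deg))
  fbc <- fbc_classifier(rt$target_lateral_deg, rt$target_polar_deg,
                        rt$response_polar_deg)
  groups <- interaction(rt$subject_id, rt$cue_condition, rt$rotation,
                        drop = TRUE)
  res <- lapply(split(seq_len(nrow(rt)), groups), function(idx) {
    f <- fbc[idx]
    elig <- !is.na(f)
    ppe_idx <- idx[!elig | f == 0]
    data.frame(
      subject = rt$subject_id[idx[1]],
      condition = rt$cue_condition[idx[1]],
      rotation = rt$rotation[idx[1]],
      lpe_deg = if (length(idx) >= 2)
        stats::sd(err$lateral_error_deg[idx]) else NA_real_,
      ppe_deg = if (length(ppe_idx) >= 2)
        stats::sd(err$polar_error_deg[ppe_idx]) else NA_real_,
      fbc_rate_pct = if (sum(elig) >= 1) 100 * mean(f[elig]) else NA_real_,
      n_trials = length(idx),
      n_fbc_eligible = sum(elig))
  })
  mt <- do.call(rbind, res)
  rownames(mt) <- NULL
  class(mt) <- c("metrics_table", "data.frame")
  mt
}

#' Trial-level FBC labels for the logistic stage
#'
#' Adds an `fbc` column (0/1) to the screened response table and drops
#' FBC-ineligible trials (targets beyond the lateral limit).
#'
#' @inheritParams compute_metrics
#' @return a data.frame with the eligible rows and an `fbc` column.
#' @export
fbc_trials <- function(rt, fbc_classifier = classify_fbc) {
  fbc <- fbc_classifier(rt$target_lateral_deg, rt$target_polar_deg,
                        rt$response_polar_deg)
  out <- as.data.frame(rt)[!is.na(fbc), , drop = FALSE]
  out$fbc <- fbc[!is.na(fbc)]
  out
}
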