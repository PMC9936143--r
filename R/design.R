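# Source grids and trial plans.
#
# The experiment tests localization over several sagittal planes ("cones of
# confusion"): a dense set of directions on the median plane (where head
# rotations help most, especially at high elevations) plus symmetric pairs of
# lateral planes. Median-plane directions are tested twice per block because
# of left-right symmetry, giving the 52-entry test list from a 41-direction
# grid.

#' Default sagittal-plane grid layout
#'
#' A layout is a list of sagittal planes, each `list(lateral_deg, polar_deg)`.
#' The default produces 41 unique directions, 11 of them on the median plane,
#' with denser polar sampling near and above 90 deg (overhead), all within
#' elevations \[-47, 90\] (the coverage of a full-sphere loudspeaker array
#' truncated below -47 deg elevation).
#'
#' @return a list of plane specifications.
#' @export
default_grid_layout <- function() {
  list(
    list(lateral_deg = 0,
         polar_deg = c(-30, 0, 30, 60, 75, 90, 105, 120, 150, 180, 210)),
    list(lateral_deg = 20,  polar_deg = c(-45, 0, 45, 90, 135, 180)),
    list(lateral_deg = -20, polar_deg = c(-45, 0, 45, 90, 135, 180)),
    list(lateral_deg = 40,  polar_deg = c(0, 60, 90, 120, 180)),
    list(lateral_deg = -40, polar_deg = c(0, 60, 90, 120, 180)),
    list(lateral_deg = 60,  polar_deg = c(0, 90, 135, 180)),
    list(lateral_deg = -60, polar_deg = c(0, 90, 135, 180))
  )
}

#' Build the source-direction grid
#'
#' Lays out directions on sagittal planes and flags those on the median
#' plane (azimuth 0 or 180). Duplicate directions or directions below the
#' supported elevation range are rejected.
#'
#' @param layout list of planes as in [default_grid_layout()].
#' @param elevation_range allowed elevations in degrees, default `c(-47, 90)`.
#' @return a data.frame of class `source_grid` with columns `azimuth_deg`,
#'   `elevation_deg`, `lateral_deg`, `polar_deg`, `on_median`.
#' @examples
#' g <- make_source_grid()
#' nrow(g)            # 41
#' sum(g$on_median)   # 11
#' @export
make_source_grid <- function(layout = default_grid_layout(),
                             elevation_range = c(-47, 90)) {
  stopifnot(is.list(layout), length(layout) >= 1)
  lat <- unlist(lapply(layout, function(p)
    rep(p$lateral_deg, length(p$polar_deg))))
  pol <- unlist(lapply(layout, function(p) p$polar_deg))
  ip <- dir_ip(lat, pol)
  sph <- interaural_to_sph(ip)
  if (any(sph$elevation_deg < elevation_range[1] - 1e-9 |
          sph$elevation_deg > elevation_range[2] + 1e-9))
    stop("layout places directions outside the supported elevation range [",
         elevation_range[1], ", ", elevation_range[2], "]")
  v <- sph_to_cart(sph)
  if (nrow(v) > 1) {
    dots <- tcrossprod(v)
    diag(dots) <- -1
    if (any(dots > 1 - 1e-12))
      stop("layout contains duplicate directions")
  }
  on_median <- abs(ip$lateral_deg) < 1e-9
  g <- data.frame(azimuth_deg = sph$azimuth_deg,
                  elevation_deg = sph$elevation_deg,
                  lateral_deg = ip$lateral_deg,
                  polar_deg = ip$polar_deg,
                  on_median = on_median)
  class(g) <- c("source_grid", "data.frame")
  g
}

#' Expand a grid into the per-block test list
#'
#' Every direction appears once, and each median-plane direction appears a
#' second time (left-right symmetry halves the effective sampling there).
#'
#' @param grid a `source_grid`.
#' @return a data.frame with the grid columns, one row per test-list entry;
#'   `length = nrow(grid) + sum(grid$on_median)`.
#' @export
make_test_list <- function(grid) {
  stopifnot(inherits(grid, "source_grid") || is.data.frame(grid))
  out <- rbind(as.data.frame(grid), as.data.frame(grid)[grid$on_median, ])
  rownames(out) <- NULL
  out
}

# Derive a stream of sub-seeds from one session seed. Simple LCG step on the
# 31-bit ring so plans are bit-reproducible yet blocks/subjects decouple.
split_seed <- function(seed, index) {
  a <- 1103515245; c <- 12345; m <- 2^31
  s <- as.numeric(seed) %% m
  for (i in seq_len(index)) s <- (a * s + c) %% m
  as.integer(s %% (m - 1)) + 1L
}

make_session <- function(grid, conditions, reps, seed, subjects,
                         session, arrows) {
  stopifnot(reps >= 1, length(conditions) >= 1)
  tl <- make_test_list(grid)
  rows <- list()
  k <- 0L
  for (si in seq_along(subjects)) {
    blocks <- expand.grid(rep = seq_len(reps), cond = conditions,
                          stringsAsFactors = FALSE)
    set.seed(split_seed(seed, si))
    blocks <- blocks[sample.int(nrow(blocks)), , drop = FALSE]
    for (bi in seq_len(nrow(blocks))) {
      if (identical(arrows, "none")) {
        trial_arrow <- rep("none", nrow(tl))
        idx <- seq_len(nrow(tl))
      } else {
        idx <- rep(seq_len(nrow(tl)), times = length(arrows))
        trial_arrow <- rep(arrows, each = nrow(tl))
      }
      k <- k + 1L
      set.seed(split_seed(seed, 1000L * si + bi))
      perm <- sample.int(length(idx))
      rot <- c(none = "static", left = "yaw", right = "yaw",
               up = "pitch", down = "pitch")[trial_arrow[perm]]
      rows[[k]] <- data.frame(
        subject_id = subjects[si],
        session = session,
        block_index = bi,
        cue_condition = blocks$cond[bi],
        rotation = unname(rot),
        arrow = trial_arrow[perm],
        target_azimuth_deg = tl$azimuth_deg[idx[perm]],
        target_elevation_deg = tl$elevation_deg[idx[perm]],
        target_lateral_deg = tl$lateral_deg[idx[perm]],
        target_polar_deg = tl$polar_deg[idx[perm]],
        repetition_index = blocks$rep[bi],
        stringsAsFactors = FALSE)
    }
  }
  plan <- do.call(rbind, rows)
  plan$trial_index <- seq_len(nrow(plan))
  class(plan) <- c("trial_plan", "data.frame")
  plan
}

#' Static-session trial plan
#'
#' `reps x length(conditions)` blocks, each a seeded permutation of the
#' 52-entry test list; block order is a per-subject seeded permutation. All
#' trials have `arrow = "none"` and `rotation = "static"`. The default
#' (3 conditions x 3 reps) yields the nine 52-trial blocks of a static
#' localization session.
#'
#' @param grid a `source_grid`.
#' @param conditions character vector of cue conditions.
#' @param reps repetitions per condition.
#' @param seed integer session seed.
#' @param subjects vector of subject ids.
#' @return a data.frame of class `trial_plan`.
#' @export
make_static_session <- function(grid,
                                conditions = c("full", "flat", "free_field"),
                                reps = 3, seed = 1, subjects = "S1") {
  make_session(grid, conditions, reps, seed, subjects,
               session = "static", arrows = "none")
}

#' Dynamic-session trial plan
#'
#' Each block crosses the four instructed arrows (up/down -> pitch,
#' left/right -> yaw) with the full test list and shuffles the result, so a
#' default block holds 4 x 52 = 208 trials; the default (4 conditions x
#' 3 reps) yields 12 blocks.
#'
#' @inheritParams make_static_session
#' @export
make_dynamic_session <- function(grid,
                                 conditions = c("full", "flat", "frozen",
                                                "free_field"),
                                 reps = 3, seed = 1, subjects = "S1") {
  make_session(grid, conditions, reps, seed, subjects,
               session = "dynamic", arrows = c("up", "down", "left", "right"))
}

#' Write / read a trial plan as CSV
#'
#' @param plan a `trial_plan`.
#' @param path file path.
#' @return `read_trial_plan` returns a `trial_plan`.
#' @export
write_trial_plan <- function(plan, path) {
  utils::write.csv(as.data.frame(plan), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_plan
#' @export
read_trial_plan <- function(path) {
  plan <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(plan) <- c("trial_plan", "data.frame")
  plan
}
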