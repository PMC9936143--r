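# Plain-text HRIR interchange. The field layout mirrors the
# SimpleFreeFieldHRIR convention (SourcePosition, Data.SamplingRate,
# Data.IR, Data.Delay) in a line-oriented text file, so sets survive a
# round trip losslessly and the file is diffable and portable.
#
# Coordinate note: the file stores azimuth counterclockwise-positive in
# [0, 360) (the interchange convention); internally azimuth is
# left-positive in [-180, 180). The two agree up to wrapping, since
# counterclockwise from the front (seen from above) is toward the left.

#' Write an HRTF set to a text HRIR file
#'
#' @param set an `hrtf_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_hrtf()]
#' @export
write_hrtf <- function(set, path) {
  stopifnot(inherits(set, "hrtf_set"))
  n <- dim(set$ir)[1]; m <- dim(set$ir)[2]
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) sprintf("%.17g", x)
  writeLines(c(
    "# dynloc HRIR text format v1 (SimpleFreeFieldHRIR field layout)",
    paste("Data.SamplingRate:", num(set$fs)),
    paste("Dimensions:", sprintf("M=%d N=%d R=2", m, n)),
    "SourcePosition: azimuth_deg elevation_deg (counterclockwise azimuth, [0,360))"
  ), con)
  pos <- cbind(wrap_angle(set$directions$azimuth_deg, 0),
               set$directions$elevation_deg)
  writeLines(apply(pos, 1, function(r) paste(num(r), collapse = " ")), con)
  if (is.null(set$toa)) {
    writeLines("Data.Delay: none", con)
  } else {
    writeLines("Data.Delay: seconds (M rows, columns left right)", con)
    writeLines(apply(set$toa, 1, function(r) paste(num(r), collapse = " ")),
               con)
  }
  writeLines("Data.IR: one row per (direction, ear), ears left then right", con)
  for (ear in 1:2)
    for (j in seq_len(m))
      writeLines(paste(num(set$ir[, j, ear]), collapse = " "), con)
  invisible(path)
}

#' Read an HRTF set from a text HRIR file
#'
#' @param path file written by [write_hrtf()].
#' @return an `hrtf_set`.
#' @export
read_hrtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  need <- function(tag) {
    i <- grep(paste0("^", tag, ":"), lines)
    if (length(i) != 1)
      stop("malformed HRIR file: missing attribute '", tag, "'")
    i
  }
  fs <- as.numeric(sub("^Data.SamplingRate:\\s*", "",
                       lines[need("Data.SamplingRate")]))
  dims <- lines[need("Dimensions")]
  m <- as.integer(sub(".*M=(\\d+).*", "\\1", dims))
  n <- as.integer(sub(".*N=(\\d+).*", "\\1", dims))
  parse_rows <- function(start, count) {
    vals <- lapply(lines[start + seq_len(count) - 1], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    lens <- lengths(vals)
    if (length(unique(lens)) != 1)
      stop("malformed HRIR file: rows of unequal length after line ", start)
    do.call(rbind, vals)
  }
  ip <- need("SourcePosition")
  pos <- parse_rows(ip + 1, m)
  if (ncol(pos) != 2) stop("malformed HRIR file: SourcePosition needs 2 columns")
  id <- need("Data.Delay")
  toa <- NULL
  ir_start <- id + 1
  if (!grepl("none", lines[id])) {
    toa <- parse_rows(id + 1, m)
    if (ncol(toa) != 2) stop("malformed HRIR file: Data.Delay needs 2 columns")
    ir_start <- id + 1 + m
  }
  ii <- need("Data.IR")
  rows <- parse_rows(ii + 1, 2 * m)
  if (ncol(rows) != n)
    stop("malformed HRIR file: Data.IR rows have ", ncol(rows),
         " samples, expected N=", n)
  ir <- array(0, c(n, m, 2))
  for (ear in 1:2)
    ir[, , ear] <- t(rows[(ear - 1) * m + seq_len(m), , drop = FALSE])
  hrtf_set(dir_sph(pos[, 1], pos[, 2]), fs, ir, toa)
}
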