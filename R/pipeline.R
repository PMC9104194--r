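# Pattern pipeline: frames -> vertical intensity profiles -> the two MagLev
# fingerprints (starting position, levitating fraction area).
#
# All frames use a bottom-up row convention internally (row 1 = bottom of
# the cuvette); heights are millimetres measured from the ROI bottom.

#' Time-lapse frame series
#'
#' @param frames List of numeric matrices, all the same shape, row 1 =
#'   bottom of the field of view.
#' @param times Frame acquisition times in seconds, strictly increasing.
#' @param pixel_to_mm Height of one pixel row in millimetres.
#' @param roi Region of interest, `list(rows = c(lo, hi), cols = c(lo, hi))`
#'   in pixel indices (bottom-up); defaults to the full frame.
#' @param meta Optional metadata list (seed, optics, ground truth, ...).
#' @return Object of class `frame_series`.
#' @export
frame_series <- function(frames, times, pixel_to_mm, roi = NULL, meta = list()) {
  stopifnot(is.list(frames), length(frames) >= 1,
            length(times) == length(frames), all(diff(times) > 0),
            pixel_to_mm > 0)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent frame shapes")
  H <- dims[1, 1]; W <- dims[2, 1]
  if (is.null(roi)) roi <- list(rows = c(1L, H), cols = c(1L, W))
  stopifnot(roi$rows[1] >= 1, roi$rows[2] <= H, roi$rows[1] < roi$rows[2],
            roi$cols[1] >= 1, roi$cols[2] <= W, roi$cols[1] <= roi$cols[2])
  structure(list(frames = frames, times = times, pixel_to_mm = pixel_to_mm,
                 roi = roi, meta = meta),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("frame_series: %d frames of %d x %d px, t = %g..%g s, %.4g mm/px\n",
              length(x$frames), d[1], d[2], min(x$times), max(x$times),
              x$pixel_to_mm))
  invisible(x)
}

# --- plain-text PGM (P2) image I/O -----------------------------------------
# ASCII PGM keeps the deliverable text-only and is readable by any image
# viewer. Intensities are quantized to 16 bits against a per-series scale
# stored in the JSON sidecar.

.write_pgm <- function(mat, path, maxval = 65535L) {
  top_down <- mat[rev(seq_len(nrow(mat))), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(mat), nrow(mat)), as.character(maxval)), con)
  write(t(top_down), file = con, ncolumns = ncol(mat))
}

.read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt[-1], collapse = " "), what = numeric(),
              quiet = TRUE)
  if (!identical(txt[1], "P2")) stop("not an ASCII PGM (P2) file: ", path)
  W <- tok[1]; H <- tok[2]
  vals <- tok[-(1:3)]
  if (length(vals) != W * H) stop("corrupt PGM payload: ", path)
  mat <- matrix(vals, nrow = H, ncol = W, byrow = TRUE)
  mat[rev(seq_len(H)), , drop = FALSE]   # back to bottom-up
}

#' Write a frame series to a directory (ASCII PGM + JSON sidecar)
#'
#' @param series A [frame_series()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_frames <- function(series, dir) {
  stopifnot(inherits(series, "frame_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lo <- min(vapply(series$frames, min, numeric(1)))
  hi <- max(vapply(series$frames, max, numeric(1)))
  scale <- if (hi > lo) 65535 / (hi - lo) else 1
  for (i in seq_along(series$frames)) {
    q <- round((series$frames[[i]] - lo) * scale)
    .write_pgm(q, file.path(dir, sprintf("frame_%04d.pgm", i)))
  }
  sidecar <- list(format = "maglevneb-frames-v1",
                  times = series$times,
                  pixel_to_mm = series$pixel_to_mm,
                  roi = series$roi,
                  intensity_offset = lo, intensity_scale = scale,
                  meta = series$meta)
  jsonlite::write_json(sidecar, file.path(dir, "frames.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a frame series from a directory of PGM files
#'
#' Frames are ordered by file name; a `frames.json` sidecar (written by
#' [write_frames()]) supplies times, calibration and ROI, which can be
#' overridden by the arguments.
#'
#' @param path Directory containing `frame_*.pgm` (plus optional sidecar).
#' @param roi,pixel_to_mm Optional overrides of the sidecar values.
#' @return A [frame_series()].
#' @export
load_frames <- function(path, roi = NULL, pixel_to_mm = NULL) {
  files <- sort(list.files(path, pattern = "\\.pgm$", full.names = TRUE))
  if (length(files) == 0) stop("no PGM frames found in ", path)
  frames <- lapply(files, .read_pgm)
  dims <- vapply(frames, dim, integer(2))
  bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
  if (length(bad))
    stop("inconsistent frame shapes: ", paste(basename(files[bad]), collapse = ", "))
  side_path <- file.path(path, "frames.json")
  meta <- list()
  times <- seq_along(frames) - 1
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    times <- side$times
    if (is.null(pixel_to_mm)) pixel_to_mm <- side$pixel_to_mm
    if (is.null(roi) && !is.null(side$roi)) roi <- side$roi
    if (!is.null(side$intensity_scale))
      frames <- lapply(frames, function(f)
        f / side$intensity_scale + side$intensity_offset)
    meta <- if (is.null(side$meta)) list() else side$meta
  }
  if (is.null(pixel_to_mm)) stop("pixel_to_mm missing (no sidecar found)")
  frame_series(frames, times, pixel_to_mm, roi = roi, meta = meta)
}

# --- profiles ---------------------------------------------------------------

#' Vertical intensity profile of one frame
#'
#' For each pixel row inside the ROI, the intensity is averaged over the ROI
#' columns; heights are row centres in millimetres from the ROI bottom.
#'
#' @param frame Numeric matrix (bottom-up rows).
#' @param roi ROI list as in [frame_series()].
#' @param pixel_to_mm Millimetres per pixel row.
#' @param time Acquisition time attached to the profile, seconds.
#' @return Object of class `intensity_profile` with `heights`, `intensities`,
#'   `time`, `normalized`.
#' @export
vertical_profile <- function(frame, roi = NULL, pixel_to_mm = 1, time = NA_real_) {
  if (is.null(roi))
    roi <- list(rows = c(1L, nrow(frame)), cols = c(1L, ncol(frame)))
  rows <- roi$rows[1]:roi$rows[2]
  cols <- roi$cols[1]:roi$cols[2]
  if (length(rows) < 1 || length(cols) < 1) stop("empty ROI")
  sub <- frame[rows, cols, drop = FALSE]
  structure(list(heights = (seq_along(rows) - 0.5) * pixel_to_mm,
                 intensities = rowMeans(sub),
                 time = time, normalized = FALSE),
            class = "intensity_profile")
}

.profile_of_frame <- function(series, index) {
  vertical_profile(series$frames[[index]], series$roi, series$pixel_to_mm,
                   time = series$times[index])
}

#' Blank profile from the per-row minimum across a series
#'
#' Used as the background estimate when no pre-injection blank frame is
#' available: migrating particles rarely occupy the same row in every frame,
#' so the per-row minimum approximates the static background.
#'
#' @param series A [frame_series()].
#' @return An `intensity_profile`.
#' @export
series_blank <- function(series) {
  profs <- lapply(seq_along(series$frames), function(i)
    .profile_of_frame(series, i)$intensities)
  p <- .profile_of_frame(series, 1)
  p$intensities <- do.call(pmin, profs)
  p$time <- NA_real_
  p
}

#' Subtract a background profile
#'
#' Pointwise difference, floored at zero.
#'
#' @param profile,blank_profile `intensity_profile`s on the same height grid.
#' @return An `intensity_profile`.
#' @export
subtract_background <- function(profile, blank_profile) {
  if (length(profile$heights) != length(blank_profile$heights) ||
      max(abs(profile$heights - blank_profile$heights)) > 1e-9)
    stop("height grids do not match")
  profile$intensities <- pmax(profile$intensities - blank_profile$intensities, 0)
  profile
}

#' Normalize a profile to the maximum intensity in a reference window
#'
#' Dividing by the in-window maximum removes exposure (gain) variation
#' between acquisitions: scaling all intensities by k > 0 leaves the result
#' unchanged.
#'
#' @param profile An `intensity_profile`.
#' @param reference_window `c(lo, hi)` in mm; default: the central 60% of
#'   the profile's height span.
#' @param norm_value Optional fixed normalization constant overriding the
#'   in-window maximum (used to compare profiles under one exposure scale).
#' @return A normalized `intensity_profile`.
#' @export
normalize_profile <- function(profile, reference_window = NULL,
                              norm_value = NULL) {
  h <- profile$heights
  if (is.null(reference_window)) {
    span <- range(h)
    reference_window <- span[1] + c(0.2, 0.8) * diff(span)
  }
  inwin <- h >= reference_window[1] & h <= reference_window[2]
  if (!any(inwin)) stop("reference window does not overlap the profile")
  m <- if (is.null(norm_value)) max(profile$intensities[inwin]) else norm_value
  if (!is.finite(m) || m <= 0)
    stop("degenerate profile: no signal in the reference window")
  profile$intensities <- profile$intensities / m
  profile$normalized <- TRUE
  profile
}

# Shared processing chain: profile -> background subtraction -> normalization.
.processed_profile <- function(series, index, params) {
  p <- .profile_of_frame(series, index)
  blank <- params$blank_profile %||% series_blank(series)
  p <- subtract_background(p, blank)
  normalize_profile(p, params$reference_window, params$norm_value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Starting position fingerprint
#'
#' Summarizes the sample band of the first processed frame. The default
#' estimator is the intensity-weighted centroid of the background-subtracted,
#' normalized first-frame profile (a peak estimator is available), reported
#' in mm from the ROI bottom.
#'
#' @param series A [frame_series()].
#' @param params List of options: `blank_profile` (an `intensity_profile`;
#'   default [series_blank()]), `reference_window`, `norm_value`,
#'   `method` (`"centroid"` or `"peak"`).
#' @return Starting position in millimetres.
#' @export
starting_position <- function(series, params = list()) {
  p <- .processed_profile(series, 1, params)
  tot <- sum(p$intensities)
  if (tot <= 0) stop("degenerate first frame: all-zero processed profile")
  method <- params$method %||% "centroid"
  switch(method,
         centroid = sum(p$heights * p$intensities) / tot,
         peak = p$heights[which.max(p$intensities)],
         stop("unknown starting-position method: ", method))
}

.trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Levitating fraction area fingerprint
#'
#' Trapezoidal integral of the normalized intensity profile at the longest
#' acquisition time (default 20 min), over heights above a sediment
#' exclusion cut (default: the bottom 10% of the ROI height, so that the
#' precipitated pellet does not count as levitating signal).
#'
#' @param series A [frame_series()].
#' @param params Options as in [starting_position()], plus
#'   `sediment_exclusion_mm` and `final_time` (seconds, default 1200).
#' @return Dimensionless area (normalized intensity x mm).
#' @export
levitating_fraction_area <- function(series, params = list()) {
  final_time <- params$final_time %||% 1200
  k <- which.min(abs(series$times - final_time))
  gap <- abs(series$times[k] - final_time)
  if (length(series$times) > 1 && gap > stats::median(diff(series$times)))
    warning(sprintf("no frame at t = %g s; using nearest frame at t = %g s",
                    final_time, series$times[k]))
  p <- .processed_profile(series, k, params)
  cut <- params$sediment_exclusion_mm %||% (0.1 * max(p$heights))
  keep <- p$heights >= cut
  if (sum(keep) < 2) return(0)
  .trapz(p$heights[keep], p$intensities[keep])
}

#' Extract the MagLev fingerprint of a series
#'
#' Runs the full chain (profile, background subtraction, normalization, the
#' two features) and records the parameters used.
#'
#' @param series A [frame_series()].
#' @param params See [starting_position()] and [levitating_fraction_area()].
#' @param donor_id,replicate_id Identifiers carried into the result.
#' @return Object of class `maglev_fingerprint` with fields
#'   `starting_position_mm`, `levitating_area`, `donor_id`, `replicate_id`,
#'   `params`.
#' @export
extract_fingerprint <- function(series, params = list(),
                                donor_id = NA_character_,
                                replicate_id = NA_integer_) {
  structure(list(starting_position_mm = starting_position(series, params),
                 levitating_area = levitating_fraction_area(series, params),
                 donor_id = donor_id, replicate_id = replicate_id,
                 params = params[setdiff(names(params), "blank_profile")]),
            class = "maglev_fingerprint")
}

#' @export
print.maglev_fingerprint <- function(x, ...) {
  cat(sprintf("MagLev fingerprint [%s/%s]: start %.3f mm, area %.4f\n",
              x$donor_id, x$replicate_id, x$starting_position_mm,
              x$levitating_area))
  invisible(x)
}

#' Average fingerprint over replicates of one donor
#'
#' Component-wise arithmetic mean; errors if the replicates belong to
#' different donors.
#'
#' @param fingerprints List of `maglev_fingerprint`s of a single donor.
#' @return A `maglev_fingerprint` with `replicate_id = NA` and an
#'   `n_replicates` field.
#' @export
average_replicates <- function(fingerprints) {
  stopifnot(length(fingerprints) >= 1)
  donors <- unique(vapply(fingerprints, `[[`, character(1), "donor_id"))
  if (length(donors) > 1)
    stop("replicates from different donors: ", paste(donors, collapse = ", "))
  structure(list(
    starting_position_mm = mean(vapply(fingerprints, `[[`, numeric(1),
                                       "starting_position_mm")),
    levitating_area = mean(vapply(fingerprints, `[[`, numeric(1),
                                  "levitating_area")),
    donor_id = donors, replicate_id = NA_integer_,
    n_replicates = length(fingerprints),
    params = fingerprints[[1]]$params),
    class = "maglev_fingerprint")
}
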