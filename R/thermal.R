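# Facial thermal-imaging features over 22 tracked regions.
#
# Features follow the first-vs-last 120-s segment design: per-region
# segment means, absolute changes, changes referenced to the forehead (the
# most temperature-stable facial area, so common drift cancels), and the
# full pairwise differential matrix.

#' The 22 thermal regions of interest
#'
#' Region ids, anatomical group and description for the facial thermal
#' regions the pipeline consumes (eyebrows, forehead, nose, nostrils, lips,
#' cheeks, chin, throat; periorbital areas are excluded because eyeglasses
#' block them).
#'
#' @return data frame with columns `roi_id`, `group`, `description`.
#' @export
thermal_rois <- function() {
  data.frame(
    roi_id = c(18L, 21L, 22L, 25L, 58L, 28L, 29L, 30L, 32L, 34L,
               48L, 49L, 50L, 51L, 52L, 53L,
               54L, 55L, 56L, 57L, 59L, 60L),
    group = c(rep("eyebrow", 4L), "forehead", rep("nose", 3L),
              rep("nostril", 2L), rep("lip", 6L), rep("cheek", 4L),
              "chin", "throat"),
    description = c(
      "left side of left eyebrow", "right side of left eyebrow",
      "left side of right eyebrow", "right side of right eyebrow",
      "forehead",
      "upper part of the nose", "middle part of the nose", "nose tip",
      "left nostril", "right nostril",
      "left side of lip", "outside of upper lip", "right side of lip",
      "outside of lower lip", "upper lip", "lower lip",
      "left cheek away from nose", "left cheek closer to nose",
      "right cheek away from nose", "right cheek closer to nose",
      "chin", "throat"),
    stringsAsFactors = FALSE
  )
}

FOREHEAD_ROI <- 58L

#' Thermal trace set constructor
#'
#' @param traces data frame with columns `time_s`, `roi_id`, `temp_c`;
#'   `roi_id` must come from the 22-region set of [thermal_rois()] and
#'   temperatures must lie in 20-45 degrees C. Missing frames are simply
#'   absent rows.
#' @param fps nominal thermal frame rate, Hz (used for coverage checks).
#' @param duration_s nominal recording length; defaults to the last
#'   timestamp plus one frame.
#' @return object of class `thermal_trace_set`.
#' @export
thermal_trace_set <- function(traces, fps, duration_s = NULL) {
  need <- c("time_s", "roi_id", "temp_c")
  if (!all(need %in% names(traces)))
    pt_validation_error(paste("thermal data needs columns:", paste(need, collapse = ", ")))
  bad <- setdiff(unique(traces$roi_id), thermal_rois()$roi_id)
  if (length(bad))
    pt_validation_error(paste("unknown thermal roi_id:", paste(bad, collapse = ", ")))
  if (any(!is.finite(traces$temp_c)) ||
      any(traces$temp_c < 20 | traces$temp_c > 45))
    pt_validation_error("temperatures must be finite and within [20, 45] degrees C")
  if (is.null(duration_s)) duration_s <- max(traces$time_s) + 1 / fps
  structure(list(traces = traces[order(traces$roi_id, traces$time_s), , drop = FALSE],
                 fps = fps, duration_s = duration_s),
            class = "thermal_trace_set")
}

#' @export
print.thermal_trace_set <- function(x, ...) {
  cat(sprintf("<thermal_trace_set> %d ROIs, %d frames @ %g fps (%.1f s)\n",
              length(unique(x$traces$roi_id)), nrow(x$traces), x$fps,
              x$duration_s))
  invisible(x)
}

#' First- and last-segment temperature means per region
#'
#' Mean temperature of the available frames in the first and the last
#' `segment_s` seconds of the recording. A window with fewer than
#' `min_coverage` of its expected frames (given the nominal frame rate) is
#' reported missing; a region missing both windows is dropped with a
#' warning.
#'
#' @param traces a [thermal_trace_set()] of at least `2 * segment_s`
#'   seconds.
#' @param segment_s segment length, seconds (default 120).
#' @param min_coverage minimum fraction of expected frames for a valid
#'   window (default 0.5).
#' @return data frame `roi_id`, `mean_first_c`, `mean_last_c`.
#' @export
segment_means <- function(traces, segment_s = 120, min_coverage = 0.5) {
  stopifnot(inherits(traces, "thermal_trace_set"))
  T <- traces$duration_s
  if (T < 2 * segment_s)
    pt_validation_error(sprintf("recording (%.1f s) shorter than two %g-s segments", T, segment_s))
  expected <- segment_s * traces$fps
  ids <- unique(traces$traces$roi_id)
  win_mean <- function(tr, lo, hi) {
    sel <- tr$time_s >= lo & tr$time_s < hi
    if (sum(sel) < min_coverage * expected) NA_real_ else mean(tr$temp_c[sel])
  }
  rows <- lapply(ids, function(id) {
    tr <- traces$traces[traces$traces$roi_id == id, , drop = FALSE]
    data.frame(roi_id = id,
               mean_first_c = win_mean(tr, 0, segment_s),
               mean_last_c = win_mean(tr, T - segment_s, T + 1e-9))
  })
  out <- do.call(rbind, rows)
  both_na <- is.na(out$mean_first_c) & is.na(out$mean_last_c)
  if (any(both_na)) {
    warning(sprintf("dropping ROI(s) with no valid window: %s",
                    paste(out$roi_id[both_na], collapse = ", ")))
    out <- out[!both_na, , drop = FALSE]
  }
  out
}

#' Absolute segment temperature changes
#'
#' Last-segment mean minus first-segment mean per region; missing means
#' propagate.
#'
#' @param means data frame from [segment_means()].
#' @return named numeric vector of changes in degrees C, names = roi_id.
#' @export
absolute_changes <- function(means) {
  stats::setNames(means$mean_last_c - means$mean_first_c,
                  as.character(means$roi_id))
}

#' Pairwise differential change matrix
#'
#' `M[i, j] = change_j - change_i` (the row region is subtracted from the
#' column region), so the matrix is antisymmetric with a zero diagonal.
#' Regions with missing changes give missing rows and columns.
#'
#' @param abs_changes named vector from [absolute_changes()] (>= 2
#'   regions).
#' @return square numeric matrix with roi_id dimnames.
#' @export
differential_matrix <- function(abs_changes) {
  if (length(abs_changes) < 2L)
    pt_validation_error("need changes for at least 2 regions")
  outer(abs_changes, abs_changes, function(i, j) j - i)
}

#' Forehead-referenced temperature changes
#'
#' Each region's change minus the forehead's change. The forehead is the
#' most temperature-stable facial area, so subtracting it cancels drift
#' common to the whole face; the forehead's own referenced change is 0.
#'
#' @param abs_changes named vector from [absolute_changes()].
#' @param ref_roi reference region id (default 58, the forehead).
#' @return named numeric vector of referenced changes, degrees C.
#' @export
forehead_referenced <- function(abs_changes, ref_roi = FOREHEAD_ROI) {
  key <- as.character(ref_roi)
  if (!key %in% names(abs_changes) || is.na(abs_changes[[key]]))
    pt_stop(sprintf("reference ROI %s has no valid change", key))
  abs_changes - abs_changes[[key]]
}

#' All thermal features of a recording
#'
#' Convenience wrapper running [segment_means()], [absolute_changes()],
#' [forehead_referenced()] and [differential_matrix()].
#'
#' @inheritParams segment_means
#' @param ref_roi reference region for referenced changes.
#' @return list of class `thermal_features`: `means`, `abs_change_c`,
#'   `ref_change_c`, `diff_matrix`.
#' @export
thermal_features <- function(traces, segment_s = 120, min_coverage = 0.5,
                             ref_roi = FOREHEAD_ROI) {
  means <- segment_means(traces, segment_s, min_coverage)
  ch <- absolute_changes(means)
  structure(list(means = means,
                 abs_change_c = ch,
                 ref_change_c = forehead_referenced(ch, ref_roi),
                 diff_matrix = differential_matrix(ch)),
            class = "thermal_features")
}

#' @export
print.thermal_features <- function(x, ...) {
  cat(sprintf("<thermal_features> %d ROIs; abs change range [%.2f, %.2f] degC\n",
              length(x$abs_change_c),
              min(x$abs_change_c, na.rm = TRUE),
              max(x$abs_change_c, na.rm = TRUE)))
  invisible(x)
}
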