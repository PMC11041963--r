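# Pulse extraction from multi-ROI facial RGB traces.
#
# The POS (plane-orthogonal-to-skin) projection turns temporally normalised
# RGB into a blood-volume-pulse waveform; overlapping 6-s Fourier windows
# then give a heart-rate series per region, the per-window median across
# regions gives the aggregate, and the MAE/HR index quantifies how much the
# regions disagree (large disagreement flags corrupted extractions).

#' Multi-ROI RGB trace set constructor
#'
#' @param traces data frame with columns `time_s`, `roi_id`, `R`, `G`, `B`;
#'   equal-length, strictly positive channel series per region.
#' @param fps frame rate in Hz.
#' @return object of class `roi_trace_set`.
#' @export
roi_trace_set <- function(traces, fps) {
  need <- c("time_s", "roi_id", "R", "G", "B")
  if (!all(need %in% names(traces)))
    pt_validation_error(paste("trace data needs columns:", paste(need, collapse = ", ")))
  assert_scalar_num(fps, "fps", lower = 1)
  vals <- as.matrix(traces[c("R", "G", "B")])
  if (any(!is.finite(vals)) || any(vals <= 0))
    pt_validation_error("channel intensities must be finite and > 0")
  lens <- table(traces$roi_id)
  if (length(lens) < 1L) pt_validation_error("at least one ROI required")
  if (length(unique(as.integer(lens))) != 1L)
    pt_validation_error("all ROIs must have equal-length channel series")
  structure(list(traces = traces[order(traces$roi_id, traces$time_s), , drop = FALSE],
                 fps = fps),
            class = "roi_trace_set")
}

#' @export
print.roi_trace_set <- function(x, ...) {
  n_roi <- length(unique(x$traces$roi_id))
  n <- nrow(x$traces) / n_roi
  cat(sprintf("<roi_trace_set> %d ROIs x %d frames @ %g fps (%.1f s)\n",
              n_roi, n, x$fps, n / x$fps))
  invisible(x)
}

#' POS pulse extraction
#'
#' For every sliding window of `pos_window_s` seconds (hop of one sample),
#' each channel is divided by its window mean (temporal normalisation, which
#' cancels per-channel gain), projected with the fixed POS matrix rows
#' (0, 1, -1) and (-2, 1, 1) to signals S1 and S2, combined as
#' `h = S1 + (sigma(S1)/sigma(S2)) * S2` with population standard
#' deviations, mean-centred, and overlap-added into the output. A window
#' with `sigma(S2) = 0` (e.g. constant input) contributes S1 alone.
#'
#' @param traces a [roi_trace_set()].
#' @param pos_window_s normalisation window length in seconds (default
#'   1.6 s, the convention of the method's original formulation).
#' @return list of `bvp_signal` objects (fields `roi_id`, `samples`,
#'   `time_s`, `fps`), one per region, each the length of its input trace.
#' @export
pos_bvp <- function(traces, pos_window_s = 1.6) {
  stopifnot(inherits(traces, "roi_trace_set"))
  fps <- traces$fps
  l <- max(2L, round(pos_window_s * fps))
  ids <- unique(traces$traces$roi_id)
  lapply(ids, function(id) {
    tr <- traces$traces[traces$traces$roi_id == id, , drop = FALSE]
    n <- nrow(tr)
    if (n < l) pt_validation_error(sprintf("ROI %s shorter than one POS window", id))
    h <- pos_core(tr$R, tr$G, tr$B, l)
    structure(list(roi_id = id, samples = h, time_s = tr$time_s, fps = fps),
              class = "bvp_signal")
  })
}

# Sliding-window POS with hop 1 and overlap-add, vectorised over windows.
pos_core <- function(R, G, B, l) {
  n <- length(R)
  W <- n - l + 1L
  idx <- outer(seq_len(l), seq_len(W) - 1L, `+`)   # l x W window indices
  Rm <- matrix(R[idx], l, W)
  Gm <- matrix(G[idx], l, W)
  Bm <- matrix(B[idx], l, W)
  Rn <- sweep(Rm, 2L, colMeans(Rm), `/`)
  Gn <- sweep(Gm, 2L, colMeans(Gm), `/`)
  Bn <- sweep(Bm, 2L, colMeans(Bm), `/`)
  S1 <- Gn - Bn
  S2 <- -2 * Rn + Gn + Bn
  sd1 <- sqrt(colMeans(S1^2) - colMeans(S1)^2)
  sd2 <- sqrt(colMeans(S2^2) - colMeans(S2)^2)
  ratio <- ifelse(sd2 > 0, sd1 / sd2, 0)
  H <- S1 + sweep(S2, 2L, ratio, `*`)
  H <- sweep(H, 2L, colMeans(H), `-`)
  out <- numeric(n)
  for (w in seq_len(W)) {
    j <- w:(w + l - 1L)
    out[j] <- out[j] + H[, w]
  }
  out
}

#' Windowed spectral heart-rate estimation
#'
#' Segments the pulse waveform into overlapping windows of `win_s` seconds
#' (hop `hop_s`); in each window the mean is removed and a zero-padded
#' magnitude spectrum is computed on a grid no coarser than 0.25 BPM; the
#' heart rate is 60 times the argmax frequency within `band_hz`. An all-zero
#' window yields a missing estimate, and a window whose in-band peak is
#' dwarfed by out-of-band power is flagged low-confidence.
#'
#' @param bvp a `bvp_signal` from [pos_bvp()].
#' @param win_s window length, seconds (default 6).
#' @param hop_s hop between window centres, seconds (default 1).
#' @param band_hz physiologic search band in Hz (default 0.65-4.0, i.e.
#'   39-240 BPM).
#' @return an [hr_series()] with one row per window (`t_center_s`,
#'   `hr_bpm`, `low_confidence`).
#' @export
windowed_hr <- function(bvp, win_s = 6, hop_s = 1, band_hz = c(0.65, 4.0)) {
  stopifnot(inherits(bvp, "bvp_signal"))
  fps <- bvp$fps
  x <- bvp$samples
  wlen <- round(win_s * fps)
  if (length(x) < wlen) pt_validation_error("signal shorter than one HR window")
  hop <- max(1L, round(hop_s * fps))
  # zero-pad so the frequency grid is at most 0.25 BPM
  nfft <- 2^ceiling(log2(fps / (0.25 / 60)))
  freq <- (seq_len(nfft %/% 2L + 1L) - 1L) * fps / nfft
  in_band <- freq >= band_hz[1L] & freq <= band_hz[2L]
  if (!any(in_band)) pt_validation_error("empty HR search band")

  starts <- seq(1L, length(x) - wlen + 1L, by = hop)
  t0 <- bvp$time_s[1L]
  centers <- t0 + (starts - 1L) / fps + win_s / 2
  hr <- rep(NA_real_, length(starts))
  lowconf <- rep(FALSE, length(starts))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + wlen - 1L)]
    seg <- seg - mean(seg)
    if (all(seg == 0)) next
    mag <- abs(stats::fft(c(seg, numeric(nfft - wlen)))[seq_along(freq)])
    pk <- which.max(mag[in_band])
    hr[i] <- 60 * freq[in_band][pk]
    lowconf[i] <- mag[in_band][pk] < 0.5 * max(mag[-1L])  # ignore DC
  }
  hr_series(t_center_s = centers, hr_bpm = hr, win_s = win_s, hop_s = hop_s,
            roi_id = bvp$roi_id, low_confidence = lowconf)
}

#' Heart-rate series constructor
#'
#' @param t_center_s strictly increasing window-centre times, seconds.
#' @param hr_bpm heart-rate estimates (NA = missing window).
#' @param win_s,hop_s window length and hop, seconds.
#' @param roi_id region id, or NULL for an aggregate series.
#' @param low_confidence optional logical flags per window.
#' @return data frame of class `hr_series` with attributes `win_s`,
#'   `hop_s`, `roi_id`.
#' @export
hr_series <- function(t_center_s, hr_bpm, win_s = 6, hop_s = 1,
                      roi_id = NULL, low_confidence = NULL) {
  if (length(t_center_s) != length(hr_bpm))
    pt_validation_error("t_center_s and hr_bpm must have equal length")
  if (is.unsorted(t_center_s, strictly = TRUE))
    pt_validation_error("window centres must be strictly increasing")
  df <- data.frame(t_center_s = as.numeric(t_center_s),
                   hr_bpm = as.numeric(hr_bpm))
  if (!is.null(low_confidence)) df$low_confidence <- low_confidence
  structure(df, win_s = win_s, hop_s = hop_s, roi_id = roi_id,
            class = c("hr_series", "data.frame"))
}

#' @export
print.hr_series <- function(x, ...) {
  id <- attr(x, "roi_id")
  cat(sprintf("<hr_series%s> %d windows (win %gs, hop %gs); mean HR %.1f BPM, %d missing\n",
              if (is.null(id)) " aggregate" else paste0(" ROI ", id),
              nrow(x), attr(x, "win_s"), attr(x, "hop_s"),
              mean(x$hr_bpm, na.rm = TRUE), sum(is.na(x$hr_bpm))))
  invisible(x)
}

#' Aggregate per-ROI heart-rate series
#'
#' Per-window median across regions, excluding missing values; robust to
#' the outlier patches the quality index is designed to flag. All series
#' must share a window grid.
#'
#' @param per_roi list of [hr_series()] on a common window grid.
#' @return aggregate [hr_series()] (no `roi_id`).
#' @export
aggregate_hr <- function(per_roi) {
  if (!length(per_roi)) pt_validation_error("no HR series to aggregate")
  grid <- per_roi[[1L]]$t_center_s
  for (s in per_roi) {
    if (length(s$t_center_s) != length(grid) ||
        any(abs(s$t_center_s - grid) > 1e-9))
      pt_validation_error("per-ROI HR series must share a window grid")
  }
  m <- vapply(per_roi, function(s) s$hr_bpm, numeric(length(grid)))
  m <- matrix(m, nrow = length(grid))
  agg <- apply(m, 1L, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else stats::median(v)
  })
  hr_series(grid, agg, win_s = attr(per_roi[[1L]], "win_s"),
            hop_s = attr(per_roi[[1L]], "hop_s"), roi_id = NULL)
}

#' MAE/HR signal-quality index
#'
#' Mean absolute deviation of per-region window heart rates from the
#' aggregate, divided by the mean aggregate heart rate. Zero means every
#' region agrees with the aggregate in every window; large values flag
#' recordings whose extraction should not be trusted.
#'
#' @param per_roi list of [hr_series()] on a common window grid.
#' @param aggregate aggregate [hr_series()] on the same grid.
#' @return list of class `quality_index` with `mae_over_hr`, `mae_bpm`,
#'   `n_rois`, `n_windows`, `n_pairs`.
#' @export
quality_mae_over_hr <- function(per_roi, aggregate) {
  grid <- aggregate$t_center_s
  abs_err <- c()
  n_windows <- 0L
  for (s in per_roi) {
    if (length(s$t_center_s) != length(grid) ||
        any(abs(s$t_center_s - grid) > 1e-9))
      pt_validation_error("per-ROI and aggregate HR series must share a window grid")
    ok <- !is.na(s$hr_bpm) & !is.na(aggregate$hr_bpm)
    abs_err <- c(abs_err, abs(s$hr_bpm[ok] - aggregate$hr_bpm[ok]))
  }
  if (!length(abs_err)) pt_stop("no valid (ROI, window) pairs for the quality index")
  mean_hr <- mean(aggregate$hr_bpm, na.rm = TRUE)
  structure(list(mae_over_hr = mean(abs_err) / mean_hr,
                 mae_bpm = mean(abs_err),
                 n_rois = length(per_roi),
                 n_windows = sum(!is.na(aggregate$hr_bpm)),
                 n_pairs = length(abs_err)),
            class = "quality_index")
}

#' @export
print.quality_index <- function(x, ...) {
  cat(sprintf("<quality_index> MAE/HR = %.4f (MAE %.2f BPM; %d ROIs, %d windows)\n",
              x$mae_over_hr, x$mae_bpm, x$n_rois, x$n_windows))
  invisible(x)
}
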