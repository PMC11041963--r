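# Heart-rate-variability analysis of a windowed HR series.
#
# The HR series is first cleaned with a jump filter (successive changes of
# more than 25 BPM mark an artifact; the member of the offending pair
# farther from the series median is removed), converted to NN intervals,
# and summarised per 120-s segment with the standard time-domain measures
# (SDNN, rMSSD, pNN50) and log LF/HF band powers. ULF and VLF are not
# computed: recordings of a few minutes cannot support them.

#' Remove implausible heart-rate jumps
#'
#' Scans left to right; wherever successive estimates differ by more than
#' `max_jump_bpm`, the member of the pair farther from the median of the
#' full input series is deleted (ties delete the current point). Passes
#' repeat until no violation remains, so the result is idempotent and a
#' subsequence of the input with timestamps preserved.
#'
#' @param hr an [hr_series()] with at least 2 points.
#' @param max_jump_bpm maximum allowed successive change (default 25 BPM).
#' @return filtered [hr_series()].
#' @examples
#' h <- hr_series(1:4, c(70, 72, 110, 71))
#' filter_hr_jumps(h)$hr_bpm  # 70 72 71
#' @export
filter_hr_jumps <- function(hr, max_jump_bpm = 25) {
  stopifnot(inherits(hr, "hr_series"))
  keep <- !is.na(hr$hr_bpm)
  t <- hr$t_center_s[keep]
  v <- hr$hr_bpm[keep]
  if (length(v) < 2L) pt_validation_error("need at least 2 HR points to filter")
  med <- stats::median(v)  # median of the full input series, fixed
  repeat {
    changed <- FALSE
    i <- 2L
    while (i <= length(v)) {
      if (abs(v[i] - v[i - 1L]) > max_jump_bpm) {
        drop <- if (abs(v[i] - med) >= abs(v[i - 1L] - med)) i else i - 1L
        v <- v[-drop]
        t <- t[-drop]
        changed <- TRUE
        i <- max(2L, drop)
      } else {
        i <- i + 1L
      }
    }
    if (!changed) break
  }
  if (length(v) < 1L) pt_stop("jump filter removed every point; segment unusable")
  hr_series(t, v, win_s = attr(hr, "win_s"), hop_s = attr(hr, "hop_s"),
            roi_id = attr(hr, "roi_id"))
}

#' NN interval series constructor
#'
#' @param nn_ms inter-beat intervals in milliseconds, all within `bounds`.
#' @param time_s timestamp carried by each interval, seconds.
#' @param bounds allowed NN range in ms.
#' @return data frame of class `nn_series`.
#' @export
nn_series <- function(nn_ms, time_s, bounds = c(300, 2000)) {
  if (length(nn_ms) < 2L) pt_validation_error("an NN series needs at least 2 intervals")
  if (any(nn_ms < bounds[1L] | nn_ms > bounds[2L]))
    pt_validation_error(sprintf("NN intervals outside [%g, %g] ms", bounds[1L], bounds[2L]))
  structure(data.frame(time_s = as.numeric(time_s), nn_ms = as.numeric(nn_ms)),
            class = c("nn_series", "data.frame"))
}

#' Convert a heart-rate series to NN intervals
#'
#' `nn_ms = 60000 / hr_bpm`, carried at the window timestamps. Values
#' falling outside `bounds` after conversion are treated as artifacts and
#' dropped (the count is reported via a message).
#'
#' @param hr a filtered [hr_series()].
#' @param bounds NN plausibility bounds in ms (default 300-2000, mirroring
#'   the HR search band).
#' @return an [nn_series()].
#' @export
hr_to_nn <- function(hr, bounds = c(300, 2000)) {
  stopifnot(inherits(hr, "hr_series"))
  ok <- !is.na(hr$hr_bpm)
  nn <- 60000 / hr$hr_bpm[ok]
  t <- hr$t_center_s[ok]
  inb <- nn >= bounds[1L] & nn <= bounds[2L]
  if (any(!inb))
    message(sprintf("hr_to_nn: dropped %d interval(s) outside [%g, %g] ms",
                    sum(!inb), bounds[1L], bounds[2L]))
  if (sum(inb) < 2L) pt_stop("fewer than 2 NN intervals survive conversion")
  nn_series(nn[inb], t[inb], bounds = bounds)
}

#' Time-domain HRV measures
#'
#' SDNN is the sample standard deviation (n-1 denominator) of the NN
#' intervals; rMSSD the root mean square of successive differences; pNN50
#' the percentage of successive differences strictly larger than 50 ms.
#' With fewer than 3 intervals rMSSD and pNN50 are undefined (NA) while
#' SDNN is still returned for n >= 2.
#'
#' @param nn an [nn_series()].
#' @return named list `sdnn_ms`, `rmssd_ms`, `pnn50_pct`.
#' @examples
#' time_domain(nn_series(c(800, 850, 800), 1:3))
#' @export
time_domain <- function(nn) {
  stopifnot(inherits(nn, "nn_series"))
  x <- nn$nn_ms
  n <- length(x)
  sdnn <- stats::sd(x)
  if (n < 3L) return(list(sdnn_ms = sdnn, rmssd_ms = NA_real_, pnn50_pct = NA_real_))
  d <- diff(x)
  list(sdnn_ms = sdnn,
       rmssd_ms = sqrt(mean(d^2)),
       pnn50_pct = 100 * sum(abs(d) > 50) / length(d))
}

#' Frequency-domain HRV measures
#'
#' The NN tachogram is resampled evenly at 4 Hz by cubic spline
#' interpolation, mean-removed, and its Welch power spectral density
#' integrated over the LF (0.04-0.15 Hz) and HF (0.15-0.40 Hz) bands, in
#' ms^2; natural logs are returned. A band with numerically non-positive
#' power yields NA with a warning.
#'
#' @param nn an [nn_series()] spanning at least `min_span_s` seconds.
#' @param resample_hz tachogram resampling rate (default 4 Hz).
#' @param welch_seg_s Welch segment length, seconds (default 64, 50%
#'   overlap).
#' @param min_span_s minimum tachogram span, seconds (default 100; a 120-s
#'   analysis segment's HR windows span slightly less than 120 s).
#' @return named list `ln_lf`, `ln_hf`, plus raw `lf_ms2`, `hf_ms2`.
#' @export
freq_domain <- function(nn, resample_hz = 4, welch_seg_s = 64,
                        min_span_s = 100) {
  stopifnot(inherits(nn, "nn_series"))
  span <- diff(range(nn$time_s))
  if (span < min_span_s)
    pt_validation_error(sprintf("NN coverage %.1f s below the %g s minimum", span, min_span_s))
  grid <- seq(min(nn$time_s), max(nn$time_s), by = 1 / resample_hz)
  x <- stats::spline(nn$time_s, nn$nn_ms, xout = grid, method = "fmm")$y
  x <- x - mean(x)
  w <- welch_psd(x, fs = resample_hz, nperseg = round(welch_seg_s * resample_hz))
  lf <- band_power(w, 0.04, 0.15)
  hf <- band_power(w, 0.15, 0.40)
  out <- list(ln_lf = NA_real_, ln_hf = NA_real_, lf_ms2 = lf, hf_ms2 = hf)
  if (lf > 0) out$ln_lf <- log(lf) else warning("non-positive LF power; ln_lf missing")
  if (hf > 0) out$ln_hf <- log(hf) else warning("non-positive HF power; ln_hf missing")
  out
}

#' Per-segment HRV measures and first-to-last changes
#'
#' Applies the jump filter, splits the recording into non-overlapping
#' `segment_s`-second segments (the last segment is the final `segment_s`
#' seconds), converts each to NN intervals and computes the heart-rate mean
#' plus all time- and frequency-domain measures; the deltas are last minus
#' first segment per measure.
#'
#' @param hr an [hr_series()] covering at least two full segments.
#' @param segment_s segment length, seconds (default 120).
#' @param nn_bounds NN plausibility bounds in ms.
#' @return list of class `segment_measures`: `segments` (data frame, one
#'   row per segment) and `changes` (data frame `measure`, `first`,
#'   `last`, `delta`).
#' @export
segment_measures <- function(hr, segment_s = 120, nn_bounds = c(300, 2000)) {
  stopifnot(inherits(hr, "hr_series"))
  win_s <- attr(hr, "win_s")
  t_end <- max(hr$t_center_s) + win_s / 2
  if (t_end < 2 * segment_s)
    pt_validation_error(sprintf(
      "recording (%.1f s) shorter than two %g-s segments", t_end, segment_s))
  hf <- filter_hr_jumps(hr)
  n_seg <- floor(t_end / segment_s)
  measure_names <- c("hr_mean_bpm", "sdnn_ms", "rmssd_ms", "pnn50_pct",
                     "ln_lf", "ln_hf")
  one_segment <- function(lo, hi) {
    sel <- hf$t_center_s >= lo & hf$t_center_s < hi
    out <- stats::setNames(as.list(rep(NA_real_, 6L)), measure_names)
    sub <- hf[sel, , drop = FALSE]
    if (nrow(sub) < 2L) return(out)
    nn <- tryCatch(
      hr_to_nn(hr_series(sub$t_center_s, sub$hr_bpm,
                         win_s = win_s, hop_s = attr(hr, "hop_s")),
               bounds = nn_bounds),
      pulsetherm_error = function(e) NULL)
    if (is.null(nn)) return(out)
    out$hr_mean_bpm <- mean(60000 / nn$nn_ms)
    td <- time_domain(nn)
    out[c("sdnn_ms", "rmssd_ms", "pnn50_pct")] <- td
    fd <- tryCatch(freq_domain(nn), pulsetherm_error = function(e) NULL,
                   warning = function(w) NULL)
    if (!is.null(fd)) out[c("ln_lf", "ln_hf")] <- fd[c("ln_lf", "ln_hf")]
    out
  }
  segs <- vector("list", n_seg)
  for (k in seq_len(n_seg)) {
    if (k < n_seg) {
      lo <- (k - 1) * segment_s; hi <- k * segment_s
    } else {
      lo <- t_end - segment_s; hi <- t_end + 1e-9  # last full window of time
    }
    segs[[k]] <- data.frame(segment = k, t_start_s = lo,
                            as.data.frame(one_segment(lo, hi)))
  }
  segments <- do.call(rbind, segs)
  first <- unlist(segments[1L, measure_names])
  last <- unlist(segments[n_seg, measure_names])
  changes <- data.frame(measure = measure_names,
                        first = as.numeric(first),
                        last = as.numeric(last),
                        delta = as.numeric(last - first),
                        row.names = NULL)
  structure(list(segments = segments, changes = changes, segment_s = segment_s),
            class = "segment_measures")
}

#' @export
print.segment_measures <- function(x, ...) {
  cat(sprintf("<segment_measures> %d segments of %g s\n",
              nrow(x$segments), x$segment_s))
  print(x$changes, digits = 4)
  invisible(x)
}
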