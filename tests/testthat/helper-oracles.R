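# Independent oracles and small fixture builders used across tests.

# Direct-formula HRV oracle, written with explicit loops so it shares no
# code path with the package implementation.
hrv_oracle <- function(nn_ms) {
  n <- length(nn_ms)
  m <- sum(nn_ms) / n
  ss <- 0
  for (v in nn_ms) ss <- ss + (v - m)^2
  sdnn <- sqrt(ss / (n - 1))
  sq <- 0
  big <- 0
  for (i in 2:n) {
    d <- nn_ms[i] - nn_ms[i - 1]
    sq <- sq + d^2
    if (abs(d) > 50) big <- big + 1
  }
  list(sdnn = sdnn,
       rmssd = sqrt(sq / (n - 1)),
       pnn50 = 100 * big / (n - 1))
}

# Periodogram argmax oracle via stats::spec.pgram (independent of the
# package's FFT code).
dominant_freq <- function(x, fs) {
  s <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                         detrend = TRUE, plot = FALSE)
  s$freq[which.max(s$spec)]
}

nn_from_beats <- function(b) {
  nn_series(1000 * diff(b$beat_times), b$beat_times[-1])
}

# A minimal constant-channel trace set.
constant_traces <- function(n = 200L, fps = 30, n_rois = 1L,
                            rgb = c(120, 100, 80)) {
  t <- (seq_len(n) - 1L) / fps
  df <- do.call(rbind, lapply(seq_len(n_rois), function(k)
    data.frame(time_s = t, roi_id = k, R = rgb[1], G = rgb[2], B = rgb[3])))
  roi_trace_set(df, fps = fps)
}

# Full r-PPG quality chain: traces -> POS -> windowed HR -> MAE/HR index.
with_hr_quality <- function(traces) {
  per_roi <- lapply(pos_bvp(traces), windowed_hr)
  quality_mae_over_hr(per_roi, aggregate_hr(per_roi))$mae_over_hr
}

# A bvp_signal wrapper for synthetic waveforms (mirrors pos_bvp output).
make_bvp <- function(samples, fps, roi_id = 1L) {
  structure(list(roi_id = roi_id, samples = samples,
                 time_s = (seq_along(samples) - 1L) / fps, fps = fps),
            class = "bvp_signal")
}
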