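#' Welch power spectral density estimate
#'
#' Averaged modified periodograms: the series is split into Hann-windowed
#' segments of `nperseg` samples with `noverlap` samples of overlap, each
#' segment is mean-removed, windowed and Fourier-transformed, and the
#' one-sided periodograms are averaged. Normalisation is such that the
#' integral of the PSD over frequency equals the variance of the signal
#' (density scaling), so band integrals carry the signal's units squared.
#'
#' @param x numeric vector, evenly sampled.
#' @param fs sampling frequency in Hz.
#' @param nperseg segment length in samples; shortened to `length(x)` when
#'   the series is shorter than one segment.
#' @param noverlap overlap in samples (default 50%).
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @examples
#' x <- sin(2 * pi * 0.25 * seq(0, 100, by = 0.25))
#' w <- welch_psd(x, fs = 4, nperseg = 128)
#' w$freq[which.max(w$psd)]  # ~0.25 Hz
#' @export
welch_psd <- function(x, fs, nperseg = 256L, noverlap = NULL) {
  n <- length(x)
  if (n < 8L) pt_validation_error("welch_psd: series too short")
  nperseg <- min(as.integer(nperseg), n)
  if (is.null(noverlap)) noverlap <- nperseg %/% 2L
  step <- nperseg - as.integer(noverlap)
  if (step < 1L) pt_validation_error("welch_psd: noverlap must be < nperseg")

  # Hann window and its power normalisation
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  u <- sum(w^2)

  starts <- seq(1L, n - nperseg + 1L, by = step)
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2 / (fs * u)
    # one-sided: double everything except DC (and Nyquist for even nperseg)
    sp[-1L] <- sp[-1L] * 2
    if (nperseg %% 2L == 0L) sp[nfreq] <- sp[nfreq] / 2
    acc <- acc + sp
  }
  list(freq = (seq_len(nfreq) - 1L) * fs / nperseg,
       psd = acc / length(starts))
}

#' Integrate a PSD over a frequency band
#'
#' Rectangle-rule integral of the PSD over `[lo, hi)` (bins whose centre
#' frequency falls in the band).
#'
#' @param w list from [welch_psd()].
#' @param lo,hi band edges in Hz.
#' @return band power in signal units squared.
#' @export
band_power <- function(w, lo, hi) {
  df <- w$freq[2L] - w$freq[1L]
  sel <- w$freq >= lo & w$freq < hi
  sum(w$psd[sel]) * df
}
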