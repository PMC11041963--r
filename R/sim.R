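# Synthetic-data generators with known ground truth.
#
# Every generator is deterministic given its `seed`, and the quantities the
# downstream stages estimate (mean heart rate, LF/HF modulation power,
# segment-wise temperature effects, class separability) are programmed in
# explicitly so parameter recovery can be tested exactly.

# Modulation frequencies sit at the centres of the standard LF (0.04-0.15 Hz)
# and HF (0.15-0.40 Hz) bands so programmed power lands unambiguously in one
# band.
LF_MOD_HZ <- 0.095
HF_MOD_HZ <- 0.275

#' Beat-time series constructor
#'
#' @param beat_times strictly increasing beat times in seconds from start.
#' @param duration_s total recording length in seconds.
#' @return object of class `beat_series`.
#' @export
beat_series <- function(beat_times, duration_s) {
  if (length(beat_times) < 2L)
    pt_validation_error("a beat series needs at least 2 beats")
  d <- diff(beat_times)
  if (any(d <= 0)) pt_validation_error("beat times must be strictly increasing")
  if (any(d < 0.3 - 1e-12) || any(d > 2.0 + 1e-12))
    pt_validation_error("inter-beat intervals must lie in [0.3, 2.0] s")
  structure(list(beat_times = as.numeric(beat_times),
                 duration_s = as.numeric(duration_s)),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  nn <- diff(x$beat_times)
  cat(sprintf("<beat_series> %d beats over %.1f s; mean NN %.1f ms (HR %.1f BPM)\n",
              length(x$beat_times), x$duration_s,
              1000 * mean(nn), 60 / mean(nn)))
  invisible(x)
}

#' Generate a beat series with programmed LF/HF structure
#'
#' Builds inter-beat (NN) intervals directly as
#' `NN(t) = 60/mean_hr_bpm + lf_amp_s*sin(2*pi*0.095*t) +
#'  hf_amp_s*sin(2*pi*0.275*t) + e`, `e ~ N(0, noise_sd_s^2)`, laying beats
#' down cumulatively from time 0 until `duration_s`. The two modulation
#' frequencies are the centres of the standard LF and HF bands, so the
#' frequency-domain analysis should recover the programmed amplitude ratio.
#' Sampled intervals are clamped to the physiologic range \[0.3, 2.0\] s.
#'
#' @param duration_s recording length in seconds (>= 30).
#' @param mean_hr_bpm mean heart rate, beats per minute, in \[40, 180\].
#' @param lf_amp_s,hf_amp_s modulation amplitudes in seconds (>= 0).
#' @param noise_sd_s white-noise standard deviation on NN, seconds.
#' @param seed integer seed; same seed, same series.
#' @return a [beat_series()].
#' @examples
#' b <- generate_beat_series(60, 60, 0, 0, 0, seed = 1)
#' diff(b$beat_times)  # all exactly 1 s
#' @export
generate_beat_series <- function(duration_s, mean_hr_bpm,
                                 lf_amp_s = 0, hf_amp_s = 0,
                                 noise_sd_s = 0, seed = 1L) {
  assert_scalar_num(duration_s, "duration_s", lower = 30)
  assert_scalar_num(mean_hr_bpm, "mean_hr_bpm", lower = 40, upper = 180)
  assert_scalar_num(lf_amp_s, "lf_amp_s", lower = 0)
  assert_scalar_num(hf_amp_s, "hf_amp_s", lower = 0)
  assert_scalar_num(noise_sd_s, "noise_sd_s", lower = 0)
  base_nn <- 60 / mean_hr_bpm
  if (base_nn - lf_amp_s - hf_amp_s < 0.3)
    pt_validation_error("minimum possible NN below 0.3 s; reduce modulation amplitudes")

  withr::local_seed(derive_seed(seed, 11L))
  times <- numeric(ceiling(duration_s / 0.3) + 1L)
  t <- 0
  k <- 1L
  times[1L] <- 0
  repeat {
    nn <- base_nn +
      lf_amp_s * sin(2 * pi * LF_MOD_HZ * t) +
      hf_amp_s * sin(2 * pi * HF_MOD_HZ * t) +
      stats::rnorm(1L, 0, noise_sd_s)
    nn <- min(max(nn, 0.3), 2.0)
    t <- t + nn
    if (t >= duration_s) break
    k <- k + 1L
    times[k] <- t
  }
  beat_series(times[seq_len(k)], duration_s)
}

# Unit-peak pulse waveform: one asymmetric Gaussian per beat (fast rise,
# slow decay), widths proportional to the local NN interval.
pulse_waveform <- function(t, beat_times) {
  nn <- diff(beat_times)
  nn <- c(nn, nn[length(nn)])
  p <- numeric(length(t))
  for (k in seq_along(beat_times)) {
    tk <- beat_times[k]
    s_rise <- 0.08 * nn[k]
    s_decay <- 0.22 * nn[k]
    # restrict to a local support for speed
    sel <- which(t >= tk - 4 * s_rise & t <= tk + 4 * s_decay)
    if (!length(sel)) next
    dt <- t[sel] - tk
    sig <- ifelse(dt < 0, s_rise, s_decay)
    p[sel] <- p[sel] + exp(-dt^2 / (2 * sig^2))
  }
  pmin(p, 1)
}

#' Synthesize pulse-modulated multi-ROI RGB traces
#'
#' Emulates the mean colour intensity of tracked facial skin patches: each
#' region's channels are `baseline * (1 + alpha * p(t) + d(t) + eta(t))`
#' where `p(t)` is a unit pulse waveform (one asymmetric Gaussian per beat),
#' `alpha` is channel-weighted with green strongest (haemoglobin absorbs
#' green light most), `d(t)` a slow illumination drift common to all regions
#' and channels, and `eta` white noise. Per-region pulse amplitudes are
#' jittered by the seed; the pulse waveform itself depends only on the beat
#' series.
#'
#' @param beats a [beat_series()].
#' @param fps frame rate, Hz (>= 10).
#' @param n_rois number of regions (>= 1).
#' @param pulse_amp fractional pulse modulation of the green channel.
#' @param noise_sd fractional white-noise standard deviation.
#' @param illum_drift_amp fractional amplitude of a slow common drift.
#' @param seed integer seed.
#' @return a [roi_trace_set()].
#' @export
synthesize_rgb_traces <- function(beats, fps = 30, n_rois = 3L,
                                  pulse_amp = 0.02, noise_sd = 0.003,
                                  illum_drift_amp = 0.01, seed = 1L) {
  stopifnot(inherits(beats, "beat_series"))
  assert_scalar_num(fps, "fps", lower = 10)
  assert_scalar_num(n_rois, "n_rois", lower = 1)
  assert_scalar_num(pulse_amp, "pulse_amp", lower = 0)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  assert_scalar_num(illum_drift_amp, "illum_drift_amp", lower = 0)
  n_rois <- as.integer(n_rois)

  n <- floor(beats$duration_s * fps)
  t <- (seq_len(n) - 1L) / fps
  p <- pulse_waveform(t, beats$beat_times)

  withr::local_seed(derive_seed(seed, 23L))
  drift_phase <- stats::runif(1L, 0, 2 * pi)
  d <- illum_drift_amp * sin(2 * pi * t / 60 + drift_phase)

  # Green carries the strongest pulse, red intermediate, blue weakest.
  chan_w <- c(R = 0.55, G = 1.0, B = 0.35)
  out <- vector("list", n_rois)
  for (k in seq_len(n_rois)) {
    base <- c(R = stats::rnorm(1L, 135, 5),
              G = stats::rnorm(1L, 110, 5),
              B = stats::rnorm(1L, 90, 5))
    jit <- stats::runif(1L, 0.8, 1.2)
    ch <- lapply(names(chan_w), function(cn) {
      eta <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
      base[[cn]] * (1 + pulse_amp * chan_w[[cn]] * jit * p + d + eta)
    })
    out[[k]] <- data.frame(time_s = t, roi_id = k,
                           R = ch[[1L]], G = ch[[2L]], B = ch[[3L]])
  }
  roi_trace_set(do.call(rbind, out), fps = fps)
}

# Table-defined thermal ROI groups (see thermal_rois()).
thermal_group_names <- function() {
  c("eyebrow", "forehead", "nose", "nostril", "lip", "cheek", "chin", "throat")
}

#' Thermal effect specification
#'
#' Programs the synthetic thermal study: per-group baseline temperature,
#' per-group difference between the mean of the last and the first 120-s
#' segment, a linear drift common to all regions, AR(1) sensor noise, and a
#' fraction of randomly missing frames (emulating frames where the face was
#' not detected).
#'
#' @param baseline_c named numeric, baseline temperature per ROI group
#'   (names from `eyebrow, forehead, nose, nostril, lip, cheek, chin,
#'   throat`); unnamed scalar recycles to all groups.
#' @param effect_c named numeric, programmed last-minus-first 120-s segment
#'   difference per group, degrees C; defaults to 0 for unlisted groups.
#' @param drift_c_per_min linear drift applied to every region, degrees C
#'   per minute.
#' @param noise_sd_c marginal standard deviation of AR(1) noise, degrees C.
#' @param missing_fraction fraction of frames dropped at random, in \[0, 1).
#' @return object of class `thermal_effect_spec`.
#' @export
thermal_effect_spec <- function(baseline_c = 34, effect_c = numeric(),
                                drift_c_per_min = 0, noise_sd_c = 0,
                                missing_fraction = 0) {
  grp <- thermal_group_names()
  base <- stats::setNames(rep_len(if (is.null(names(baseline_c))) baseline_c else 34, 8L), grp)
  if (!is.null(names(baseline_c))) {
    bad <- setdiff(names(baseline_c), grp)
    if (length(bad)) pt_validation_error(paste("unknown ROI group:", paste(bad, collapse = ", ")))
    base[names(baseline_c)] <- baseline_c
  }
  eff <- stats::setNames(numeric(8L), grp)
  if (length(effect_c)) {
    if (is.null(names(effect_c))) pt_validation_error("effect_c must be named by ROI group")
    bad <- setdiff(names(effect_c), grp)
    if (length(bad)) pt_validation_error(paste("unknown ROI group:", paste(bad, collapse = ", ")))
    eff[names(effect_c)] <- effect_c
  }
  assert_scalar_num(noise_sd_c, "noise_sd_c", lower = 0)
  assert_scalar_num(missing_fraction, "missing_fraction", lower = 0, upper = 1 - 1e-9)
  structure(list(baseline_c = base, effect_c = eff,
                 drift_c_per_min = drift_c_per_min,
                 noise_sd_c = noise_sd_c,
                 missing_fraction = missing_fraction),
            class = "thermal_effect_spec")
}

#' Generate per-ROI facial temperature traces
#'
#' Each of the 22 regions receives its group baseline plus a linear ramp
#' sized so that the mean of the last 120 s minus the mean of the first
#' 120 s equals the programmed group effect, plus the common drift and AR(1)
#' noise; a `missing_fraction` of frames is then dropped at random.
#'
#' @param spec a [thermal_effect_spec()].
#' @param duration_s recording length, seconds (>= 240 so both 120-s
#'   segments fit).
#' @param fps_thermal thermal frame rate, Hz (thermal cameras are slower
#'   than RGB; default 8).
#' @param seed integer seed.
#' @return a [thermal_trace_set()].
#' @export
generate_thermal_traces <- function(spec, duration_s = 480, fps_thermal = 8,
                                    seed = 1L) {
  stopifnot(inherits(spec, "thermal_effect_spec"))
  assert_scalar_num(duration_s, "duration_s", lower = 240)
  assert_scalar_num(fps_thermal, "fps_thermal", lower = 0.5)

  rois <- thermal_rois()
  n <- floor(duration_s * fps_thermal)
  t <- (seq_len(n) - 1L) / fps_thermal
  seg <- 120
  # ramp a*t shifts the last-vs-first 120-s segment means by a*(T - seg)
  ramp_per_effect <- 1 / (duration_s - seg)
  drift <- spec$drift_c_per_min / 60

  withr::local_seed(derive_seed(seed, 37L))
  phi <- 0.6
  out <- vector("list", nrow(rois))
  for (k in seq_len(nrow(rois))) {
    g <- rois$group[k]
    temp <- spec$baseline_c[[g]] +
      (spec$effect_c[[g]] * ramp_per_effect + drift) * t
    if (spec$noise_sd_c > 0) {
      innov <- stats::rnorm(n, 0, spec$noise_sd_c * sqrt(1 - phi^2))
      temp <- temp + as.numeric(stats::filter(innov, phi, method = "recursive"))
    }
    keep <- seq_len(n)
    if (spec$missing_fraction > 0) {
      keep <- sort(sample(n, round(n * (1 - spec$missing_fraction))))
    }
    out[[k]] <- data.frame(time_s = t[keep], roi_id = rois$roi_id[k],
                           temp_c = temp[keep])
  }
  thermal_trace_set(do.call(rbind, out), fps = fps_thermal,
                    duration_s = duration_s)
}

#' Default per-condition effect profile for the synthetic study
#'
#' The stimulus state raises heart rate and lowers every HRV measure, and
#' warms condition-specific facial regions: under sustained cognitive load
#' the lips and cheeks warm; under moral elevation the nose, nostrils, lips,
#' cheeks and chin warm more diffusely. Magnitudes are on the order of the
#' within-record noise so neither modality is trivially separable.
#'
#' @param condition `"stress"` or `"elevation"`.
#' @return list with `rppg_shift`, `thermal_shift`, `rppg_noise_sd`,
#'   `thermal_noise_sd`, `rppg_subject_sd`, `thermal_subject_sd`.
#' @export
default_effect_profile <- function(condition = c("stress", "elevation")) {
  condition <- match.arg(condition)
  rois <- thermal_rois()
  th_shift <- stats::setNames(numeric(nrow(rois)), paste0("thermal_roi_", rois$roi_id))
  if (condition == "stress") {
    rppg <- c(hr_mean_bpm = 5, sdnn_ms = -10, rmssd_ms = -8,
              pnn50_pct = -6, ln_lf = -0.4, ln_hf = -0.3)
    th_shift[paste0("thermal_roi_", rois$roi_id[rois$group %in% c("lip", "cheek")])] <- 0.20
  } else {
    rppg <- c(hr_mean_bpm = 2, sdnn_ms = -5, rmssd_ms = -4,
              pnn50_pct = -4, ln_lf = -0.2, ln_hf = -0.2)
    warm <- c("nose", "nostril", "lip", "cheek", "chin")
    th_shift[paste0("thermal_roi_", rois$roi_id[rois$group %in% warm])] <- 0.18
  }
  list(rppg_shift = rppg,
       thermal_shift = th_shift,
       rppg_noise_sd = c(hr_mean_bpm = 4, sdnn_ms = 10, rmssd_ms = 9,
                         pnn50_pct = 7, ln_lf = 0.5, ln_hf = 0.5),
       thermal_noise_sd = 0.15,
       rppg_subject_sd = c(hr_mean_bpm = 7, sdnn_ms = 14, rmssd_ms = 12,
                           pnn50_pct = 9, ln_lf = 0.7, ln_hf = 0.7),
       thermal_subject_sd = 0.25)
}

#' Generate a labeled synthetic two-state study
#'
#' For each subject, simulates one baseline-state and one stimulus-state
#' record. Record-level features are the six r-PPG measures (HR mean, SDNN,
#' rMSSD, pNN50, ln LF, ln HF) and the 22 regional temperature deviations;
#' the stimulus state applies the profile's programmed shifts on top of a
#' subject random effect and record-level noise. Rows are labeled
#' `baseline`/`stimulus`; cross-validation downstream keeps both records of
#' a subject in the same fold.
#'
#' @param n_subjects number of subjects (>= 10).
#' @param condition `"stress"` or `"elevation"` (sets the default profile).
#' @param effect_profile profile as from [default_effect_profile()]; pass a
#'   modified copy to program other effect sizes or noise levels.
#' @param seed integer seed.
#' @return a [fusion_dataset()] with two rows per subject.
#' @export
generate_labeled_study <- function(n_subjects = 60L,
                                   condition = c("stress", "elevation"),
                                   effect_profile = NULL, seed = 1L) {
  assert_scalar_num(n_subjects, "n_subjects", lower = 10)
  condition <- match.arg(condition)
  prof <- if (is.null(effect_profile)) default_effect_profile(condition) else effect_profile
  n_subjects <- as.integer(n_subjects)

  rppg_base <- c(hr_mean_bpm = 72, sdnn_ms = 50, rmssd_ms = 42,
                 pnn50_pct = 20, ln_lf = 6.5, ln_hf = 6.0)
  rppg_names <- names(rppg_base)
  th_names <- names(prof$thermal_shift)

  withr::local_seed(derive_seed(seed, 53L))
  rows <- vector("list", 2L * n_subjects)
  for (s in seq_len(n_subjects)) {
    subj_rppg <- rppg_base + stats::rnorm(6L, 0, prof$rppg_subject_sd)
    subj_th <- stats::rnorm(length(th_names), 0, prof$thermal_subject_sd)
    for (state in c("baseline", "stimulus")) {
      rp <- subj_rppg + stats::rnorm(6L, 0, prof$rppg_noise_sd)
      th <- subj_th + stats::rnorm(length(th_names), 0, prof$thermal_noise_sd)
      if (state == "stimulus") {
        rp <- rp + prof$rppg_shift[rppg_names]
        th <- th + prof$thermal_shift
      }
      row <- data.frame(subject_id = sprintf("S%03d", s), label = state)
      row[paste0("rppg_", rppg_names)] <- as.list(rp)
      row[th_names] <- as.list(th)
      rows[[2L * (s - 1L) + (state == "stimulus") + 1L]] <- row
    }
  }
  df <- do.call(rbind, rows)
  modality <- c(stats::setNames(rep("rppg", 6L), paste0("rppg_", rppg_names)),
                stats::setNames(rep("thermal", length(th_names)), th_names))
  fusion_dataset(df, modality)
}
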