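test_that("unmodulated beat series lays beats at exactly the programmed rate", {
  b <- generate_beat_series(60, 60, 0, 0, 0, seed = 42)
  expect_length(b$beat_times, 60L)
  expect_equal(diff(b$beat_times), rep(1, 59))
})

test_that("generated mean NN tracks the programmed heart rate", {
  b <- generate_beat_series(300, 72, 0.02, 0.02, 0.005, seed = 1)
  mean_nn <- mean(diff(b$beat_times))
  expect_lt(abs(mean_nn - 60 / 72) / (60 / 72), 0.02)
})

test_that("beat generation rejects modulation that could drive NN below 0.3 s", {
  expect_error(generate_beat_series(60, 170, lf_amp_s = 0.2, seed = 1),
               "0.3")
  expect_error(generate_beat_series(20, 60, seed = 1), "duration_s")
})

test_that("beat generation is deterministic given the seed", {
  a <- generate_beat_series(120, 80, 0.03, 0.02, 0.01, seed = 9)
  b <- generate_beat_series(120, 80, 0.03, 0.02, 0.01, seed = 9)
  c <- generate_beat_series(120, 80, 0.03, 0.02, 0.01, seed = 10)
  expect_identical(a$beat_times, b$beat_times)
  expect_false(identical(a$beat_times, c$beat_times))
})

test_that("noise-free zero-amplitude traces are constant per channel", {
  b <- generate_beat_series(40, 60, 0, 0, 0, seed = 1)
  tr <- synthesize_rgb_traces(b, fps = 30, n_rois = 2, pulse_amp = 0,
                              noise_sd = 0, illum_drift_amp = 0, seed = 1)
  for (id in 1:2) {
    sub <- tr$traces[tr$traces$roi_id == id, ]
    for (ch in c("R", "G", "B")) expect_equal(stats::sd(sub[[ch]]), 0)
  }
})

test_that("green channel of a 1 Hz pulse train peaks at 1.0 Hz", {
  b <- generate_beat_series(60, 60, 0, 0, 0, seed = 1)
  tr <- synthesize_rgb_traces(b, fps = 30, n_rois = 1, noise_sd = 0,
                              illum_drift_amp = 0, seed = 1)
  g <- tr$traces$G
  expect_equal(dominant_freq(g - mean(g), 30), 1.0, tolerance = 0.03)
})

test_that("trace synthesis reuses the pulse waveform across seeds but not the noise", {
  b <- generate_beat_series(40, 72, 0, 0, 0, seed = 1)
  noiseless <- function(s) synthesize_rgb_traces(b, fps = 20, n_rois = 1,
                                                 noise_sd = 0, illum_drift_amp = 0,
                                                 seed = s)
  t1 <- noiseless(1)$traces
  t2 <- noiseless(2)$traces
  # same pulse waveform: green series agree up to an affine gain
  g1 <- t1$G - mean(t1$G)
  g2 <- t2$G - mean(t2$G)
  expect_gt(stats::cor(g1, g2), 0.999999)
  n1 <- synthesize_rgb_traces(b, fps = 20, n_rois = 1, noise_sd = 0.01,
                              illum_drift_amp = 0, seed = 1)$traces
  n2 <- synthesize_rgb_traces(b, fps = 20, n_rois = 1, noise_sd = 0.01,
                              illum_drift_amp = 0, seed = 2)$traces
  expect_false(identical(n1$G, n2$G))
})

test_that("thermal generator recovers programmed segment effects", {
  quiet <- thermal_effect_spec()
  tr0 <- generate_thermal_traces(quiet, 480, 8, seed = 1)
  ch0 <- absolute_changes(segment_means(tr0))
  expect_equal(unname(ch0), rep(0, 22))

  spec <- thermal_effect_spec(effect_c = c(lip = 0.3))
  tr <- generate_thermal_traces(spec, 480, 8, seed = 1)
  ch <- absolute_changes(segment_means(tr))
  lips <- as.character(48:53)
  expect_equal(unname(ch[lips]), rep(0.3, 6), tolerance = 1e-6)
  expect_equal(unname(ch[setdiff(names(ch), lips)]), rep(0, 16),
               tolerance = 1e-6)
})

test_that("missing_fraction drops the stated share of thermal frames", {
  spec <- thermal_effect_spec(missing_fraction = 0.2)
  tr <- generate_thermal_traces(spec, 480, 8, seed = 3)
  per_roi <- table(tr$traces$roi_id)
  expect_equal(unname(as.integer(per_roi)), rep(round(0.8 * 480 * 8), 22))
  expect_error(generate_thermal_traces(spec, 200), "duration")
})

test_that("labeled study generation is byte-identical across runs", {
  d1 <- generate_labeled_study(10, "stress", seed = 5)
  d2 <- generate_labeled_study(10, "stress", seed = 5)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trace_csv(d1, f1); write_trace_csv(d2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(nrow(d1), 20L)
  expect_setequal(levels(d1$label), c("baseline", "stimulus"))
})
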