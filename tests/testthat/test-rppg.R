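test_that("POS maps constant input to an identically zero pulse", {
  tr <- constant_traces(n = 300)
  bvp <- pos_bvp(tr)
  expect_equal(bvp[[1L]]$samples, rep(0, 300))
})

test_that("POS is invariant to per-channel multiplicative gain", {
  b <- generate_beat_series(30, 72, 0, 0, 0, seed = 1)
  tr <- synthesize_rgb_traces(b, fps = 30, n_rois = 1, noise_sd = 0.002, seed = 4)
  scaled <- tr
  scaled$traces$R <- tr$traces$R * 3
  scaled$traces$G <- tr$traces$G * 1.7
  scaled$traces$B <- tr$traces$B * 0.5
  expect_equal(pos_bvp(tr)[[1L]]$samples, pos_bvp(scaled)[[1L]]$samples,
               tolerance = 1e-9)
})

test_that("POS recovers the programmed pulse frequency", {
  # 1.2 Hz pulse = 72 BPM beat train, no noise
  b <- generate_beat_series(60, 72, 0, 0, 0, seed = 1)
  tr <- synthesize_rgb_traces(b, fps = 30, n_rois = 1, noise_sd = 0,
                              illum_drift_amp = 0.01, seed = 1)
  bvp <- pos_bvp(tr)[[1L]]
  expect_equal(dominant_freq(bvp$samples, 30), 1.2, tolerance = 0.03)
})

test_that("POS rejects non-positive intensities and short traces", {
  tr <- constant_traces(n = 100)
  tr$traces$G[5] <- -1
  expect_error(roi_trace_set(tr$traces, 30), "finite and > 0")
  expect_error(pos_bvp(constant_traces(n = 10)), "POS window")
})

test_that("windowed spectral HR finds a pure tone to within the grid", {
  fps <- 30
  t <- (0:(20 * fps - 1)) / fps
  hr <- windowed_hr(make_bvp(sin(2 * pi * 1.2 * t), fps))
  expect_true(all(abs(hr$hr_bpm - 72) <= 0.5))
  expect_false(any(hr$low_confidence))
  # window count: floor((T - win)/hop) + 1
  expect_equal(nrow(hr), floor((20 - 6) / 1) + 1)
})

test_that("out-of-band tones are confined to the band and flagged", {
  fps <- 30
  t <- (0:(15 * fps - 1)) / fps
  hr <- windowed_hr(make_bvp(sin(2 * pi * 0.5 * t), fps))
  expect_true(all(hr$hr_bpm >= 39 & hr$hr_bpm <= 240))
  expect_true(all(hr$low_confidence))
})

test_that("the stronger of two tones wins the spectral argmax", {
  fps <- 30
  t <- (0:(15 * fps - 1)) / fps
  x <- sin(2 * pi * 1.0 * t) + 0.3 * sin(2 * pi * 2.0 * t)
  hr <- windowed_hr(make_bvp(x, fps))
  expect_true(all(abs(hr$hr_bpm - 60) <= 0.5))
})

test_that("all-zero windows yield missing HR", {
  fps <- 30
  hr <- windowed_hr(make_bvp(numeric(10 * fps), fps))
  expect_true(all(is.na(hr$hr_bpm)))
})

test_that("aggregation is the per-window median with missing values excluded", {
  mk <- function(v) hr_series(1:3, v)
  agg <- aggregate_hr(list(mk(c(72, 60, 70)), mk(c(72, 72, NA)),
                           mk(c(72, 150, 71))))
  expect_equal(agg$hr_bpm, c(72, 72, 70.5))
  expect_null(attr(agg, "roi_id"))
  expect_true(is.na(aggregate_hr(list(mk(c(NA, 60, 60)),
                                      mk(c(NA, 61, 61))))$hr_bpm[1L]))
})

test_that("MAE/HR quality index matches its definition and is scale-free", {
  mk <- function(v) hr_series(1, v)
  agg <- mk(70)
  q <- quality_mae_over_hr(list(mk(60), mk(80)), agg)
  expect_equal(q$mae_bpm, 10)
  expect_equal(q$mae_over_hr, 10 / 70)
  q2 <- quality_mae_over_hr(list(mk(120), mk(160)), mk(140))
  expect_equal(q2$mae_over_hr, q$mae_over_hr)
  # zero iff every ROI equals the aggregate
  expect_equal(quality_mae_over_hr(list(mk(70), mk(70)), agg)$mae_over_hr, 0)
})

test_that("adding noise to some ROIs does not decrease MAE/HR in expectation", {
  base <- generate_beat_series(60, 72, 0, 0, 0, seed = 1)
  deltas <- replicate(20, {
    s <- sample.int(1e6, 1L)
    tr <- synthesize_rgb_traces(base, fps = 20, n_rois = 3,
                                noise_sd = 0.002, seed = s)
    noisy <- tr
    sel <- noisy$traces$roi_id == 1
    set.seed(s)
    noisy$traces$G[sel] <- noisy$traces$G[sel] * (1 + stats::rnorm(sum(sel), 0, 0.01))
    q0 <- with_hr_quality(tr)
    q1 <- with_hr_quality(noisy)
    q1 - q0
  })
  expect_gt(mean(deltas), 0)
})
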