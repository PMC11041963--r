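test_that("the jump filter removes the pair member farther from the median", {
  h <- hr_series(1:4, c(70, 72, 110, 71))
  out <- filter_hr_jumps(h)
  expect_equal(out$hr_bpm, c(70, 72, 71))
  expect_equal(out$t_center_s, c(1, 2, 4))
})

test_that("series without large jumps pass unchanged and filtering is idempotent", {
  h <- hr_series(1:3, c(70, 71, 72))
  expect_equal(filter_hr_jumps(h)$hr_bpm, c(70, 71, 72))
  h2 <- hr_series(1:8, c(70, 100, 72, 71, 130, 69, 68, 140))
  once <- filter_hr_jumps(h2)
  twice <- filter_hr_jumps(once)
  expect_identical(once$hr_bpm, twice$hr_bpm)
})

test_that("filtered output is a jump-free subsequence of its input", {
  set.seed(11)
  for (i in 1:50) {
    v <- stats::rnorm(30, 75, 20)
    h <- hr_series(seq_along(v), v)
    out <- filter_hr_jumps(h)
    expect_true(all(abs(diff(out$hr_bpm)) <= 25))
    # subsequence: surviving (t, hr) pairs appear in the input in order
    idx <- match(out$t_center_s, h$t_center_s)
    expect_false(any(is.na(idx)))
    expect_true(!is.unsorted(idx, strictly = TRUE))
    expect_equal(out$hr_bpm, h$hr_bpm[idx])
  }
})

test_that("HR converts to NN with out-of-range values dropped", {
  expect_equal(hr_to_nn(hr_series(1:2, c(60, 75)))$nn_ms, c(1000, 800))
  expect_message(nn <- hr_to_nn(hr_series(1:3, c(60, 250, 75))), "dropped 1")
  expect_equal(nn$nn_ms, c(1000, 800))
  expect_error(suppressMessages(hr_to_nn(hr_series(1:2, c(250, 20)))),
               "fewer than 2")
})

test_that("time-domain measures match hand-computed values", {
  expect_equal(time_domain(nn_series(c(800, 800, 800), 1:3)),
               list(sdnn_ms = 0, rmssd_ms = 0, pnn50_pct = 0))
  td <- time_domain(nn_series(c(800, 850, 800), 1:3))
  expect_equal(td$rmssd_ms, 50)
  expect_equal(td$pnn50_pct, 0)        # strict > 50 ms
  expect_equal(td$sdnn_ms, 28.86751, tolerance = 1e-6)
  expect_equal(time_domain(nn_series(c(800, 860, 800), 1:3))$pnn50_pct, 100)
  short <- time_domain(nn_series(c(800, 850), 1:2))
  expect_false(is.na(short$sdnn_ms))
  expect_true(is.na(short$rmssd_ms) && is.na(short$pnn50_pct))
})

test_that("time-domain measures agree with a direct-formula oracle", {
  set.seed(7)
  for (i in 1:20) {
    nn <- stats::runif(sample(5:50, 1), 400, 1500)
    got <- time_domain(nn_series(nn, seq_along(nn)))
    want <- hrv_oracle(nn)
    expect_equal(got$sdnn_ms, want$sdnn, tolerance = 1e-12)
    expect_equal(got$rmssd_ms, want$rmssd, tolerance = 1e-12)
    expect_equal(got$pnn50_pct, want$pnn50, tolerance = 1e-12)
  }
})

test_that("frequency analysis places programmed modulation in the right band", {
  b_lf <- generate_beat_series(300, 72, 0.05, 0, 0.002, seed = 3)
  f_lf <- freq_domain(nn_from_beats(b_lf))
  expect_gt(f_lf$lf_ms2 / f_lf$hf_ms2, 5)
  b_hf <- generate_beat_series(300, 72, 0, 0.05, 0.002, seed = 3)
  f_hf <- freq_domain(nn_from_beats(b_hf))
  expect_gt(f_hf$hf_ms2 / f_hf$lf_ms2, 5)
})

test_that("constant NN yields missing band powers with a warning", {
  nn <- nn_series(rep(800, 500), seq(0, 499) * 0.8)
  w <- capture_warnings(fd <- freq_domain(nn))
  expect_true(length(w) >= 1L && all(grepl("non-positive", w)))
  expect_true(is.na(fd$ln_lf) || is.na(fd$ln_hf))
  expect_error(freq_domain(nn_series(c(800, 820, 810), 1:3)), "coverage")
})

test_that("segment deltas recover a programmed heart-rate step", {
  t <- seq(3, 477, by = 1)
  hr <- ifelse(t < 240, 70, 75) + 2 * sin(2 * pi * t / 9) + 1.5 * sin(2 * pi * t / 31)
  sm <- segment_measures(hr_series(t, hr))
  d_hr <- sm$changes$delta[sm$changes$measure == "hr_mean_bpm"]
  expect_equal(d_hr, 5, tolerance = 0.2)
  expect_equal(nrow(sm$segments), 4L)
})

test_that("identical first and last segments give zero deltas", {
  # two bit-identical 120-point segments (window length chosen so the
  # recording spans exactly two segments)
  pattern <- 70 + 3 * sin(2 * pi * (0:119) / 10)
  sm <- segment_measures(hr_series(0:239, rep(pattern, 2L), win_s = 2))
  expect_equal(sm$changes$delta, rep(0, 6))
})

test_that("recordings shorter than two segments are rejected", {
  t <- seq(3, 197, by = 1)
  expect_error(segment_measures(hr_series(t, rep(70, length(t)))),
               "shorter than two")
})
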