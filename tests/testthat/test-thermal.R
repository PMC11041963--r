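mk_thermal <- function(temp_fun, duration = 480, fps = 4,
                       rois = thermal_rois()$roi_id) {
  t <- seq(0, duration - 1 / fps, by = 1 / fps)
  df <- do.call(rbind, lapply(rois, function(id)
    data.frame(time_s = t, roi_id = id, temp_c = temp_fun(t, id))))
  thermal_trace_set(df, fps = fps, duration_s = duration)
}

test_that("segment means: constant and ramp traces match closed forms", {
  const <- mk_thermal(function(t, id) rep(34, length(t)), rois = c(58L, 30L))
  m <- segment_means(const)
  expect_equal(m$mean_first_c, c(34, 34))
  expect_equal(m$mean_last_c, c(34, 34))
  ramp <- mk_thermal(function(t, id) 34 + t / 480, fps = 8, rois = 58L)
  mr <- segment_means(ramp)
  # continuous-time means of the ramp over [0,120] and [360,480]
  expect_equal(mr$mean_first_c, 34.125, tolerance = 2e-4)
  expect_equal(mr$mean_last_c, 34.875, tolerance = 2e-4)
})

test_that("windows below minimum coverage are reported missing", {
  tr <- mk_thermal(function(t, id) rep(34, length(t)), rois = c(58L, 30L))
  keep <- !(tr$traces$roi_id == 30 & tr$traces$time_s < 120 &
              tr$traces$time_s %% 1 < 0.6)  # drop 60% of ROI 30's first window
  tr2 <- thermal_trace_set(tr$traces[keep, ], fps = 4, duration_s = 480)
  m <- segment_means(tr2, min_coverage = 0.5)
  expect_true(is.na(m$mean_first_c[m$roi_id == 30]))
  expect_false(is.na(m$mean_last_c[m$roi_id == 30]))
})

test_that("differential matrix follows its definition and is antisymmetric", {
  ch <- c(`30` = 0.2, `58` = -0.1)
  M <- differential_matrix(ch)
  expect_equal(M["30", "58"], -0.3)
  expect_equal(M["58", "30"], 0.3)
  set.seed(2)
  ch2 <- stats::setNames(stats::rnorm(22), thermal_rois()$roi_id)
  M2 <- differential_matrix(ch2)
  expect_equal(M2, -t(M2))
  expect_equal(unname(diag(M2)), rep(0, 22))
})

test_that("forehead referencing subtracts the reference change", {
  ch <- c(`30` = 0.3, `58` = 0.1)
  ref <- forehead_referenced(ch)
  expect_equal(unname(ref["30"]), 0.2)
  expect_equal(unname(ref["58"]), 0)
  expect_error(forehead_referenced(c(`30` = 0.3)), "reference ROI")
})

test_that("referenced changes equal the forehead row of the differential matrix", {
  set.seed(4)
  ch <- stats::setNames(stats::rnorm(22, 0, 0.3), thermal_rois()$roi_id)
  f <- thermal_features(mk_thermal(function(t, id)
    34 + ch[[as.character(id)]] * t / (480 - 120), fps = 4))
  expect_equal(f$ref_change_c, f$diff_matrix["58", ])
})

test_that("a common additive offset changes no referenced or differential feature", {
  base_fun <- function(t, id) 33 + (id %% 5) * 0.1 + 0.4 * t / 480
  f1 <- thermal_features(mk_thermal(base_fun))
  f2 <- thermal_features(mk_thermal(function(t, id) base_fun(t, id) + 2))
  expect_equal(f1$ref_change_c, f2$ref_change_c)
  expect_equal(f1$diff_matrix, f2$diff_matrix)
})

test_that("a programmed common drift cancels under forehead referencing", {
  spec <- thermal_effect_spec(effect_c = c(lip = 0.3), drift_c_per_min = 0.1)
  f <- thermal_features(generate_thermal_traces(spec, 480, 8, seed = 2))
  lips <- as.character(48:53)
  # absolute changes carry the drift; referenced changes recover the effect
  expect_true(all(abs(f$abs_change_c[lips] - 0.3) > 0.1))
  expect_equal(unname(f$ref_change_c[lips]), rep(0.3, 6), tolerance = 1e-6)
})

test_that("unknown regions and out-of-range temperatures are rejected", {
  df <- data.frame(time_s = 0:3, roi_id = 99L, temp_c = 34)
  expect_error(thermal_trace_set(df, fps = 1), "unknown thermal roi_id")
  df2 <- data.frame(time_s = 0:3, roi_id = 58L, temp_c = c(34, 34, 80, 34))
  expect_error(thermal_trace_set(df2, fps = 1), "20, 45")
})
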