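# Profile helpers for programmed study designs.
separable_profile <- function() {
  p <- default_effect_profile("stress")
  p$rppg_shift <- p$rppg_shift * 20
  p$thermal_shift <- p$thermal_shift * 20
  p$rppg_noise_sd[] <- 0.01
  p$thermal_noise_sd <- 0.01
  p$rppg_subject_sd[] <- 0.01
  p$thermal_subject_sd <- 0.01
  p
}

null_profile <- function() {
  p <- default_effect_profile("stress")
  p$rppg_shift[] <- 0
  p$thermal_shift[] <- 0
  p
}

test_that("assemble_features inner-joins modalities and flags incomplete subjects", {
  ids <- sprintf("S%02d", 1:10)
  rp <- data.frame(subject_id = ids, d_hr = stats::rnorm(10))
  th <- data.frame(subject_id = ids, thermal_roi_58 = stats::rnorm(10))
  lab <- data.frame(subject_id = ids, label = rep(c("baseline", "stimulus"), 5))
  ds <- assemble_features(rp, th, lab)
  expect_s3_class(ds, "fusion_dataset")
  expect_equal(nrow(ds), 10L)
  expect_length(attr(ds, "incomplete"), 0L)

  ds2 <- assemble_features(rp, th[-1L, ], lab)
  expect_equal(attr(ds2, "incomplete"), ids[1L])
  expect_equal(nrow(ds2), 9L)

  expect_error(assemble_features(rp, th, lab[0L, ]), "empty label")
  expect_error(assemble_features(rp[c(1, 1:9), ], th, lab), "duplicate")
})

test_that("a linearly separable study is classified perfectly by both models", {
  ds <- generate_labeled_study(12, effect_profile = separable_profile(), seed = 1)
  for (model in c("svm", "rf")) {
    ev <- train_eval(ds, "all", model, cv_folds = 3, seed = 1)
    expect_equal(ev$avg_accuracy, 1.0)
    expect_equal(ev$avg_f1, 1.0)
  }
})

test_that("evaluation is deterministic and invariant to feature column order", {
  ds <- generate_labeled_study(12, seed = 2)
  e1 <- train_eval(ds, "rppg", "svm", cv_folds = 3, seed = 3)
  e2 <- train_eval(ds, "rppg", "svm", cv_folds = 3, seed = 3)
  expect_identical(e1$avg_accuracy, e2$avg_accuracy)
  expect_identical(e1$fold_assignment, e2$fold_assignment)
  # permute feature columns
  perm <- ds[, c("subject_id", "label", sample(setdiff(names(ds), c("subject_id", "label"))))]
  dsp <- fusion_dataset(perm, attr(ds, "modality"))
  e3 <- train_eval(dsp, "rppg", "svm", cv_folds = 3, seed = 3)
  expect_identical(e1$avg_accuracy, e3$avg_accuracy)
})

test_that("late fusion copies agreeing, correct base models", {
  ds <- generate_labeled_study(12, effect_profile = separable_profile(), seed = 4)
  ev <- late_fusion_eval(ds, cv_folds = 3, seed = 4)
  expect_equal(ev$avg_accuracy, 1.0)
})

test_that("late fusion stays near chance when both modalities are noise", {
  accs <- vapply(1:3, function(s) {
    ds <- generate_labeled_study(20, effect_profile = null_profile(), seed = s)
    late_fusion_eval(ds, base_models = c(rppg = "svm", thermal = "svm"),
                     cv_folds = 4, seed = s)$avg_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.2)
})

test_that("an uninformative modality does not sink random-forest early fusion", {
  p <- default_effect_profile("stress")
  p$thermal_shift[] <- 0  # thermal pure noise
  accs <- vapply(1:3, function(s) {
    ds <- generate_labeled_study(30, effect_profile = p, seed = s)
    c(early_fusion_eval(ds, "rf", cv_folds = 3, seed = s)$avg_accuracy,
      train_eval(ds, "rppg", "rf", cv_folds = 3, seed = s)$avg_accuracy)
  }, numeric(2))
  expect_lt(abs(mean(accs[1, ]) - mean(accs[2, ])), 0.1)
})

test_that("Shapley attribution is zero for features the model ignores", {
  ds <- generate_labeled_study(15, effect_profile = separable_profile(), seed = 5)
  const_col <- names(which(attr(ds, "modality") == "thermal"))[1L]
  ds[[const_col]] <- 1.0  # constant: no tree can split on it
  m <- fit_model(ds, "all", "rf", seed = 5)
  imp <- shap_importance(m, ds, nsim = 10, seed = 5)
  expect_equal(imp$mean_abs_shap[imp$feature == const_col], 0)
  expect_equal(sort(imp$rank), seq_len(nrow(imp)))
})

test_that("a single dominant programmed feature ranks first", {
  p <- null_profile()
  p$rppg_shift["sdnn_ms"] <- 40
  ds <- generate_labeled_study(25, effect_profile = p, seed = 6)
  m <- fit_model(ds, "all", "rf", seed = 6)
  imp <- shap_importance(m, ds, nsim = 15, seed = 6)
  expect_equal(imp$feature[imp$rank == 1L], "rppg_sdnn_ms")
})

test_that("Shapley ranks are invariant to feature column order", {
  p <- null_profile()
  p$rppg_shift["sdnn_ms"] <- 40
  ds <- generate_labeled_study(15, effect_profile = p, seed = 7)
  m <- fit_model(ds, "rppg", "rf", seed = 7)
  imp1 <- shap_importance(m, ds, nsim = 10, seed = 8)
  perm <- ds[, c("subject_id", "label", rev(setdiff(names(ds), c("subject_id", "label"))))]
  dsp <- fusion_dataset(perm, attr(ds, "modality"))
  imp2 <- shap_importance(m, dsp, nsim = 10, seed = 8)
  expect_identical(imp1$feature, imp2$feature)
  expect_identical(imp1$rank, imp2$rank)
})
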