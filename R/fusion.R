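# Multimodal fusion: per-record feature vectors from the r-PPG and thermal
# paths, stratified subject-level cross-validation with in-fold grid search
# (so neither standardization nor hyperparameter selection leaks test
# data), early fusion (feature concatenation) and late fusion (a
# Gini-criterion decision tree over the base models' class probabilities).

#' Fusion dataset constructor
#'
#' @param df data frame with `subject_id`, `label` (two levels; the second
#'   level is the positive class, e.g. "stimulus") and numeric feature
#'   columns.
#' @param modality named character vector mapping every feature column to
#'   `"rppg"` or `"thermal"`.
#' @return data frame of class `fusion_dataset` with a `modality`
#'   attribute.
#' @export
fusion_dataset <- function(df, modality) {
  if (!all(c("subject_id", "label") %in% names(df)))
    pt_validation_error("fusion data needs `subject_id` and `label` columns")
  feats <- setdiff(names(df), c("subject_id", "label"))
  if (!length(feats)) pt_validation_error("no feature columns")
  if (anyDuplicated(feats)) pt_validation_error("feature names must be unique")
  missing_tag <- setdiff(feats, names(modality))
  if (length(missing_tag))
    pt_validation_error(paste("features lacking a modality tag:",
                              paste(missing_tag, collapse = ", ")))
  if (!all(modality[feats] %in% c("rppg", "thermal")))
    pt_validation_error("modality tags must be 'rppg' or 'thermal'")
  df$label <- factor(df$label)
  if (nlevels(df$label) != 2L)
    pt_validation_error("label must have exactly two levels")
  structure(df, modality = modality[feats],
            class = c("fusion_dataset", "data.frame"))
}

#' @export
print.fusion_dataset <- function(x, ...) {
  mod <- attr(x, "modality")
  cat(sprintf("<fusion_dataset> %d records, %d subjects; %d rppg + %d thermal features; labels: %s\n",
              nrow(x), length(unique(x$subject_id)),
              sum(mod == "rppg"), sum(mod == "thermal"),
              paste(levels(x$label), collapse = "/")))
  invisible(x)
}

#' Assemble per-subject features from both modalities
#'
#' Inner-joins r-PPG deltas and thermal changes on `subject_id`, attaches
#' labels, and tags each feature with its modality. Subjects missing one
#' modality are reported via the `incomplete` attribute and excluded from
#' the joined rows (complete-case fusion); they remain usable in unimodal
#' datasets built from the single-modality input.
#'
#' @param rppg_features data frame: `subject_id` + numeric r-PPG feature
#'   columns.
#' @param thermal_features data frame: `subject_id` + numeric thermal
#'   feature columns.
#' @param labels data frame: `subject_id`, `label`.
#' @param quality optional data frame: `subject_id`, `mae_over_hr`,
#'   attached as an attribute.
#' @return a [fusion_dataset()].
#' @export
assemble_features <- function(rppg_features, thermal_features, labels,
                              quality = NULL) {
  for (nm in c("rppg_features", "thermal_features", "labels")) {
    d <- get(nm)
    if (anyDuplicated(d$subject_id))
      pt_validation_error(sprintf("duplicate subject ids in %s", nm))
  }
  if (!nrow(labels)) pt_validation_error("empty label set")
  common <- Reduce(intersect, list(rppg_features$subject_id,
                                   thermal_features$subject_id,
                                   labels$subject_id))
  all_ids <- union(rppg_features$subject_id, thermal_features$subject_id)
  incomplete <- setdiff(all_ids, common)
  df <- merge(merge(labels, rppg_features, by = "subject_id"),
              thermal_features, by = "subject_id")
  rp_cols <- setdiff(names(rppg_features), "subject_id")
  th_cols <- setdiff(names(thermal_features), "subject_id")
  modality <- c(stats::setNames(rep("rppg", length(rp_cols)), rp_cols),
                stats::setNames(rep("thermal", length(th_cols)), th_cols))
  out <- fusion_dataset(df, modality)
  attr(out, "incomplete") <- incomplete
  if (!is.null(quality)) attr(out, "quality") <- quality
  out
}

# ---- internal CV machinery ----------------------------------------------

# Feature columns of a modality, in canonical (sorted) order so results do
# not depend on column order.
feature_cols <- function(dataset, modality) {
  mod <- attr(dataset, "modality")
  cols <- if (modality == "all") names(mod) else names(mod)[mod == modality]
  if (!length(cols)) pt_validation_error(sprintf("no features for modality '%s'", modality))
  sort(cols)
}

# Stratified subject-level fold assignment: subjects are stratified by
# their label profile (for two-record subjects both labels appear in every
# fold automatically) and dealt round-robin after a seeded shuffle.
make_subject_folds <- function(dataset, k, seed) {
  subj <- unique(dataset$subject_id)
  prof <- vapply(subj, function(s)
    paste(sort(unique(as.character(dataset$label[dataset$subject_id == s]))),
          collapse = "+"), character(1L))
  withr::local_seed(derive_seed(seed, 71L))
  fold <- stats::setNames(integer(length(subj)), subj)
  for (p in unique(prof)) {
    ids <- sample(subj[prof == p])
    fold[ids] <- rep_len(seq_len(k), length(ids))
  }
  fold
}

svm_grid <- function() {
  expand.grid(cost = c(0.1, 1, 10, 100),
              gamma = c(NA, 0.01, 0.1, 1))  # NA = 1/(p * var(X)) heuristic
}

rf_grid <- function() {
  expand.grid(ntree = c(100L, 300L),
              maxdepth = c(NA, 3L, 5L),
              nodesize = c(1L, 3L))
}

fit_clf <- function(x, y, model, params, seed) {
  set.seed(derive_seed(seed, 101L))
  if (model == "svm") {
    gamma <- params$gamma
    if (is.na(gamma)) gamma <- 1 / (ncol(x) * max(stats::var(as.vector(x)), 1e-12))
    fit <- e1071::svm(x = x, y = y, kernel = "radial",
                      cost = params$cost, gamma = gamma,
                      probability = TRUE)
  } else {
    # cap terminal nodes at what the sample can support (avoids the
    # randomForest maxnodes warning on small training folds)
    maxnodes <- if (is.na(params$maxdepth)) NULL else
      min(2L^params$maxdepth, nrow(x))
    fit <- randomForest::randomForest(x = x, y = y, ntree = params$ntree,
                                      maxnodes = maxnodes,
                                      nodesize = params$nodesize)
  }
  list(fit = fit, model = model, levels = levels(y))
}

predict_clf <- function(clf, x, type = c("class", "prob")) {
  type <- match.arg(type)
  pos <- clf$levels[2L]
  if (clf$model == "svm") {
    pr <- stats::predict(clf$fit, x, probability = (type == "prob"))
    if (type == "class") return(factor(as.character(pr), levels = clf$levels))
    pm <- attr(pr, "probabilities")
    if (is.null(pm)) return(as.numeric(pr == pos))
    return(pm[, pos])
  }
  if (type == "class") {
    factor(as.character(stats::predict(clf$fit, x)), levels = clf$levels)
  } else {
    stats::predict(clf$fit, x, type = "prob")[, pos]
  }
}

# z-score using training statistics; constant columns get scale 1
fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}
apply_scaler <- function(x, s) scale(x, center = s$center, scale = s$scale)

f1_score <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  if (tp == 0 && (fp > 0 || fn > 0)) return(0)
  if (tp == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

# Grid search by inner grouped CV on the training rows; returns the best
# parameter row (ties keep the first, so selection is deterministic).
grid_search <- function(x, y, subjects, model, seed, inner_k = 3L) {
  grid <- if (model == "svm") svm_grid() else rf_grid()
  subj <- unique(subjects)
  withr::local_seed(derive_seed(seed, 131L))
  fold <- stats::setNames(rep_len(seq_len(inner_k), length(subj)), sample(subj))
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L; total <- 0L
    for (f in seq_len(inner_k)) {
      tr <- fold[as.character(subjects)] != f
      te <- !tr
      if (!any(te) || length(unique(y[tr])) < 2L) next
      sc <- fit_scaler(x[tr, , drop = FALSE])
      clf <- fit_clf(apply_scaler(x[tr, , drop = FALSE], sc), y[tr],
                     model, grid[g, , drop = FALSE],
                     seed = derive_seed(seed, 1000L + 10L * g + f))
      pred <- predict_clf(clf, apply_scaler(x[te, , drop = FALSE], sc))
      correct <- correct + sum(pred == y[te])
      total <- total + sum(te)
    }
    acc[g] <- if (total) correct / total else 0
  }
  grid[which.max(acc), , drop = FALSE]
}

#' Cross-validated evaluation of a unimodal or fused classifier
#'
#' Stratified subject-level k-fold cross-validation (all records of a
#' subject share a fold). Within each training fold, features are z-scored
#' with training statistics and hyperparameters are chosen by an inner
#' grouped grid search (SVM: radial kernel, cost 0.1-100, gamma heuristic
#' or 0.01-1; random forest: 100/300 trees, depth unrestricted/3/5, minimum
#' leaf 1/3); the refit model is then scored on the held-out fold. Feature
#' columns are used in canonical sorted order, so column permutations do
#' not change the result.
#'
#' @param dataset a [fusion_dataset()].
#' @param modality `"rppg"`, `"thermal"` or `"all"` (early fusion).
#' @param model `"svm"` or `"rf"`.
#' @param cv_folds number of folds (default 5).
#' @param seed integer seed controlling folds, grid search and model fits.
#' @return list of class `eval_result`: `avg_accuracy`, `avg_f1`,
#'   per-fold metrics, chosen hyperparameters, fold assignment.
#' @export
train_eval <- function(dataset, modality = "all", model = c("svm", "rf"),
                       cv_folds = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "fusion_dataset"))
  model <- match.arg(model)
  cols <- feature_cols(dataset, modality)
  keep <- stats::complete.cases(dataset[cols])
  d <- dataset[keep, , drop = FALSE]
  y <- droplevels(d$label)
  if (nlevels(y) < 2L || min(table(y)) < 2L)
    pt_validation_error("need at least 2 records per class")
  x <- as.matrix(d[cols])
  fold <- make_subject_folds(d, cv_folds, seed)
  fold_of_row <- fold[as.character(d$subject_id)]
  pos <- levels(y)[2L]

  accs <- f1s <- numeric(cv_folds)
  params <- vector("list", cv_folds)
  for (f in seq_len(cv_folds)) {
    tr <- fold_of_row != f
    te <- !tr
    if (!any(te)) pt_stop("empty test fold; use fewer folds")
    if (length(unique(y[tr])) < 2L || length(unique(y[te])) < 2L)
      pt_stop("a fold contains one class only; use fewer folds")
    best <- grid_search(x[tr, , drop = FALSE], y[tr], d$subject_id[tr],
                        model, seed = derive_seed(seed, 200L + f))
    sc <- fit_scaler(x[tr, , drop = FALSE])
    clf <- fit_clf(apply_scaler(x[tr, , drop = FALSE], sc), y[tr], model,
                   best, seed = derive_seed(seed, 300L + f))
    pred <- predict_clf(clf, apply_scaler(x[te, , drop = FALSE], sc))
    accs[f] <- mean(pred == y[te])
    f1s[f] <- f1_score(y[te], pred, pos)
    params[[f]] <- best
  }
  structure(list(model = model,
                 modality = if (modality == "all") "early_fusion" else modality,
                 avg_accuracy = mean(accs), avg_f1 = mean(f1s),
                 fold_accuracy = accs, fold_f1 = f1s,
                 fold_assignment = fold, params = params,
                 n_records = nrow(d), seed = seed),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s / %s: avg accuracy %.3f, avg F1 %.3f (%d folds, %d records)\n",
              x$modality, x$model, x$avg_accuracy, x$avg_f1,
              length(x$fold_accuracy), x$n_records))
  invisible(x)
}

#' Early fusion: one classifier on the concatenated feature vector
#'
#' Concatenates r-PPG and thermal features (complete cases in both
#' modalities) and evaluates as [train_eval()].
#'
#' @inheritParams train_eval
#' @return an `eval_result` with modality `early_fusion`.
#' @export
early_fusion_eval <- function(dataset, model = c("svm", "rf"), cv_folds = 5L,
                              seed = 1L) {
  train_eval(dataset, modality = "all", model = match.arg(model),
             cv_folds = cv_folds, seed = seed)
}

#' Late fusion: a decision tree over per-modality predictions
#'
#' Per outer fold, one base model per modality is grid-searched and fitted
#' on the training fold; a Gini-criterion decision tree (depth at most 2)
#' is then trained on the two base models' class probabilities — obtained
#' on the training rows by inner 3-fold cross-fitting so the tree never
#' sees resubstitution scores — and evaluated on the held-out fold.
#'
#' @param dataset a [fusion_dataset()] with both modalities present.
#' @param base_models named character: model per modality, e.g.
#'   `c(rppg = "svm", thermal = "rf")`.
#' @param cv_folds number of outer folds.
#' @param seed integer seed.
#' @return an `eval_result` with modality `late_fusion`.
#' @export
late_fusion_eval <- function(dataset, base_models = c(rppg = "svm", thermal = "rf"),
                             cv_folds = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "fusion_dataset"))
  mods <- c("rppg", "thermal")
  if (!all(mods %in% names(base_models)))
    pt_validation_error("base_models must name models for 'rppg' and 'thermal'")
  cols_by_mod <- lapply(stats::setNames(mods, mods), feature_cols, dataset = dataset)
  keep <- stats::complete.cases(dataset[unlist(cols_by_mod)])
  d <- dataset[keep, , drop = FALSE]
  y <- droplevels(d$label)
  if (nlevels(y) < 2L || min(table(y)) < 2L)
    pt_validation_error("need at least 2 records per class")
  fold <- make_subject_folds(d, cv_folds, seed)
  fold_of_row <- fold[as.character(d$subject_id)]
  pos <- levels(y)[2L]

  accs <- f1s <- numeric(cv_folds)
  for (f in seq_len(cv_folds)) {
    tr <- which(fold_of_row != f)
    te <- which(fold_of_row == f)
    if (!length(te)) pt_stop("empty test fold; use fewer folds")
    if (length(unique(y[tr])) < 2L || length(unique(y[te])) < 2L)
      pt_stop("a fold contains one class only; use fewer folds")
    train_p <- matrix(NA_real_, length(tr), 2L,
                      dimnames = list(NULL, paste0("p_", mods)))
    test_p <- matrix(NA_real_, length(te), 2L,
                     dimnames = list(NULL, paste0("p_", mods)))
    for (m in seq_along(mods)) {
      x <- as.matrix(d[cols_by_mod[[m]]])
      model <- base_models[[mods[m]]]
      best <- grid_search(x[tr, , drop = FALSE], y[tr], d$subject_id[tr],
                          model, seed = derive_seed(seed, 400L + 10L * f + m))
      # cross-fitted training probabilities (inner 3 folds by subject)
      subj_tr <- unique(d$subject_id[tr])
      withr::local_seed(derive_seed(seed, 500L + 10L * f + m))
      inner <- stats::setNames(rep_len(seq_len(3L), length(subj_tr)), sample(subj_tr))
      for (g in 1:3) {
        in_tr <- tr[inner[as.character(d$subject_id[tr])] != g]
        in_te_pos <- which(inner[as.character(d$subject_id[tr])] == g)
        if (!length(in_te_pos) || length(unique(y[in_tr])) < 2L) next
        sc <- fit_scaler(x[in_tr, , drop = FALSE])
        clf <- fit_clf(apply_scaler(x[in_tr, , drop = FALSE], sc), y[in_tr],
                       model, best, seed = derive_seed(seed, 600L + 100L * f + 10L * m + g))
        train_p[in_te_pos, m] <- predict_clf(
          clf, apply_scaler(x[tr[in_te_pos], , drop = FALSE], sc), type = "prob")
      }
      sc <- fit_scaler(x[tr, , drop = FALSE])
      clf <- fit_clf(apply_scaler(x[tr, , drop = FALSE], sc), y[tr], model,
                     best, seed = derive_seed(seed, 700L + 10L * f + m))
      test_p[, m] <- predict_clf(clf, apply_scaler(x[te, , drop = FALSE], sc),
                                 type = "prob")
    }
    ok <- stats::complete.cases(train_p)
    tree_df <- data.frame(label = y[tr][ok], train_p[ok, , drop = FALSE])
    set.seed(derive_seed(seed, 800L + f))
    tree <- rpart::rpart(label ~ ., data = tree_df, method = "class",
                         parms = list(split = "gini"),
                         control = rpart::rpart.control(maxdepth = 2L,
                                                        minsplit = 6L,
                                                        cp = 0.0, xval = 0L))
    pred <- factor(as.character(
      stats::predict(tree, data.frame(test_p), type = "class")),
      levels = levels(y))
    accs[f] <- mean(pred == y[te])
    f1s[f] <- f1_score(y[te], pred, pos)
  }
  structure(list(model = paste0("tree(", paste(base_models[mods], collapse = "+"), ")"),
                 modality = "late_fusion",
                 avg_accuracy = mean(accs), avg_f1 = mean(f1s),
                 fold_accuracy = accs, fold_f1 = f1s,
                 fold_assignment = fold, params = NULL,
                 n_records = nrow(d), seed = seed),
            class = "eval_result")
}

#' Fit a single final classifier on a whole dataset
#'
#' Grid-searches hyperparameters by grouped inner cross-validation on all
#' rows, then refits once; used as the model input for Shapley importance.
#'
#' @inheritParams train_eval
#' @param params optional one-row data frame of hyperparameters to skip the
#'   grid search.
#' @return object of class `pt_model` (predict with
#'   [predict.pt_model()]).
#' @export
fit_model <- function(dataset, modality = "all", model = c("svm", "rf"),
                      seed = 1L, params = NULL) {
  stopifnot(inherits(dataset, "fusion_dataset"))
  model <- match.arg(model)
  cols <- feature_cols(dataset, modality)
  keep <- stats::complete.cases(dataset[cols])
  d <- dataset[keep, , drop = FALSE]
  y <- droplevels(d$label)
  x <- as.matrix(d[cols])
  if (is.null(params))
    params <- grid_search(x, y, d$subject_id, model, seed = derive_seed(seed, 900L))
  sc <- fit_scaler(x)
  clf <- fit_clf(apply_scaler(x, sc), y, model, params,
                 seed = derive_seed(seed, 901L))
  structure(list(clf = clf, model = model, features = cols, scaler = sc,
                 params = params, levels = levels(y)),
            class = "pt_model")
}

#' Predict method for fitted pipeline classifiers
#'
#' @param object a `pt_model` from [fit_model()].
#' @param newdata data frame or matrix containing the model's feature
#'   columns.
#' @param type `"prob"` (positive-class probability) or `"class"`.
#' @param ... unused.
#' @return numeric probabilities or a factor of class labels.
#' @export
predict.pt_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(as.data.frame(newdata)[object$features])
  predict_clf(object$clf, apply_scaler(x, object$scaler), type = type)
}
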