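# Shapley-value feature importance by Monte-Carlo permutation sampling
# (Strumbelj & Kononenko estimator). For each explained instance and each
# sampled permutation, features are switched one at a time from a random
# background record to the instance; the change in the model's
# positive-class probability at the step where feature j is switched is an
# unbiased draw of j's Shapley contribution. A feature the model ignores
# changes no prediction, so its attribution is exactly zero.

#' Shapley-value feature importance
#'
#' Mean absolute Monte-Carlo Shapley value per feature for a fitted
#' classifier, on the model's positive-class probability scale, ranked
#' descending. The estimator is model-agnostic (applied identically to SVM
#' and random-forest models) and fully seeded. Features are processed in
#' canonical sorted order, so column order does not affect the report.
#'
#' @param model a `pt_model` from [fit_model()].
#' @param dataset a [fusion_dataset()] providing the instances to explain
#'   and the background distribution.
#' @param nsim permutations sampled per instance (default 30).
#' @param max_instances cap on explained instances (subsampled, seeded).
#' @param seed integer seed.
#' @return data frame of class `importance_report`: `feature`,
#'   `mean_abs_shap`, `rank`, `modality`.
#' @export
shap_importance <- function(model, dataset, nsim = 30L, max_instances = 60L,
                            seed = 1L) {
  stopifnot(inherits(model, "pt_model"), inherits(dataset, "fusion_dataset"))
  cols <- model$features
  keep <- stats::complete.cases(dataset[cols])
  X <- as.matrix(dataset[keep, cols, drop = FALSE])
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2L) pt_validation_error("need at least 2 rows to explain")

  withr::local_seed(derive_seed(seed, 61L))
  inst <- if (n > max_instances) sort(sample(n, max_instances)) else seq_len(n)
  ni <- length(inst)

  # Build every perturbed row up front, then predict once in a batch:
  # for instance i and permutation s, rows walk from a background record z
  # to x_i adding one feature per step ((p + 1) rows per walk).
  n_walk <- ni * nsim
  big <- matrix(NA_real_, n_walk * (p + 1L), p, dimnames = list(NULL, cols))
  perm_store <- matrix(NA_integer_, n_walk, p)
  r <- 0L
  w <- 0L
  for (i in inst) {
    for (s in seq_len(nsim)) {
      w <- w + 1L
      z <- X[sample(n, 1L), ]
      perm <- sample.int(p)
      perm_store[w, ] <- perm
      cur <- z
      big[r + 1L, ] <- cur
      for (k in seq_len(p)) {
        cur[perm[k]] <- X[i, perm[k]]
        big[r + 1L + k, ] <- cur
      }
      r <- r + p + 1L
    }
  }
  pr <- predict(model, big, type = "prob")

  contrib <- matrix(0, ni, p, dimnames = list(NULL, cols))
  r <- 0L
  w <- 0L
  for (ii in seq_len(ni)) {
    for (s in seq_len(nsim)) {
      w <- w + 1L
      steps <- pr[(r + 2L):(r + p + 1L)] - pr[(r + 1L):(r + p)]
      contrib[ii, perm_store[w, ]] <- contrib[ii, perm_store[w, ]] + steps
      r <- r + p + 1L
    }
  }
  contrib <- contrib / nsim
  imp <- colMeans(abs(contrib))
  mod_tag <- attr(dataset, "modality")[cols]
  out <- data.frame(feature = cols, mean_abs_shap = as.numeric(imp),
                    modality = as.character(mod_tag), row.names = NULL)
  out <- out[order(-out$mean_abs_shap, out$feature), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  structure(out[c("feature", "mean_abs_shap", "rank", "modality")],
            class = c("importance_report", "data.frame"))
}

#' @export
print.importance_report <- function(x, n = 10L, ...) {
  cat(sprintf("<importance_report> %d features; top %d:\n", nrow(x), min(n, nrow(x))))
  print(utils::head(as.data.frame(x), n), digits = 4, row.names = FALSE)
  invisible(x)
}
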