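## Model-based feature-importance framework: LASSO stability selection,
## random-forest importance, [0,1] rescaling with mean aggregation, and
## k-fold MSE benchmarking of competing feature sets.

#' LASSO stability selection frequencies
#'
#' Repeatedly fits an L1-penalized linear model on random half-subsamples of
#' the rows across a grid of penalties; a feature's score is the fraction of
#' (subsample, lambda) fits in which its coefficient is nonzero.
#'
#' @param X numeric matrix, observations x features (>= 20 rows).
#' @param y numeric response (e.g. allelic logSkew).
#' @param n_subsamples number of subsamples (>= 50).
#' @param subsample_fraction fraction of rows per subsample, without
#'   replacement.
#' @param lambda_grid penalty grid; default 20 log-spaced values taken from a
#'   full-data glmnet path.
#' @param seed RNG seed.
#' @return named numeric vector of selection frequencies in \[0, 1\].
#' @export
stability_selection <- function(X, y, n_subsamples = 100, subsample_fraction = 0.5,
                                lambda_grid = NULL, seed = 1) {
  X <- as.matrix(X)
  assert_that(nrow(X) >= 20, "need at least 20 observations")
  assert_that(n_subsamples >= 50, "need at least 50 subsamples")
  assert_that(sd(y) > 0, "degenerate response: y is constant")
  if (is.null(lambda_grid)) {
    # the sparse upper decade of the path: stability selection counts
    # selections where the penalty still enforces sparsity, not the
    # near-OLS tail where every feature enters
    lmax <- max(glmnet::glmnet(X, y, alpha = 1)$lambda)
    lambda_grid <- exp(seq(log(lmax), log(0.3 * lmax), length.out = 20))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  m <- floor(subsample_fraction * nrow(X))
  assert_that(m >= 2, "subsample too small")
  counts <- numeric(ncol(X))
  with_seed(seed, {
    for (b in seq_len(n_subsamples)) {
      idx <- sample.int(nrow(X), m)
      fit <- glmnet::glmnet(X[idx, , drop = FALSE], y[idx], alpha = 1,
                            lambda = lambda_grid)
      beta <- as.matrix(fit$beta)  # features x lambdas
      counts <- counts + rowSums(beta != 0)
    }
  })
  freq <- counts / (n_subsamples * length(lambda_grid))
  names(freq) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  freq
}

#' Random-forest regression feature importance
#'
#' Impurity-based importance from a random-forest regressor, normalized to
#' sum to one.
#'
#' @inheritParams stability_selection
#' @param n_trees number of trees.
#' @return named nonnegative numeric vector summing to 1.
#' @export
rf_importance <- function(X, y, n_trees = 500, seed = 1) {
  X <- as.matrix(X)
  assert_that(sd(y) > 0, "degenerate response: y is constant")
  fit <- with_seed(seed, randomForest::randomForest(x = X, y = y, ntree = n_trees,
                                                    importance = FALSE))
  imp <- fit$importance[, "IncNodePurity"]
  imp <- pmax(imp, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
  names(imp) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  imp
}

#' Combine selection methods into one importance ranking
#'
#' Each method's scores are min-max scaled to \[0, 1\] and averaged; the
#' overall ranking sorts by mean importance descending with lexicographic
#' tie-breaks on feature id.
#'
#' @param stability named frequency vector from [stability_selection()].
#' @param rf named importance vector from [rf_importance()] (same features).
#' @return data frame of class `importance_report` with columns `tf_id`,
#'   `stability_frequency`, `stability_scaled`, `rf_importance`,
#'   `rf_importance_scaled`, `mean_importance`, sorted by the overall ranking.
#' @export
combine_importance <- function(stability, rf) {
  assert_that(length(stability) == length(rf), "method vectors must align")
  ids <- names(stability) %||% paste0("f", seq_along(stability))
  if (!is.null(names(rf))) {
    assert_that(setequal(ids, names(rf)), "feature ids disagree between methods")
    rf <- rf[ids]
  }
  s_scaled <- minmax_scale(stability)
  r_scaled <- minmax_scale(rf)
  mean_imp <- (s_scaled + r_scaled) / 2
  out <- data.frame(tf_id = ids,
                    stability_frequency = as.numeric(stability),
                    stability_scaled = s_scaled,
                    rf_importance = as.numeric(rf),
                    rf_importance_scaled = r_scaled,
                    mean_importance = mean_imp,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_importance, out$tf_id), ]
  rownames(out) <- NULL
  class(out) <- c("importance_report", "data.frame")
  out
}

fit_predict_regressor <- function(model, X_train, y_train, X_test, seed) {
  switch(model,
    lasso = {
      # extend the path far below the default floor so the noiseless limit
      # can reach an (essentially) unpenalized fit when CV favors it
      lmax <- max(glmnet::glmnet(X_train, y_train, alpha = 1)$lambda)
      grid <- exp(seq(log(lmax), log(lmax * 1e-8), length.out = 100))
      cv <- with_seed(seed, glmnet::cv.glmnet(X_train, y_train, alpha = 1,
                                              lambda = grid, nfolds = 5))
      as.numeric(predict(cv, X_test, s = "lambda.min"))
    },
    svr = {
      fit <- e1071::svm(x = X_train, y = y_train, type = "eps-regression")
      as.numeric(predict(fit, X_test))
    },
    random_forest = {
      fit <- with_seed(seed, randomForest::randomForest(x = X_train, y = y_train,
                                                        ntree = 300))
      as.numeric(predict(fit, X_test))
    },
    stop_gram(sprintf("unknown model: %s", model))
  )
}

#' Benchmark feature sets by cross-validated MSE
#'
#' Fits LASSO, SVR and/or random-forest regressors on each candidate feature
#' set under a shared k-fold split and reports the mean squared error of the
#' held-out predictions, for comparing e.g. binding-score features against
#' scores imported from other variant-prioritization tools.
#'
#' @param feature_sets named list of numeric matrices sharing row order.
#' @param y numeric response (e.g. logSkew).
#' @param models subset of `c("lasso", "svr", "random_forest")`.
#' @param k number of folds (>= 2).
#' @param seed RNG seed for the shared fold split and the fits.
#' @return data frame `feature_set`, `model`, `mse`.
#' @export
benchmark_feature_sets <- function(feature_sets, y,
                                   models = c("lasso", "svr", "random_forest"),
                                   k = 5, seed = 1) {
  assert_that(k >= 2, "k must be >= 2")
  assert_that(is.list(feature_sets) && !is.null(names(feature_sets)),
              "feature_sets must be a named list of matrices")
  nr <- unique(vapply(feature_sets, nrow, integer(1)))
  assert_that(length(nr) == 1 && nr == length(y),
              "all feature sets must share variant rows aligned with y")
  models <- match.arg(models, several.ok = TRUE)
  fold <- make_folds(paste0("row", seq_len(nr)), k = k, seed = seed)$fold
  res <- list()
  for (set_name in names(feature_sets)) {
    X <- as.matrix(feature_sets[[set_name]])
    for (model in models) {
      pred <- numeric(nr)
      for (f in seq_len(k)) {
        test <- which(fold == f)
        pred[test] <- fit_predict_regressor(model, X[-test, , drop = FALSE],
                                            y[-test], X[test, , drop = FALSE],
                                            seed = seed + f)
      }
      res[[length(res) + 1L]] <- data.frame(feature_set = set_name, model = model,
                                            mse = mean((pred - y)^2),
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
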