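## The three-step model core: F1 (universal regulatory activity), F2 (cell
## type modifiers, binding and expression arms), F3 (L1-regularized logistic
## integration), plus the dataset container and full training driver.

#' Model configuration
#'
#' Collects the tunable parameters of the three-step model in one place.
#'
#' @param n_trees trees per random forest (default 500).
#' @param min_node minimum terminal-node size of the probability trees.
#' @param seed base RNG seed recorded in the bundle.
#' @param activity_mode `"count_test"` (default; fold change gated by a count
#'   test, the right choice for read-count assays) or `"fold_change"` (the
#'   plain rule used for fluorescence readouts) for step-1 labels.
#' @param fc_cutoff activity fold-change cutoff (default 1.5).
#' @param alpha significance level for count tests (default 0.05).
#' @param lower_q,upper_q Vodds quantile boundaries for modifier labels.
#' @param skew_threshold emVAR filter on `|logSkew|`; default
#'   `|log2(1.5)| = 0.5849`.
#' @param key_allele allele keying the expression reordering. The default
#'   `"max"` ranks TFs by their strongest binding on either allele, so a TF
#'   whose motif is created by the variant still reaches a top rank; `"ref"`
#'   and `"alt"` restrict the key to one allele.
#' @param eps probability clip for the odds feature.
#' @param lambda_grid optional penalty grid for step 3 (default: glmnet path).
#' @param step3_cv_k folds for the inner lambda selection.
#' @return a `gram_config` list.
#' @export
gram_config <- function(n_trees = 500, min_node = 10, seed = 1,
                        activity_mode = c("count_test", "fold_change"),
                        fc_cutoff = 1.5, alpha = 0.05,
                        lower_q = 0.25, upper_q = 0.75,
                        skew_threshold = abs(log2(1.5)),
                        key_allele = c("max", "ref", "alt"),
                        eps = 1e-6, lambda_grid = NULL, step3_cv_k = 10) {
  structure(list(n_trees = n_trees, min_node = min_node, seed = seed,
                 activity_mode = match.arg(activity_mode),
                 fc_cutoff = fc_cutoff, alpha = alpha,
                 lower_q = lower_q, upper_q = upper_q,
                 skew_threshold = skew_threshold,
                 key_allele = match.arg(key_allele),
                 eps = eps, lambda_grid = lambda_grid,
                 step3_cv_k = step3_cv_k),
            class = "gram_config")
}

#' Assemble a training dataset from binding scores, expression and counts
#'
#' Derives all labels the three steps need from the MPRA count tables:
#' per-allele activity calls, logSkew and Vodds per (variant, cell type),
#' quantile-based modifier labels (computed within each cell type), and emVAR
#' labels. emVAR labels may also be supplied directly (e.g. externally
#' computed calls, or simulation ground truth); otherwise they are called
#' from the counts via a two-sided Fisher test on the 2x2 table combined with
#' the `|logSkew|` filter.
#'
#' @param bsm a `binding_scores` object covering all counted variants.
#' @param expression an `expression_profiles` matrix whose rows are the cell
#'   types appearing in `counts`.
#' @param counts an `mpra_counts` data frame.
#' @param emvar_labels optional data frame `variant_id`, `cell_type`,
#'   `is_emvar` overriding the count-based calls.
#' @param config a [gram_config()].
#' @return a `gram_dataset` list with elements `bsm`, `expression`, `counts`,
#'   `activity`, `stats`, `modifier`, `labels`, `config`.
#' @export
gram_dataset <- function(bsm, expression, counts, emvar_labels = NULL,
                         config = gram_config()) {
  counts <- mpra_counts(counts)
  missing_v <- setdiff(counts$variant_id, variant_ids(bsm))
  assert_that(length(missing_v) == 0,
              sprintf("counts reference variants absent from binding scores: %s",
                      paste(head(missing_v, 5), collapse = ", ")))
  missing_c <- setdiff(unique(counts$cell_type), rownames(expression))
  assert_that(length(missing_c) == 0,
              sprintf("cell type(s) missing from expression profiles: %s",
                      paste(missing_c, collapse = ", ")))
  activity <- call_activity(counts, mode = config$activity_mode,
                            fc_cutoff = config$fc_cutoff, alpha = config$alpha)
  stats_df <- data.frame(variant_id = counts$variant_id,
                         cell_type = counts$cell_type,
                         log_skew = log_skew(counts),
                         vodds = vodds(counts),
                         stringsAsFactors = FALSE)
  modifier <- do.call(rbind, lapply(split(stats_df, stats_df$cell_type), function(d) {
    ml <- modifier_labels(setNames(d$vodds, d$variant_id),
                          lower_q = config$lower_q, upper_q = config$upper_q)
    data.frame(variant_id = ml$variant_id, cell_type = d$cell_type[1],
               vodds = ml$vodds, klass = ml$klass, stringsAsFactors = FALSE)
  }))
  rownames(modifier) <- NULL
  if (is.null(emvar_labels)) {
    signif <- vapply(seq_len(nrow(counts)), function(i) {
      tab <- round(matrix(c(counts$n1[i], counts$n2[i], counts$n3[i], counts$n4[i]), 2))
      fisher.test(tab)$p.value < config$alpha
    }, logical(1))
    em <- label_emvar(stats_df$log_skew, signif, config$skew_threshold)
    labels <- data.frame(variant_id = counts$variant_id,
                         cell_type = counts$cell_type,
                         is_emvar = em$is_emvar, stringsAsFactors = FALSE)
  } else {
    assert_that(all(c("variant_id", "cell_type", "is_emvar") %in% names(emvar_labels)),
                "emvar_labels needs variant_id, cell_type, is_emvar")
    labels <- merge(counts[, c("variant_id", "cell_type")], emvar_labels,
                    by = c("variant_id", "cell_type"), sort = FALSE)
    assert_that(nrow(labels) == nrow(counts), "emvar_labels do not cover all counted rows")
  }
  structure(list(bsm = bsm, expression = expression, counts = counts,
                 activity = activity, stats = stats_df, modifier = modifier,
                 labels = labels, config = config),
            class = "gram_dataset")
}

#' @export
print.gram_dataset <- function(x, ...) {
  cat(sprintf("<gram_dataset> %d variants, %d TFs, %d cell type(s), %d emVAR-positive rows\n",
              length(unique(x$counts$variant_id)), length(tf_ids(x$bsm)),
              length(unique(x$counts$cell_type)), sum(x$labels$is_emvar)))
  invisible(x)
}

as_class_factor <- function(y, levels) {
  if (is.logical(y)) y <- ifelse(y, levels[2], levels[1])
  y <- factor(y, levels = levels)
  assert_that(!anyNA(y), "labels contain values outside the expected classes")
  assert_that(nlevels(droplevels(y)) == 2, "both classes must be present")
  y
}

## Probability random forest shared by steps 1 and 2. The forest's output is
## consumed as a probability (it feeds the log-odds feature and the logistic
## integration), so trees are grown as probability trees (per-leaf class
## frequencies, Malley-style) rather than majority voters.
fit_prob_forest <- function(X, y, n_trees, seed, min_node = 10) {
  X <- as.matrix(X)
  ranger::ranger(x = X, y = y, probability = TRUE, num.trees = n_trees,
                 mtry = max(1L, floor(sqrt(ncol(X)))),
                 min.node.size = min_node, seed = seed,
                 num.threads = 1)
}

predict_prob <- function(forest, X, positive) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  as.numeric(predict(forest, as.matrix(X), num.threads = 1)$predictions[, positive])
}

#' Fit step 1: the universal regulatory-activity classifier
#'
#' A random-forest probability classifier over TF binding-score vectors of
#' individual alleles; its predicted probability of the active class is the
#' universal score U in \[0, 1\], independent of cell type.
#'
#' @param X numeric matrix, (variant, allele) instances x TFs.
#' @param y activity labels: logical, or factor with levels
#'   `c("inactive", "active")`.
#' @param n_trees number of trees.
#' @param seed RNG seed.
#' @param min_node minimum terminal-node size of the probability trees
#'   (larger values smooth the probability estimates).
#' @return a fitted `ranger` probability forest.
#' @export
fit_step1 <- function(X, y, n_trees = 500, seed = 1, min_node = 10) {
  y <- as_class_factor(y, c("inactive", "active"))
  fit_prob_forest(X, y, n_trees, seed, min_node)
}

#' Predict the universal activity score U
#'
#' @param f1 fitted step-1 classifier.
#' @param X numeric matrix (or single feature vector) of binding scores.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict_U <- function(f1, X) {
  predict_prob(f1, X, "active")
}

#' The absolute allelic log-odds feature
#'
#' `|log2( (U_mut/(1-U_mut)) / (U_wt/(1-U_wt)) )|` with both probabilities
#' clipped to `[eps, 1-eps]` so the value is always finite. Symmetric under
#' swapping the two alleles; zero iff the clipped probabilities are equal.
#'
#' @param u_mut,u_wt universal scores of the alternative and reference allele.
#' @param eps clip width in (0, 0.5).
#' @return nonnegative numeric vector.
#' @export
odds_feature <- function(u_mut, u_wt, eps = 1e-6) {
  assert_that(eps > 0 && eps < 0.5, "eps must be in (0, 0.5)")
  um <- pmin(pmax(u_mut, eps), 1 - eps)
  uw <- pmin(pmax(u_wt, eps), 1 - eps)
  abs(log2((um / (1 - um)) / (uw / (1 - uw))))
}

#' Fit step 2: a cell-type-modifier classifier
#'
#' A random-forest classifier trained on the high- vs low-variability classes
#' (top vs bottom Vodds quantiles). Fit once on TF binding scores (the S_b
#' arm) and once on rank-reordered TF expression (the S_e arm).
#'
#' @param X numeric matrix, (variant, cell) rows x features.
#' @param y modifier classes: logical (`TRUE` = high), or factor with levels
#'   `c("low", "high")`; `excluded` rows must be dropped beforehand.
#' @param n_trees number of trees.
#' @param seed RNG seed.
#' @param min_node minimum terminal-node size of the probability trees.
#' @return a fitted `ranger` probability forest.
#' @export
fit_step2 <- function(X, y, n_trees = 500, seed = 1, min_node = 10) {
  y <- as_class_factor(y, c("low", "high"))
  fit_prob_forest(X, y, n_trees, seed, min_node)
}

#' Predict a modifier score S in \[0, 1\]
#'
#' @param f2 fitted step-2 classifier.
#' @param X feature matrix or vector.
#' @return probability of the high-variability class.
#' @export
predict_S <- function(f2, X) {
  predict_prob(f2, X, "high")
}

binomial_deviance <- function(y, p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

ls_logit_fit <- function(X, y, lambda) {
  ## Literal squared-error-with-logit-link objective:
  ## 1/(2V) * sum((plogis(Xb) - y)^2) + lambda * sum(|b_slopes|),
  ## minimized quasi-Newton with a smoothed absolute value.
  obj <- function(b) {
    eta <- drop(cbind(1, X) %*% b)
    mean((plogis(eta) - y)^2) / 2 + lambda * sum(sqrt(b[-1]^2 + 1e-10))
  }
  fit <- optim(rep(0, ncol(X) + 1), obj, method = "BFGS",
               control = list(maxit = 500))
  fit$par
}

#' Fit step 3: L1-regularized logistic integration
#'
#' Fits the final model `M = logistic(b_u * Odds + b_s1 * S_b + b_s2 * S_e +
#' b0)` with an L1 penalty on the slopes, choosing the penalty that minimizes
#' the mean k-fold cross-validated error over the grid. The default
#' `"logistic"` objective is penalized maximum likelihood (glmnet); the
#' `"ls_logit"` objective minimizes the squared error between the logistic
#' prediction and the 0/1 labels directly.
#'
#' @param odds,s_b,s_e aligned feature vectors over (variant, cell) rows.
#' @param y emVAR labels (logical or 0/1).
#' @param lambda_grid penalty grid; default: the glmnet path on the full data.
#' @param k folds for the lambda selection (default 10).
#' @param seed RNG seed for the fold split.
#' @param objective `"logistic"` (default) or `"ls_logit"`.
#' @return list of class `gram_step3` with `b_u`, `b_s1`, `b_s2`, `b0`,
#'   `lambda`, `cv_error` (mean CV error per grid value), `lambda_grid`,
#'   `objective`.
#' @export
fit_step3 <- function(odds, s_b, s_e, y, lambda_grid = NULL, k = 10, seed = 1,
                      objective = c("logistic", "ls_logit")) {
  objective <- match.arg(objective)
  y <- as.numeric(y)
  assert_that(all(y %in% c(0, 1)), "y must be binary")
  assert_that(length(unique(y)) == 2, "both classes must be present")
  X <- cbind(odds = odds, s_b = s_b, s_e = s_e)
  assert_that(!anyNA(X), "features contain missing values")
  if (!is.null(lambda_grid)) assert_that(length(lambda_grid) > 0, "empty lambda grid")
  if (is.null(lambda_grid)) {
    lambda_grid <- glmnet::glmnet(X, y, family = "binomial", alpha = 1)$lambda
  }
  lambda_grid <- sort(unique(lambda_grid), decreasing = TRUE)
  k <- min(k, length(y))
  fold <- make_folds(paste0("row", seq_along(y)), k = k, seed = seed)$fold
  cv_err <- matrix(NA_real_, nrow = k, ncol = length(lambda_grid))
  for (f in seq_len(k)) {
    test <- which(fold == f)
    if (length(unique(y[-test])) < 2) next
    if (objective == "logistic") {
      fit <- glmnet::glmnet(X[-test, , drop = FALSE], y[-test], family = "binomial",
                            alpha = 1, lambda = lambda_grid)
      p <- predict(fit, X[test, , drop = FALSE], type = "response")
      for (j in seq_len(ncol(p))) cv_err[f, j] <- binomial_deviance(y[test], p[, j])
      if (ncol(p) < length(lambda_grid)) cv_err[f, seq(ncol(p) + 1, length(lambda_grid))] <- Inf
    } else {
      for (j in seq_along(lambda_grid)) {
        b <- ls_logit_fit(X[-test, , drop = FALSE], y[-test], lambda_grid[j])
        p <- plogis(drop(cbind(1, X[test, , drop = FALSE]) %*% b))
        cv_err[f, j] <- mean((p - y[test])^2)
      }
    }
  }
  mean_err <- colMeans(cv_err, na.rm = TRUE)
  best <- which.min(mean_err)
  lambda_star <- lambda_grid[best]
  if (objective == "logistic") {
    full <- glmnet::glmnet(X, y, family = "binomial", alpha = 1, lambda = lambda_grid)
    cf <- as.numeric(coef(full, s = lambda_star))
  } else {
    b <- ls_logit_fit(X, y, lambda_star)
    cf <- b
  }
  structure(list(b0 = cf[1], b_u = cf[2], b_s1 = cf[3], b_s2 = cf[4],
                 lambda = lambda_star, cv_error = mean_err,
                 lambda_grid = lambda_grid, objective = objective),
            class = "gram_step3")
}

## --- full training driver -------------------------------------------------

## Out-of-bag probability of the positive class for the rows a forest was
## trained on. In-sample predictions of a random forest are biased toward
## the training labels; stacking step 3 on them would mismatch the honest
## probabilities seen at predict time, so all step-3 training features come
## from OOB predictions.
oob_prob <- function(forest, positive) {
  as.numeric(forest$predictions[, positive])
}

## Fit all three steps on the subset of a dataset restricted to `variants`.
## Shared by train_full (all variants) and cross_validate (per-fold).
fit_gram_models <- function(dataset, variants, config) {
  bsm <- dataset$bsm
  act <- dataset$activity[dataset$activity$variant_id %in% variants, ]
  act <- act[order(act$allele != "ref"), ]  # ref block first, then alt
  X1 <- rbind(bsm$scores_ref[act$variant_id[act$allele == "ref"], , drop = FALSE],
              bsm$scores_alt[act$variant_id[act$allele == "alt"], , drop = FALSE])
  y1 <- c(act$active[act$allele == "ref"], act$active[act$allele == "alt"])
  f1 <- fit_step1(X1, y1, n_trees = config$n_trees, seed = config$seed,
                  min_node = config$min_node %||% 10)

  mod <- dataset$modifier[dataset$modifier$variant_id %in% variants &
                            dataset$modifier$klass != "excluded", ]
  X2b <- bsm$scores_ref[mod$variant_id, , drop = FALSE]
  f2b <- fit_step2(X2b, mod$klass == "high", n_trees = config$n_trees,
                   seed = config$seed + 1, min_node = config$min_node %||% 10)
  X2e <- reordered_pairs_matrix(bsm, dataset$expression, mod$variant_id,
                                mod$cell_type, config$key_allele)
  f2e <- fit_step2(X2e, mod$klass == "high", n_trees = config$n_trees,
                   seed = config$seed + 2, min_node = config$min_node %||% 10)

  # step-3 training features: OOB for rows the forests saw, honest predict
  # for the rest, aggregated per (variant [, cell]) by mean
  u_oob <- oob_prob(f1, "active")
  u_key <- paste(act$variant_id, act$allele)
  u_by <- tapply(u_oob, u_key, mean)
  lab <- dataset$labels[dataset$labels$variant_id %in% variants, ]
  u_wt <- as.numeric(u_by[paste(lab$variant_id, "ref")])
  u_mut <- as.numeric(u_by[paste(lab$variant_id, "alt")])
  # rows never out of bag (possible at tiny tree counts) fall back to predict
  if (anyNA(u_wt)) {
    nas <- which(is.na(u_wt))
    u_wt[nas] <- predict_U(f1, bsm$scores_ref[lab$variant_id[nas], , drop = FALSE])
  }
  if (anyNA(u_mut)) {
    nas <- which(is.na(u_mut))
    u_mut[nas] <- predict_U(f1, bsm$scores_alt[lab$variant_id[nas], , drop = FALSE])
  }
  odds <- odds_feature(u_mut, u_wt, eps = config$eps)

  mod_key <- paste(mod$variant_id, mod$cell_type)
  lab_key <- paste(lab$variant_id, lab$cell_type)
  sb_oob <- setNames(oob_prob(f2b, "high"), mod_key)
  se_oob <- setNames(oob_prob(f2e, "high"), mod_key)
  in_mod <- lab_key %in% mod_key
  s_b <- s_e <- numeric(nrow(lab))
  s_b[in_mod] <- sb_oob[lab_key[in_mod]]
  s_e[in_mod] <- se_oob[lab_key[in_mod]]
  if (anyNA(s_b[in_mod])) {  # rows never out of bag
    nas <- which(in_mod & !is.finite(s_b))
    s_b[nas] <- predict_S(f2b, bsm$scores_ref[lab$variant_id[nas], , drop = FALSE])
  }
  if (anyNA(s_e[in_mod])) {
    nas <- which(in_mod & !is.finite(s_e))
    Xe_na <- reordered_pairs_matrix(bsm, dataset$expression, lab$variant_id[nas],
                                    lab$cell_type[nas], config$key_allele)
    s_e[nas] <- predict_S(f2e, Xe_na)
  }
  if (any(!in_mod)) {
    s_b[!in_mod] <- predict_S(f2b, bsm$scores_ref[lab$variant_id[!in_mod], , drop = FALSE])
    Xe <- reordered_pairs_matrix(bsm, dataset$expression, lab$variant_id[!in_mod],
                                 lab$cell_type[!in_mod], config$key_allele)
    s_e[!in_mod] <- predict_S(f2e, Xe)
  }
  f3 <- fit_step3(odds, s_b, s_e, lab$is_emvar,
                  lambda_grid = config$lambda_grid, k = config$step3_cv_k,
                  seed = config$seed + 3)
  list(f1 = f1, f2b = f2b, f2e = f2e, f3 = f3)
}

## Reordered-expression design for explicit (variant, cell) pairs.
reordered_pairs_matrix <- function(bsm, expr, variants, cells, key_allele) {
  tfs <- tf_ids(bsm)
  e <- expr[, tfs, drop = FALSE]
  out <- matrix(NA_real_, nrow = length(variants), ncol = length(tfs))
  ords <- list()
  for (i in seq_along(variants)) {
    v <- variants[i]
    ord <- ords[[v]]
    if (is.null(ord)) {
      ord <- binding_rank_order(bsm, v, key_allele)
      ords[[v]] <- ord
    }
    out[i, ] <- e[cells[i], ord]
  }
  colnames(out) <- paste0("rank_", seq_along(tfs))
  out
}

#' Train the full three-step model
#'
#' Runs step 1 (universal activity forest on pooled allele instances), step 2
#' (both modifier arms on the high/low Vodds classes) and step 3 (penalized
#' logistic integration) on the whole dataset and packages the result.
#'
#' @param dataset a [gram_dataset()].
#' @param config a [gram_config()]; defaults to the dataset's own config.
#' @return a `gram_model` bundle: fitted submodels, step-3 coefficients,
#'   penalty, feature schema (TF ids, key allele, eps) and training metadata.
#' @export
train_full <- function(dataset, config = dataset$config) {
  fits <- fit_gram_models(dataset, unique(dataset$counts$variant_id), config)
  structure(list(step1 = fits$f1,
                 step2_binding = fits$f2b,
                 step2_expression = fits$f2e,
                 step3 = fits$f3,
                 tf_ids = tf_ids(dataset$bsm),
                 key_allele = config$key_allele,
                 eps = config$eps,
                 metadata = list(seed = config$seed, n_trees = config$n_trees,
                                 n_variants = length(unique(dataset$counts$variant_id)),
                                 cell_types = unique(dataset$counts$cell_type),
                                 format_version = "1.0")),
            class = "gram_model")
}

#' @export
print.gram_model <- function(x, ...) {
  cat(sprintf("<gram_model> %d TFs; b_u=%.3f b_s1=%.3f b_s2=%.3f b0=%.3f lambda=%.4g\n",
              length(x$tf_ids), x$step3$b_u, x$step3$b_s1, x$step3$b_s2,
              x$step3$b0, x$step3$lambda))
  invisible(x)
}

#' Score variants in cellular contexts with a trained model
#'
#' Computes, for each (variant, sample) pair: the universal scores of both
#' alleles, the absolute log-odds feature, both modifier scores, and the
#' final molecular-effect score
#' `M = logistic(b_u * Odds + b_s1 * S_b + b_s2 * S_e + b0)`.
#'
#' @param bundle a trained `gram_model`.
#' @param bsm a `binding_scores` object (aligned to the bundle schema by TF
#'   id; column order is irrelevant).
#' @param expression an `expression_profiles` matrix; its rows are the
#'   samples / cell types to score.
#' @param variants variant ids to score (default: all in `bsm`).
#' @param samples sample ids to score (default: all rows of `expression`).
#' @return data frame with one row per (variant, sample): `variant_id`,
#'   `sample_id`, `U_wt`, `U_mut`, `odds`, `S_b`, `S_e`, `M`.
#' @export
predict_gram <- function(bundle, bsm, expression, variants = NULL, samples = NULL) {
  bsm <- align_binding(bsm, bundle$tf_ids)
  variants <- variants %||% variant_ids(bsm)
  samples <- samples %||% rownames(expression)
  unknown <- setdiff(variants, variant_ids(bsm))
  assert_that(length(unknown) == 0,
              sprintf("unknown variant id(s): %s", paste(unknown, collapse = ", ")))
  missing_tfs <- setdiff(bundle$tf_ids, colnames(expression))
  assert_that(length(missing_tfs) == 0,
              sprintf("expression profiles missing TF(s): %s",
                      paste(head(missing_tfs, 5), collapse = ", ")))
  u_wt <- setNames(predict_U(bundle$step1, bsm$scores_ref[variants, , drop = FALSE]), variants)
  u_mut <- setNames(predict_U(bundle$step1, bsm$scores_alt[variants, , drop = FALSE]), variants)
  odds <- odds_feature(u_mut, u_wt, eps = bundle$eps)
  s_b <- setNames(predict_S(bundle$step2_binding,
                            bsm$scores_ref[variants, , drop = FALSE]), variants)
  grid <- expand.grid(sample_id = samples, variant_id = variants,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("variant_id", "sample_id")]
  Xe <- reordered_pairs_matrix(bsm, expression, grid$variant_id, grid$sample_id,
                               bundle$key_allele)
  s_e <- predict_S(bundle$step2_expression, Xe)
  cf <- bundle$step3
  out <- data.frame(variant_id = grid$variant_id,
                    sample_id = grid$sample_id,
                    U_wt = u_wt[grid$variant_id],
                    U_mut = u_mut[grid$variant_id],
                    odds = odds[grid$variant_id],
                    S_b = s_b[grid$variant_id],
                    S_e = s_e,
                    stringsAsFactors = FALSE)
  out$M <- plogis(cf$b_u * out$odds + cf$b_s1 * out$S_b + cf$b_s2 * out$S_e + cf$b0)
  rownames(out) <- NULL
  out
}
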