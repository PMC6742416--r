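## Leakage-free multi-step cross-validation and ranking metrics.

#' Partition variants into k folds
#'
#' Variants are randomly permuted under `seed` and chunked contiguously into
#' k folds whose sizes differ by at most one. All rows belonging to a variant
#' (both alleles, every cell type or sample) share its fold, which is what
#' makes the multi-step cross-validation leakage-free.
#'
#' @param variant_ids character vector of unique variant ids.
#' @param k number of folds (default 10).
#' @param seed RNG seed.
#' @return list of class `fold_assignment` with `fold` (named integer vector
#'   over variants), `k`, `seed`.
#' @export
make_folds <- function(variant_ids, k = 10, seed = 1) {
  variant_ids <- as.character(variant_ids)
  assert_that(!anyDuplicated(variant_ids), "variant ids must be unique")
  v <- length(variant_ids)
  assert_that(k >= 2, "k must be >= 2")
  assert_that(k <= v, "k exceeds the number of variants")
  perm <- with_seed(seed, sample(variant_ids))
  sizes <- rep(v %/% k, k)
  if (v %% k > 0) sizes[seq_len(v %% k)] <- sizes[seq_len(v %% k)] + 1L
  fold <- integer(v)
  names(fold) <- perm
  fold[] <- rep(seq_len(k), times = sizes)
  fold <- fold[variant_ids]
  structure(list(fold = fold, k = k, seed = seed), class = "fold_assignment")
}

#' Area under the ROC curve
#'
#' Mann-Whitney U statistic normalized by `n_pos * n_neg`, i.e. the
#' probability that a random positive outranks a random negative, with 0.5
#' credit for ties.
#'
#' @param scores numeric predictions (higher = more positive).
#' @param labels binary labels (logical or 0/1).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  assert_that(n_pos > 0 && n_neg > 0, "need both classes to compute AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-interpolated integration (average precision): scores are sorted
#' descending and precision is accumulated at each recall increment, with
#' tied scores processed as one block.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  assert_that(n_pos > 0, "need at least one positive to compute AUPRC")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # collapse tied scores into blocks so ties don't depend on input order
  blocks <- rle(s)$lengths
  tp <- fp <- 0
  ap <- 0
  i <- 1L
  for (b in blocks) {
    idx <- seq.int(i, i + b - 1L)
    d_tp <- sum(y[idx]); d_fp <- b - d_tp
    tp <- tp + d_tp; fp <- fp + d_fp
    precision <- tp / (tp + fp)
    ap <- ap + d_tp / n_pos * precision
    i <- i + b
  }
  ap
}

check_fold_classes <- function(dataset, train_variants) {
  act <- dataset$activity$active[dataset$activity$variant_id %in% train_variants]
  mod <- dataset$modifier[dataset$modifier$variant_id %in% train_variants &
                            dataset$modifier$klass != "excluded", ]
  lab <- dataset$labels$is_emvar[dataset$labels$variant_id %in% train_variants]
  length(unique(act)) == 2 &&
    length(unique(mod$klass)) == 2 &&
    length(unique(lab)) == 2
}

#' Leakage-free k-fold cross-validation of the full model
#'
#' Variants are split into k folds; for each fold, every submodel (step 1,
#' both step-2 arms and step 3) is trained only on the remaining folds, the
#' held-out (variant, cell) rows are scored, and the held-out predictions of
#' all folds are concatenated before computing AUROC and AUPRC. If any fold
#' leaves a training step with a single class the split is redrawn with the
#' next seed (at most 10 attempts, logged).
#'
#' @param dataset a [gram_dataset()].
#' @param k number of folds (default 10).
#' @param seed RNG seed for the fold split.
#' @param config a [gram_config()]; defaults to the dataset's.
#' @return list with `predictions` (per held-out row: ids, `M`, `is_emvar`,
#'   `fold`), `auroc`, `auprc`, `folds` (the `fold_assignment` used) and
#'   `fold_variants` (per fold: train/test id vectors, for audit).
#' @export
cross_validate <- function(dataset, k = 10, seed = 1, config = dataset$config) {
  all_variants <- unique(dataset$counts$variant_id)
  folds <- NULL
  for (attempt in 0:9) {
    cand <- make_folds(all_variants, k = k, seed = seed + attempt)
    ok <- all(vapply(seq_len(k), function(f) {
      check_fold_classes(dataset, all_variants[cand$fold[all_variants] != f])
    }, logical(1)))
    if (ok) { folds <- cand; break }
    message(sprintf("fold split with seed %d left a single-class step; redrawing", seed + attempt))
  }
  assert_that(!is.null(folds), "could not draw folds with both classes at every step")
  preds <- list()
  fold_variants <- list()
  for (f in seq_len(k)) {
    test_ids <- all_variants[folds$fold[all_variants] == f]
    train_ids <- setdiff(all_variants, test_ids)
    fold_variants[[f]] <- list(train = train_ids, test = test_ids)
    fits <- fit_gram_models(dataset, train_ids, config)
    lab <- dataset$labels[dataset$labels$variant_id %in% test_ids, ]
    bsm <- dataset$bsm
    u_wt <- setNames(predict_U(fits$f1, bsm$scores_ref[test_ids, , drop = FALSE]), test_ids)
    u_mut <- setNames(predict_U(fits$f1, bsm$scores_alt[test_ids, , drop = FALSE]), test_ids)
    odds <- odds_feature(u_mut[lab$variant_id], u_wt[lab$variant_id], eps = config$eps)
    s_b <- predict_S(fits$f2b, bsm$scores_ref[lab$variant_id, , drop = FALSE])
    Xe <- reordered_pairs_matrix(bsm, dataset$expression, lab$variant_id,
                                 lab$cell_type, config$key_allele)
    s_e <- predict_S(fits$f2e, Xe)
    cf <- fits$f3
    m <- plogis(cf$b_u * odds + cf$b_s1 * s_b + cf$b_s2 * s_e + cf$b0)
    preds[[f]] <- data.frame(variant_id = lab$variant_id, cell_type = lab$cell_type,
                             M = m, is_emvar = lab$is_emvar, fold = f,
                             stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  list(predictions = predictions,
       auroc = auroc(predictions$M, predictions$is_emvar),
       auprc = auprc(predictions$M, predictions$is_emvar),
       folds = folds,
       fold_variants = fold_variants)
}
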