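## Feature construction: allele-level binding vectors, binding deltas
## (motif-break-like features) and rank-reordered TF expression.

#' Binding-score feature vector for one allele of a variant
#'
#' @param bsm a `binding_scores` object.
#' @param variant_id variant to extract.
#' @param allele `"ref"` or `"alt"`.
#' @return named numeric vector of length N (TFs), in `tf_ids(bsm)` order.
#' @export
allele_feature_vector <- function(bsm, variant_id, allele = c("ref", "alt")) {
  allele <- match.arg(allele)
  assert_that(variant_id %in% variant_ids(bsm),
              sprintf("unknown variant id: %s", variant_id))
  mat <- if (allele == "ref") bsm$scores_ref else bsm$scores_alt
  mat[variant_id, ]
}

#' Binding-score delta (alt minus ref) per TF
#'
#' The elementwise difference of the two allele layers; the package's
#' motif-alteration feature (zero wherever the alleles score identically).
#'
#' @inheritParams allele_feature_vector
#' @return named numeric vector of length N.
#' @export
binding_delta <- function(bsm, variant_id) {
  allele_feature_vector(bsm, variant_id, "alt") -
    allele_feature_vector(bsm, variant_id, "ref")
}

## Per-variant TF ordering by descending binding score on the key allele,
## ties broken lexicographically by TF id. Returns an index vector into
## tf_ids(bsm).
binding_rank_order <- function(bsm, variant_id, key_allele = c("ref", "alt", "max")) {
  key_allele <- match.arg(key_allele)
  assert_that(variant_id %in% variant_ids(bsm),
              sprintf("unknown variant id: %s", variant_id))
  key <- switch(key_allele,
                ref = bsm$scores_ref[variant_id, ],
                alt = bsm$scores_alt[variant_id, ],
                max = pmax(bsm$scores_ref[variant_id, ], bsm$scores_alt[variant_id, ]))
  order(-key, tf_ids(bsm))
}

#' Rank-reorder a TF expression profile by binding strength
#'
#' TFs are sorted by their binding score on the variant's element
#' (descending; ties broken lexicographically by TF id) and the sample's
#' expression values are placed in that order, so position k carries the
#' expression of the k-th most strongly bound TF, regardless of which TF that
#' is. This makes expression features comparable across variants.
#'
#' @param bsm a `binding_scores` object.
#' @param variant_id variant whose element defines the ranking.
#' @param profile named numeric vector of TF expression (covering
#'   `tf_ids(bsm)`), or an `expression_profiles` matrix together with
#'   `sample_id`.
#' @param key_allele allele whose scores define the ranking: `"ref"`
#'   (default), `"alt"`, or elementwise `"max"`.
#' @param sample_id required when `profile` is an `expression_profiles` matrix.
#' @return list of class `reordered_expression` with `variant_id`,
#'   `sample_id`, `values` (expression in binding-rank order) and `tf_order`
#'   (the TF ids at each position).
#' @export
reorder_expression <- function(bsm, variant_id, profile,
                               key_allele = c("ref", "alt", "max"),
                               sample_id = NULL) {
  key_allele <- match.arg(key_allele)
  if (inherits(profile, "expression_profiles") || is.matrix(profile)) {
    assert_that(!is.null(sample_id), "sample_id required for an expression matrix")
    profile <- expression_profile(profile, sample_id, tf_ids(bsm))
  }
  shared <- intersect(tf_ids(bsm), names(profile))
  assert_that(length(shared) > 0, "no TFs shared between binding scores and profile")
  prof <- profile[tf_ids(bsm)]
  if (anyNA(prof)) {
    stop_gram(sprintf("profile missing TF(s): %s",
                      paste(setdiff(tf_ids(bsm), names(profile)), collapse = ", ")))
  }
  ord <- binding_rank_order(bsm, variant_id, key_allele)
  structure(list(variant_id = variant_id,
                 sample_id = sample_id %||% NA_character_,
                 values = unname(prof[ord]),
                 tf_order = tf_ids(bsm)[ord]),
            class = "reordered_expression")
}

## Bulk reordered-expression design matrix for (variant, sample) pairs.
## expr: expression_profiles matrix; rows of the result are indexed by
## paste(variant_id, sample_id). Used by the model-fitting and scoring paths.
reordered_expression_matrix <- function(bsm, expr, variants = variant_ids(bsm),
                                        samples = rownames(expr),
                                        key_allele = "ref") {
  tfs <- tf_ids(bsm)
  missing_tfs <- setdiff(tfs, colnames(expr))
  assert_that(length(missing_tfs) == 0,
              sprintf("expression matrix missing TF(s): %s", paste(missing_tfs, collapse = ", ")))
  e <- expr[, tfs, drop = FALSE]
  out <- matrix(NA_real_, nrow = length(variants) * length(samples), ncol = length(tfs))
  rn <- character(nrow(out))
  row <- 1L
  for (v in variants) {
    ord <- binding_rank_order(bsm, v, key_allele)
    for (s in samples) {
      out[row, ] <- e[s, ord]
      rn[row] <- paste(v, s, sep = "\r")
      row <- row + 1L
    }
  }
  rownames(out) <- rn
  colnames(out) <- paste0("rank_", seq_along(tfs))
  out
}
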