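## MPRA-derived statistics and training-label construction: allelic logSkew,
## the Vodds variability statistic, regulatory-activity calls, emVAR labels
## and quartile-based cell-type-modifier labels.

default_pseudocount <- function(n1, n2, n3, n4, pseudocount) {
  if (!is.null(pseudocount)) return(pseudocount)
  # Haldane-Anscombe correction only when a table contains zeros
  ifelse(n1 > 0 & n2 > 0 & n3 > 0 & n4 > 0, 0, 0.5)
}

counts_cols <- function(x) {
  if (is.data.frame(x)) {
    assert_that(all(c("n1", "n2", "n3", "n4") %in% names(x)),
                "expected an mpra_counts table with columns n1..n4")
    list(n1 = x$n1, n2 = x$n2, n3 = x$n3, n4 = x$n4)
  } else {
    assert_that(is.numeric(x) && length(x) == 4, "expected n1..n4")
    list(n1 = x[1], n2 = x[2], n3 = x[3], n4 = x[4])
  }
}

#' Allelic log-skew of an MPRA count table
#'
#' The log2 odds ratio of the 2x2 assay/control x allele table, oriented
#' alternative-over-reference:
#' `log2( ((n3+ps)/(n4+ps)) / ((n1+ps)/(n2+ps)) )`. Positive values mean the
#' alternative allele drives relatively more reporter expression. The
#' statistic is antisymmetric under swapping the two allele columns.
#'
#' @param x an `mpra_counts` data frame (vectorized over rows) or a numeric
#'   vector `c(n1, n2, n3, n4)`.
#' @param pseudocount added to every cell; `NULL` (default) uses 0 for
#'   all-positive tables and 0.5 (Haldane-Anscombe) for tables with zeros.
#' @return numeric vector of log2 skew values.
#' @export
log_skew <- function(x, pseudocount = NULL) {
  cc <- counts_cols(x)
  if (any(cc$n1 == 0 & cc$n2 == 0 & cc$n3 == 0 & cc$n4 == 0)) {
    stop_gram("empty table")
  }
  ps <- default_pseudocount(cc$n1, cc$n2, cc$n3, cc$n4, pseudocount)
  log2(((cc$n3 + ps) / (cc$n4 + ps)) / ((cc$n1 + ps) / (cc$n2 + ps)))
}

#' Vodds: delta-method SD of the log odds ratio
#'
#' `sqrt(1/n1 + 1/n2 + 1/n3 + 1/n4)` over the 2x2 count table; the asymptotic
#' standard deviation of its log odds ratio, used as a cell-type-specific
#' variability signal. Strictly decreasing in each count.
#'
#' @inheritParams log_skew
#' @return numeric vector of nonnegative Vodds values.
#' @export
vodds <- function(x, pseudocount = NULL) {
  cc <- counts_cols(x)
  ps <- default_pseudocount(cc$n1, cc$n2, cc$n3, cc$n4, pseudocount)
  if (any(cc$n1 + ps <= 0 | cc$n2 + ps <= 0 | cc$n3 + ps <= 0 | cc$n4 + ps <= 0)) {
    stop_gram("zero count; use pseudocount")
  }
  sqrt(1 / (cc$n1 + ps) + 1 / (cc$n2 + ps) + 1 / (cc$n3 + ps) + 1 / (cc$n4 + ps))
}

#' Call per-allele regulatory activity from an MPRA count table
#'
#' An allele is active when its assay/control fold change exceeds
#' `fc_cutoff` (strictly). In `count_test` mode a two-sided conditional
#' binomial test of the assay count against the assay+control total must also
#' reject at `alpha`; this count-ratio test is the package's self-contained
#' activity test (externally computed calls, e.g. from a dedicated
#' count-model package, can be supplied wherever labels are accepted).
#'
#' @param x an `mpra_counts` data frame.
#' @param mode `"fold_change"` (default) or `"count_test"`.
#' @param fc_cutoff fold-change cutoff (1.5 by default; 2 is the common
#'   stricter choice for fluorescence assays).
#' @param alpha significance level for `count_test` mode.
#' @param pseudocount as in [log_skew()].
#' @return data frame with one row per (variant, cell type, allele):
#'   `variant_id`, `cell_type`, `allele`, `fold_change`, `p_value`, `active`.
#' @export
call_activity <- function(x, mode = c("fold_change", "count_test"),
                          fc_cutoff = 1.5, alpha = 0.05, pseudocount = NULL) {
  mode <- match.arg(mode)
  assert_that(is.numeric(alpha) && alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  assert_that(fc_cutoff > 0, "fc_cutoff must be positive")
  cc <- counts_cols(x)
  ps <- default_pseudocount(cc$n1, cc$n2, cc$n3, cc$n4, pseudocount)
  long <- data.frame(
    variant_id = rep(x$variant_id, 2L),
    cell_type = rep(x$cell_type, 2L),
    allele = rep(c("ref", "alt"), each = nrow(x)),
    assay = c(cc$n1, cc$n3),
    control = c(cc$n2, cc$n4),
    ps = rep(ps, 2L),
    stringsAsFactors = FALSE
  )
  long$fold_change <- (long$assay + long$ps) / (long$control + long$ps)
  long$p_value <- NA_real_
  if (mode == "count_test") {
    long$p_value <- vapply(seq_len(nrow(long)), function(i) {
      a <- round(long$assay[i]); b <- round(long$control[i])
      if (a + b == 0) return(1)
      binom.test(a, a + b, p = 0.5)$p.value
    }, numeric(1))
    long$active <- long$fold_change > fc_cutoff & long$p_value < alpha
  } else {
    long$active <- long$fold_change > fc_cutoff
  }
  long$assay <- long$control <- long$ps <- NULL
  long
}

#' Label expression-modulating variants (emVARs)
#'
#' A variant is an emVAR when its allelic skew is statistically significant
#' and the absolute log2 skew exceeds the filter threshold. The default
#' threshold `|log2(1.5)| = 0.5849` corresponds to a 1.5-fold allelic skew.
#'
#' @param log_skew numeric vector of log2 skew values.
#' @param significant logical vector: skew significance from the upstream
#'   differential test.
#' @param skew_threshold positive threshold on `|log_skew|`.
#' @return data frame with `log_skew`, `passes_skew_filter`, `is_emvar`.
#' @export
label_emvar <- function(log_skew, significant, skew_threshold = abs(log2(1.5))) {
  assert_that(skew_threshold > 0, "skew_threshold must be positive")
  assert_that(length(log_skew) == length(significant),
              "log_skew and significant must have equal length")
  passes <- abs(log_skew) > skew_threshold
  data.frame(log_skew = log_skew,
             passes_skew_filter = passes,
             is_emvar = as.logical(significant) & passes)
}

#' Quartile-based cell-type-modifier labels from Vodds
#'
#' Variants in the top quantile of Vodds are labeled `high` (positive
#' modifier-training class), the bottom quantile `low`, and the middle band
#' `excluded`. Boundaries use the linear-interpolation empirical quantile
#' (type 7); boundary ties are labeled inward (into `high`/`low`).
#'
#' @param vodds_values numeric vector of Vodds, optionally named by variant id.
#' @param lower_q,upper_q quantile boundaries, defaults 0.25 / 0.75.
#' @return data frame `variant_id`, `vodds`, `klass` with attribute `counts`.
#' @export
modifier_labels <- function(vodds_values, lower_q = 0.25, upper_q = 0.75) {
  assert_that(length(vodds_values) >= 8, "need at least 8 variants")
  assert_that(lower_q > 0 && upper_q < 1 && lower_q < upper_q,
              "require 0 < lower_q < upper_q < 1")
  if (max(vodds_values) - min(vodds_values) <= 0) stop_gram("degenerate distribution")
  qs <- quantile(vodds_values, c(lower_q, upper_q), names = FALSE, type = 7)
  klass <- ifelse(vodds_values >= qs[2], "high",
                  ifelse(vodds_values <= qs[1], "low", "excluded"))
  ids <- names(vodds_values) %||% paste0("v", seq_along(vodds_values))
  out <- data.frame(variant_id = ids, vodds = as.numeric(vodds_values),
                    klass = klass, stringsAsFactors = FALSE)
  attr(out, "counts") <- c(high = sum(klass == "high"),
                           low = sum(klass == "low"),
                           excluded = sum(klass == "excluded"))
  attr(out, "boundaries") <- c(lower = qs[1], upper = qs[2])
  out
}

#' PCA of Vodds profiles across cell lines
#'
#' Centers the variants-by-cell matrix and reports per-cell principal
#' component loadings plus explained variance, for qualitative comparison of
#' cell lines' variability patterns.
#'
#' @param vodds_by_cell numeric matrix, cell lines x variants (>= 2 rows,
#'   >= 3 columns, no missing values).
#' @return list with `loadings` (cells x components), `scores`
#'   (variants x components) and `explained_variance` (proportions).
#' @export
pca_vodds <- function(vodds_by_cell) {
  vodds_by_cell <- as.matrix(vodds_by_cell)
  assert_that(nrow(vodds_by_cell) >= 2, "need at least 2 cell rows")
  assert_that(ncol(vodds_by_cell) >= 3, "need at least 3 variant columns")
  if (anyNA(vodds_by_cell)) stop_gram("missing values not allowed")
  pr <- prcomp(t(vodds_by_cell), center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  list(loadings = pr$rotation,
       scores = pr$x,
       explained_variance = ev / sum(ev))
}
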