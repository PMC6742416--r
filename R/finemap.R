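## Fine-mapping workflow: per-sample scoring of the variants in a region,
## average-score ranking, and score--target-gene-expression correlation.

#' Score every variant in every cohort sample
#'
#' Computes the molecular-effect score M(i, c) for each (variant, sample)
#' pair using each sample's own expression profile as the cellular context.
#' In `carriers_only` mode samples with alternative-allele dosage 0 are
#' masked as `NA` and excluded from downstream means.
#'
#' @param cohort a `gram_cohort` (see [simulate_cohort()] for the structure:
#'   `bsm`, `genotypes`, `expression`, ids).
#' @param bundle a trained `gram_model`.
#' @param mode `"all_samples"` (default) or `"carriers_only"`.
#' @return numeric matrix, variants x samples, of M scores (with `NA` for
#'   masked cells).
#' @export
score_cohort <- function(cohort, bundle, mode = c("all_samples", "carriers_only")) {
  mode <- match.arg(mode)
  samples <- rownames(cohort$expression)
  assert_that(identical(sort(samples), sort(rownames(cohort$genotypes))),
              "samples disagree between genotypes and expression")
  scored <- predict_gram(bundle, cohort$bsm, cohort$expression,
                         variants = cohort$variant_ids, samples = samples)
  m <- matrix(NA_real_, length(cohort$variant_ids), length(samples),
              dimnames = list(cohort$variant_ids, samples))
  m[cbind(scored$variant_id, scored$sample_id)] <- scored$M
  if (mode == "carriers_only") {
    non_carrier <- t(cohort$genotypes[samples, cohort$variant_ids, drop = FALSE]) == 0
    m[non_carrier] <- NA_real_
  }
  m
}

#' Rank variants by average score
#'
#' @param score_matrix variants x samples matrix from [score_cohort()].
#' @return data frame `variant_id`, `mean_score`, `n_samples` (non-missing),
#'   `rank`, sorted descending by mean score with ties broken by variant id.
#' @export
rank_variants <- function(score_matrix) {
  mean_score <- rowMeans(score_matrix, na.rm = TRUE)
  n_samples <- rowSums(!is.na(score_matrix))
  out <- data.frame(variant_id = rownames(score_matrix),
                    mean_score = mean_score, n_samples = n_samples,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_score, out$variant_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Correlate per-sample scores with target-gene expression
#'
#' Pearson correlation (with the two-sided t-test p-value) between each
#' variant's per-sample M scores and the expression of its eQTL target gene.
#' Variants with fewer than 3 complete pairs, or a constant score or
#' expression vector, are reported as missing with a reason.
#'
#' @param score_matrix variants x samples matrix from [score_cohort()].
#' @param target_expression samples x genes matrix.
#' @param eqtl_targets named character vector mapping variant id -> gene id.
#' @return data frame `variant_id`, `gene`, `r`, `p_value`, `n`, `reason`
#'   (`NA` when the correlation was computed).
#' @export
correlate_scores_expression <- function(score_matrix, target_expression, eqtl_targets) {
  samples <- colnames(score_matrix)
  assert_that(all(samples %in% rownames(target_expression)),
              "target_expression must cover all scored samples")
  res <- lapply(rownames(score_matrix), function(v) {
    gene <- unname(eqtl_targets[v])
    base <- data.frame(variant_id = v, gene = gene %||% NA_character_,
                       r = NA_real_, p_value = NA_real_, n = 0L,
                       reason = NA_character_, stringsAsFactors = FALSE)
    if (is.null(gene) || is.na(gene) || !gene %in% colnames(target_expression)) {
      base$reason <- "no target gene"
      return(base)
    }
    s <- score_matrix[v, samples]
    e <- target_expression[samples, gene]
    ok <- !is.na(s) & !is.na(e)
    base$n <- sum(ok)
    if (base$n < 3) { base$reason <- "fewer than 3 paired samples"; return(base) }
    if (sd(s[ok]) == 0 || sd(e[ok]) == 0) {
      base$reason <- "constant scores or expression"
      return(base)
    }
    ct <- cor.test(s[ok], e[ok], method = "pearson")
    base$r <- unname(ct$estimate); base$p_value <- ct$p.value
    base
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Run the fine-mapping workflow on one region
#'
#' Scores the cohort, ranks variants by mean score, and correlates scores
#' with target-gene expression.
#'
#' @inheritParams score_cohort
#' @return list of class `finemap_result` with `region`, `score_matrix`,
#'   `ranking`, `correlations`, `mode`.
#' @export
finemap_region <- function(cohort, bundle, mode = c("all_samples", "carriers_only")) {
  mode <- match.arg(mode)
  m <- score_cohort(cohort, bundle, mode)
  structure(list(region = cohort$region,
                 score_matrix = m,
                 ranking = rank_variants(m),
                 correlations = correlate_scores_expression(
                   m, cohort$target_expression, cohort$eqtl_targets),
                 genotypes = cohort$genotypes,
                 mode = mode),
            class = "finemap_result")
}

region_slug <- function(region, i) {
  slug <- gsub("[^A-Za-z0-9._-]+", "_", region %||% sprintf("region%02d", i))
  if (nchar(slug) == 0) sprintf("region%02d", i) else slug
}

#' Write per-region fine-mapping reports
#'
#' For each result writes a long-form score TSV (region, variant, sample, M,
#' dosage), a summary TSV (mean scores, ranks, correlations), and -- when
#' plotting is enabled and the pheatmap package is available -- a per-region
#' heatmap PNG of the score matrix. File names are deterministic, derived
#' from the region label.
#'
#' @param results a `finemap_result` or a list of them (one per region).
#' @param out_dir output directory (created if needed; unwritable -> error).
#' @param plot draw heatmaps (default `FALSE`).
#' @return character vector of files written, invisibly.
#' @export
render_region_report <- function(results, out_dir, plot = FALSE) {
  if (inherits(results, "finemap_result")) results <- list(results)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(out_dir) && file.access(out_dir, 2) == 0,
              sprintf("cannot write to directory: %s", out_dir))
  written <- character(0)
  for (i in seq_along(results)) {
    res <- results[[i]]
    slug <- region_slug(res$region, i)
    m <- res$score_matrix
    if (nrow(m) == 0 || ncol(m) == 0) {
      message(sprintf("region %s is empty; writing header-only report", slug))
      long <- data.frame(region = character(0), variant_id = character(0),
                         sample_id = character(0), M = numeric(0),
                         dosage = integer(0))
    } else {
      long <- data.frame(
        region = res$region,
        variant_id = rep(rownames(m), times = ncol(m)),
        sample_id = rep(colnames(m), each = nrow(m)),
        M = as.vector(m),
        dosage = as.vector(t(res$genotypes[colnames(m), rownames(m), drop = FALSE])),
        stringsAsFactors = FALSE)
    }
    score_path <- file.path(out_dir, paste0(slug, "_scores.tsv"))
    data.table::fwrite(long, score_path, sep = "\t")
    summary_df <- merge(res$ranking, res$correlations, by = "variant_id", sort = FALSE)
    summary_path <- file.path(out_dir, paste0(slug, "_summary.tsv"))
    data.table::fwrite(summary_df[order(summary_df$rank), ], summary_path, sep = "\t")
    written <- c(written, score_path, summary_path)
    if (plot && nrow(m) > 1 && ncol(m) > 1) {
      if (requireNamespace("pheatmap", quietly = TRUE)) {
        png_path <- file.path(out_dir, paste0(slug, "_heatmap.png"))
        grDevices::png(png_path, width = 900, height = 700)
        pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                           main = res$region)
        grDevices::dev.off()
        written <- c(written, png_path)
      } else {
        message("pheatmap not installed; skipping heatmap")
      }
    }
  }
  invisible(written)
}
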