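## Typed matrix containers: per-allele TF binding scores, TF expression
## profiles, and MPRA 2x2 count tables, plus their TSV readers/writers.

#' Construct a per-allele TF binding-score container
#'
#' @param scores_ref numeric matrix, variants x TFs, with row names = variant
#'   ids and column names = TF ids (reference-allele element scores).
#' @param scores_alt same shape and dimnames, alternative-allele scores.
#' @param assay_type optional character vector per TF (`"SELEX"` or
#'   `"ChIP-Seq"`).
#' @return an object of class `binding_scores`.
#' @export
binding_scores <- function(scores_ref, scores_alt, assay_type = NULL) {
  scores_ref <- as.matrix(scores_ref); scores_alt <- as.matrix(scores_alt)
  assert_that(all(dim(scores_ref) == dim(scores_alt)),
              "ref and alt score matrices must share shape")
  assert_that(!is.null(rownames(scores_ref)) && !is.null(colnames(scores_ref)),
              "binding matrices need variant row names and TF column names")
  assert_that(identical(dimnames(scores_ref), dimnames(scores_alt)),
              "ref and alt score matrices must share dimnames")
  assert_that(!anyDuplicated(rownames(scores_ref)), "duplicate variant ids")
  assert_that(!anyDuplicated(colnames(scores_ref)), "duplicate TF ids")
  assert_that(!anyNA(scores_ref) && !anyNA(scores_alt),
              "binding matrices must not contain missing values after imputation")
  if (!is.null(assay_type)) {
    assert_that(length(assay_type) == ncol(scores_ref),
                "assay_type must have one entry per TF")
  }
  structure(list(scores_ref = scores_ref, scores_alt = scores_alt,
                 assay_type = assay_type),
            class = "binding_scores")
}

#' @export
print.binding_scores <- function(x, ...) {
  cat(sprintf("<binding_scores> %d variants x %d TFs\n",
              nrow(x$scores_ref), ncol(x$scores_ref)))
  invisible(x)
}

#' Variant ids of a binding-score container
#' @param bsm a `binding_scores` object.
#' @return character vector of variant ids.
#' @export
variant_ids <- function(bsm) rownames(bsm$scores_ref)

#' TF ids of a binding-score container
#' @param bsm a `binding_scores` object.
#' @return character vector of TF ids.
#' @export
tf_ids <- function(bsm) colnames(bsm$scores_ref)

#' Align a binding-score container to a TF schema
#'
#' Columns are matched by TF id, never by position, so a permuted matrix
#' scores identically.
#'
#' @param bsm a `binding_scores` object.
#' @param tfs character vector of TF ids in the required order.
#' @return a `binding_scores` object with columns in `tfs` order.
#' @export
align_binding <- function(bsm, tfs) {
  missing_tfs <- setdiff(tfs, tf_ids(bsm))
  assert_that(length(missing_tfs) == 0,
              sprintf("binding scores missing TF(s): %s", paste(missing_tfs, collapse = ", ")))
  idx <- match(tfs, tf_ids(bsm))
  binding_scores(bsm$scores_ref[, idx, drop = FALSE],
                 bsm$scores_alt[, idx, drop = FALSE],
                 if (!is.null(bsm$assay_type)) bsm$assay_type[idx] else NULL)
}

#' Construct an MPRA count-table container
#'
#' One row per (variant, cell type) with the 2x2 layout: `n1` assay/reference,
#' `n2` null-control/reference, `n3` assay/alternative, `n4`
#' null-control/alternative. Counts are averages over replicates and may be
#' non-integer.
#'
#' @param df data frame with columns `variant_id`, `cell_type`, `n1`..`n4`.
#' @return an `mpra_counts` data frame.
#' @export
mpra_counts <- function(df) {
  need <- c("variant_id", "cell_type", "n1", "n2", "n3", "n4")
  missing_cols <- setdiff(need, names(df))
  assert_that(length(missing_cols) == 0,
              sprintf("count table missing column(s): %s", paste(missing_cols, collapse = ", ")))
  df <- as.data.frame(df, stringsAsFactors = FALSE)[, need]
  for (col in c("n1", "n2", "n3", "n4")) {
    x <- as.numeric(df[[col]])
    assert_that(!anyNA(x), sprintf("missing value in %s", col))
    if (any(x < 0)) stop_gram("negative count")
    df[[col]] <- x
  }
  class(df) <- c("mpra_counts", "data.frame")
  df
}

#' Construct an expression-profile container
#'
#' @param mat numeric matrix, samples (or cell types) x TFs, with row names =
#'   sample ids and column names = TF ids. Nonnegative expression values
#'   (e.g. log-scale abundance).
#' @return an `expression_profiles` matrix.
#' @export
expression_profiles <- function(mat) {
  mat <- as.matrix(mat)
  assert_that(!is.null(rownames(mat)) && !is.null(colnames(mat)),
              "expression matrix needs sample row names and TF column names")
  assert_that(!anyDuplicated(rownames(mat)), "duplicate sample ids")
  assert_that(!anyDuplicated(colnames(mat)), "duplicate TF ids")
  assert_that(!anyNA(mat), "expression matrix must not contain missing values")
  assert_that(all(mat >= 0), "expression values must be nonnegative")
  class(mat) <- c("expression_profiles", class(mat))
  mat
}

#' Extract one sample's expression profile, aligned to a TF schema
#'
#' Missing TFs are imputed with the sample's median expression and flagged via
#' a warning, per the container's imputation policy.
#'
#' @param expr an `expression_profiles` matrix.
#' @param sample_id row to extract.
#' @param tfs optional TF-id ordering to align to.
#' @return named numeric vector of expression values.
#' @export
expression_profile <- function(expr, sample_id, tfs = NULL) {
  assert_that(sample_id %in% rownames(expr),
              sprintf("unknown sample id: %s", sample_id))
  prof <- expr[sample_id, ]
  names(prof) <- colnames(expr)
  if (is.null(tfs)) return(prof)
  out <- prof[tfs]
  names(out) <- tfs
  if (anyNA(out)) {
    n_imp <- sum(is.na(out))
    out[is.na(out)] <- median(prof)
    warning(sprintf("imputed %d TF(s) absent from expression profile '%s' with the sample median",
                    n_imp, sample_id))
  }
  out
}

read_numeric_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  assert_that(nrow(dt) > 0 && ncol(dt) > 1, "empty matrix")
  ids <- as.character(dt[[1]])
  assert_that(!anyDuplicated(ids), "duplicate row ids")
  mat <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  assert_that(!anyDuplicated(colnames(mat)), "duplicate column ids")
  mat
}

impute_column_median <- function(mat, what) {
  n_missing <- sum(is.na(mat))
  if (n_missing > 0) {
    for (j in seq_len(ncol(mat))) {
      nas <- is.na(mat[, j])
      if (any(nas)) mat[nas, j] <- median(mat[, j], na.rm = TRUE)
    }
    message(sprintf("imputed %d missing %s value(s) with the column (TF) median",
                    n_missing, what))
  }
  mat
}

#' Read a typed matrix or count table from TSV
#'
#' Binding kinds return a bare numeric matrix (variants x TFs) with missing
#' cells imputed by the column (TF) median; `expression` returns an
#' `expression_profiles` matrix (samples x TFs); `counts` returns an
#' `mpra_counts` data frame. Count TSVs use the column names `assay_ref`,
#' `ctrl_ref`, `assay_alt`, `ctrl_alt` for the 2x2 roles (mapped to
#' `n1`..`n4`), or `n1`..`n4` directly.
#'
#' @param path TSV path; matrices carry row ids in the first column and
#'   column ids in the header.
#' @param kind one of `"binding_ref"`, `"binding_alt"`, `"expression"`,
#'   `"counts"`.
#' @return see Details.
#' @export
read_matrix <- function(path, kind = c("binding_ref", "binding_alt", "expression", "counts")) {
  kind <- match.arg(kind)
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  if (kind == "counts") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
    assert_that(nrow(dt) > 0, "empty matrix")
    role_cols <- c(assay_ref = "n1", ctrl_ref = "n2", assay_alt = "n3", ctrl_alt = "n4")
    for (nm in names(role_cols)) {
      if (nm %in% names(dt)) names(dt)[names(dt) == nm] <- role_cols[[nm]]
    }
    if (!"cell_type" %in% names(dt)) dt$cell_type <- "unknown"
    return(mpra_counts(dt))
  }
  mat <- read_numeric_matrix(path)
  if (kind == "expression") return(expression_profiles(mat))
  impute_column_median(mat, sub("binding_", "", kind))
}

#' Read the two allele layers of a binding-score matrix
#'
#' @param ref_path TSV of reference-allele scores (variants x TFs).
#' @param alt_path TSV of alternative-allele scores, same layout.
#' @param assay_type optional per-TF assay annotation.
#' @return a `binding_scores` object.
#' @export
read_binding_scores <- function(ref_path, alt_path, assay_type = NULL) {
  ref <- read_matrix(ref_path, "binding_ref")
  alt <- read_matrix(alt_path, "binding_alt")
  assert_that(identical(rownames(ref), rownames(alt)) &&
                identical(colnames(ref), colnames(alt)),
              "ref and alt binding TSVs must share row and column ids")
  binding_scores(ref, alt, assay_type)
}

#' Write a numeric matrix as TSV with row ids
#'
#' @param mat matrix with dimnames.
#' @param path output path.
#' @param id_col name for the row-id column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), as.data.frame(unclass(mat)), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Write an MPRA count table as TSV with role-named columns
#'
#' @param counts an `mpra_counts` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- as.data.frame(counts)
  names(df) <- c("variant_id", "cell_type", "assay_ref", "ctrl_ref", "assay_alt", "ctrl_alt")
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
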