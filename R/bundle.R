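## On-disk serialization of a trained model: a directory holding the three
## fitted forests plus a JSON manifest with the step-3 coefficients, penalty,
## feature schema and training metadata.

BUNDLE_FORMAT_VERSION <- "1.0"

#' Save a trained model bundle to a directory
#'
#' @param bundle a `gram_model` from [train_full()].
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
save_bundle <- function(bundle, path) {
  assert_that(inherits(bundle, "gram_model"), "bundle must be a gram_model")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    format_version = BUNDLE_FORMAT_VERSION,
    step3_coefficients = bundle$step3[c("b_u", "b_s1", "b_s2", "b0")],
    lambda = bundle$step3$lambda,
    objective = bundle$step3$objective,
    tf_ids = bundle$tf_ids,
    key_allele = bundle$key_allele,
    eps = bundle$eps,
    metadata = bundle$metadata
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # the manifest is the human-readable record; the exact coefficient bits
  # live in step3.rds so reloaded predictions are bitwise identical
  saveRDS(bundle$step3, file.path(path, "step3.rds"))
  saveRDS(bundle$step1, file.path(path, "step1.rds"))
  saveRDS(bundle$step2_binding, file.path(path, "step2_binding.rds"))
  saveRDS(bundle$step2_expression, file.path(path, "step2_expression.rds"))
  invisible(path)
}

#' Load a model bundle from a directory
#'
#' Validates the manifest (format version, presence of the step-3
#' coefficients and schema) before reconstructing the model; a mismatched or
#' truncated bundle is an error, never silently coerced.
#'
#' @param path bundle directory written by [save_bundle()].
#' @return a `gram_model`.
#' @export
load_bundle <- function(path) {
  mf <- file.path(path, "manifest.json")
  assert_that(file.exists(mf), sprintf("no manifest.json under %s", path))
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  assert_that(identical(manifest$format_version, BUNDLE_FORMAT_VERSION),
              sprintf("bundle format version mismatch: found '%s', need '%s'",
                      manifest$format_version %||% "<missing>", BUNDLE_FORMAT_VERSION))
  cf <- manifest$step3_coefficients
  assert_that(!is.null(cf) && all(c("b_u", "b_s1", "b_s2", "b0") %in% names(cf)),
              "bundle manifest missing step3 coefficients")
  assert_that(!is.null(manifest$tf_ids), "bundle manifest missing TF schema")
  for (f in c("step1.rds", "step2_binding.rds", "step2_expression.rds", "step3.rds")) {
    assert_that(file.exists(file.path(path, f)), sprintf("bundle missing %s", f))
  }
  step3 <- readRDS(file.path(path, "step3.rds"))
  structure(list(step1 = readRDS(file.path(path, "step1.rds")),
                 step2_binding = readRDS(file.path(path, "step2_binding.rds")),
                 step2_expression = readRDS(file.path(path, "step2_expression.rds")),
                 step3 = step3,
                 tf_ids = as.character(manifest$tf_ids),
                 key_allele = manifest$key_allele %||% "ref",
                 eps = manifest$eps %||% 1e-6,
                 metadata = manifest$metadata),
            class = "gram_model")
}
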