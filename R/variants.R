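## Variant parsing and element-sequence construction.
##
## Coordinate conventions: a variant position is 1-based (VCF convention);
## the element interval around it is 0-based half-open (BED convention).
## All conversions happen here and nowhere else.

VALID_BASES <- c("A", "C", "G", "T")

new_gram_variants <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  class(df) <- c("gram_variants", "data.frame")
  df
}

#' Read biallelic SNVs from a VCF or headered TSV
#'
#' TSV input must carry a header line with columns `chrom`, `pos`, `ref`,
#' `alt` and optionally `variant_id`; missing ids are synthesized as
#' `chrom_pos_ref_alt`. VCF input (via the vcfR package) keeps biallelic SNV
#' records only; indels and multi-allelic records are skipped with a warning
#' and counted in the `skipped` attribute.
#'
#' @param path path to the variant file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return a `gram_variants` data frame with columns `variant_id`, `chrom`,
#'   `pos`, `ref`, `alt` (one row per SNV, in file order) and attribute
#'   `skipped` giving the number of non-SNV records dropped.
#' @export
read_variants <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  assert_that(file.exists(path), sprintf("variant file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") read_variants_vcf(path) else read_variants_tsv(path)
}

read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(need, names(df))
  assert_that(length(missing_cols) == 0,
              sprintf("variant TSV missing column(s): %s", paste(missing_cols, collapse = ", ")))
  skipped <- 0L
  keep <- rep(TRUE, nrow(df))
  pos <- suppressWarnings(as.integer(as.character(df$pos)))
  for (i in seq_len(nrow(df))) {
    line_no <- i + 1L  # header occupies line 1
    if (is.na(pos[i])) stop_gram(sprintf("line %d: non-integer position", line_no))
    ref <- toupper(df$ref[i]); alt <- toupper(df$alt[i])
    if (nchar(ref) != 1L || nchar(alt) != 1L) {
      keep[i] <- FALSE; skipped <- skipped + 1L; next
    }
    if (!(ref %in% VALID_BASES) || !(alt %in% VALID_BASES)) {
      stop_gram(sprintf("line %d: invalid allele '%s'/'%s'", line_no, ref, alt))
    }
    if (ref == alt) stop_gram(sprintf("line %d: ref equals alt", line_no))
  }
  out <- data.frame(
    variant_id = if ("variant_id" %in% names(df)) as.character(df$variant_id) else
      paste(df$chrom, pos, toupper(df$ref), toupper(df$alt), sep = "_"),
    chrom = as.character(df$chrom),
    pos = pos,
    ref = toupper(df$ref),
    alt = toupper(df$alt),
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (skipped > 0) warning(sprintf("skipped %d non-SNV record(s)", skipped))
  assert_that(!anyDuplicated(out$variant_id), "duplicate variant ids")
  structure(new_gram_variants(out), skipped = skipped)
}

read_variants_vcf <- function(path) {
  assert_that(requireNamespace("vcfR", quietly = TRUE),
              "reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ref <- toupper(fix$REF); alt <- toupper(fix$ALT)
  is_snv <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% VALID_BASES & alt %in% VALID_BASES & ref != alt
  skipped <- sum(!is_snv)
  if (skipped > 0) warning(sprintf("skipped %d non-SNV record(s)", skipped))
  fix <- fix[is_snv, , drop = FALSE]
  ids <- fix$ID
  no_id <- is.na(ids) | ids == "." | ids == ""
  ids[no_id] <- paste(fix$CHROM[no_id], fix$POS[no_id],
                      toupper(fix$REF[no_id]), toupper(fix$ALT[no_id]), sep = "_")
  out <- data.frame(
    variant_id = ids,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = toupper(fix$REF),
    alt = toupper(fix$ALT),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  assert_that(!anyDuplicated(out$variant_id), "duplicate variant ids")
  structure(new_gram_variants(out), skipped = skipped)
}

#' Write variants to a headered TSV
#'
#' @param variants a `gram_variants` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  cols <- intersect(c("variant_id", "chrom", "pos", "ref", "alt"), names(variants))
  utils::write.table(as.data.frame(variants)[, cols], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

load_genome <- function(genome) {
  if (is_single_string(genome) && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  } else if (is.character(genome)) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  assert_that(methods::is(genome, "DNAStringSet") && !is.null(names(genome)),
              "genome must be a FASTA path or a named DNAStringSet/character vector")
  genome
}

#' Build the tested element sequence around each SNV
#'
#' Each SNV is extended symmetrically by `flank` bases on both sides, giving
#' an element of `2 * flank + 1` bp (149 bp at the default flank of 74). The
#' reference element is read from the genome and uppercased; the alternative
#' element substitutes the alternative allele at the center position.
#'
#' @param variants a `gram_variants` data frame.
#' @param genome FASTA path, named `DNAStringSet`, or named character vector of
#'   chromosome sequences.
#' @param flank extension in bp on each side (default 74).
#' @param strict if `TRUE` (default) a genome base that disagrees with the
#'   stated reference allele is an error; if `FALSE` such variants are dropped
#'   with a warning.
#' @return the input with columns `element_start` (0-based), `element_end`
#'   (half-open), `ref_sequence` and `alt_sequence` added.
#' @export
extract_element_sequences <- function(variants, genome, flank = 74L, strict = TRUE) {
  flank <- as.integer(flank)
  assert_that(flank >= 0L, "flank must be >= 0")
  genome <- load_genome(genome)
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  n <- nrow(v)
  ref_seq <- alt_seq <- character(n)
  start0 <- v$pos - flank - 1L   # 0-based start
  end0 <- v$pos + flank          # half-open end
  mismatched <- character(0)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    chrom <- v$chrom[i]
    assert_that(chrom %in% names(genome), sprintf("chromosome not in genome: %s", chrom))
    chr_len <- Biostrings::width(genome[chrom])
    if (start0[i] < 0L || end0[i] > chr_len) {
      stop_gram(sprintf("variant %s: element [%d, %d) out of bounds for %s (length %d)",
                        v$variant_id[i], start0[i], end0[i], chrom, chr_len))
    }
    s <- toupper(as.character(Biostrings::subseq(genome[[chrom]],
                                                 start = start0[i] + 1L, end = end0[i])))
    center <- flank + 1L
    if (substr(s, center, center) != v$ref[i]) {
      mismatched <- c(mismatched, v$variant_id[i])
      keep[i] <- FALSE
      next
    }
    ref_seq[i] <- s
    substr(s, center, center) <- v$alt[i]
    alt_seq[i] <- s
  }
  if (length(mismatched) > 0) {
    msg <- sprintf("genome base does not match reference allele for: %s",
                   paste(mismatched, collapse = ", "))
    if (strict) stop_gram(msg)
    warning(paste0(msg, " (dropped)"))
  }
  v$element_start <- start0
  v$element_end <- end0
  v$ref_sequence <- ref_seq
  v$alt_sequence <- alt_seq
  out <- new_gram_variants(v[keep, , drop = FALSE])
  rownames(out) <- NULL
  out
}
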