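test_that("read_variants parses a headered TSV, keeps order, skips non-SNVs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tvariant_id",
               "chr1\t100\tA\tG\trs1",
               "chr1\t200\tC\tT\trs2",
               "chr2\t50\tG\tA\trs3"), path)
  v <- read_variants(path)
  expect_s3_class(v, "gram_variants")
  expect_equal(v$variant_id, c("rs1", "rs2", "rs3"))
  expect_equal(v$pos, c(100L, 200L, 50L))
  expect_equal(attr(v, "skipped"), 0L)

  # an indel row is skipped with a warning and counted
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt",
               "chr1\t100\tA\tG",
               "chr1\t150\tAT\tA",
               "chr1\t200\tC\tT"), path2)
  expect_warning(v2 <- read_variants(path2), "skipped 1")
  expect_equal(nrow(v2), 2L)
  expect_equal(attr(v2, "skipped"), 1L)
})

test_that("read_variants rejects malformed rows with the offending line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt",
               "chr1\tx\tA\tG"), path)
  expect_error(read_variants(path), "line 2: non-integer position")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt",
               "chr1\t100\tA\tG",
               "chr1\t150\tC\tC"), path2)
  expect_error(read_variants(path2), "line 3: ref equals alt")
})

test_that("read_variants handles VCF input and skips indels", {
  skip_if_not_installed("vcfR")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##contig=<ID=chr1>',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\trs1\tA\tG\t.\tPASS\t.",
               "chr1\t150\trs2\tAT\tA\t.\tPASS\t.",
               "chr1\t200\t.\tC\tT\t.\tPASS\t."), path)
  expect_warning(v <- read_variants(path), "skipped 1")
  expect_equal(nrow(v), 2L)
  expect_equal(v$variant_id[1], "rs1")
  expect_equal(v$variant_id[2], "chr1_200_C_T")  # synthesized id
})

test_that("element sequences have length 2*flank+1, differ only at center", {
  genome <- make_tiny_genome()
  # choose positions whose genome base we then declare as the ref allele
  pos <- c(100L, 210L)
  df <- data.frame(variant_id = c("s1", "s2"), chrom = "chr1", pos = pos,
                   ref = vapply(pos, function(p) genome_base_at(genome, "chr1", p), ""),
                   alt = NA_character_, stringsAsFactors = FALSE)
  df$alt <- ifelse(df$ref == "A", "G", "A")
  v <- extract_element_sequences(df, genome, flank = 74)
  expect_equal(unique(nchar(v$ref_sequence)), 149L)
  expect_equal(unique(nchar(v$alt_sequence)), 149L)
  for (i in seq_len(nrow(v))) {
    diffs <- which(strsplit(v$ref_sequence[i], "")[[1]] !=
                     strsplit(v$alt_sequence[i], "")[[1]])
    expect_equal(diffs, 75L)  # the center of a 149-mer
    expect_equal(substr(v$ref_sequence[i], 75, 75), v$ref[i])
    expect_equal(substr(v$alt_sequence[i], 75, 75), v$alt[i])
  }
  # interval is 0-based half-open, covers pos, has sequence length
  expect_equal(v$element_end - v$element_start, rep(149L, 2))
  expect_true(all(v$element_start < v$pos & v$pos <= v$element_end))
})

test_that("flank 0 degenerates to the alleles themselves; bounds are enforced", {
  genome <- make_tiny_genome()
  ref <- genome_base_at(genome, "chr1", 50)
  df <- data.frame(variant_id = "s", chrom = "chr1", pos = 50L, ref = ref,
                   alt = ifelse(ref == "T", "C", "T"), stringsAsFactors = FALSE)
  v0 <- extract_element_sequences(df, genome, flank = 0)
  expect_equal(v0$ref_sequence, df$ref)
  expect_equal(v0$alt_sequence, df$alt)
  df$pos <- 10L
  expect_error(extract_element_sequences(df, genome, flank = 74), "out of bounds")
})

test_that("reference-allele mismatch errors in strict mode, drops in lenient mode", {
  genome <- make_tiny_genome()
  ref <- genome_base_at(genome, "chr1", 100)
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[1]
  df <- data.frame(variant_id = "bad", chrom = "chr1", pos = 100L, ref = wrong,
                   alt = ref, stringsAsFactors = FALSE)
  expect_error(extract_element_sequences(df, genome), "bad")
  expect_warning(v <- extract_element_sequences(df, genome, strict = FALSE), "dropped")
  expect_equal(nrow(v), 0L)
})

test_that("element construction invariants hold over random SNVs (property)", {
  genome <- make_tiny_genome(len = 1000, seed = 11)
  set.seed(13)
  flank <- sample(0:74, 1)
  pos <- sample(100:900, 25)
  ref <- vapply(pos, function(p) genome_base_at(genome, "chr2", p), "")
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  df <- data.frame(variant_id = paste0("p", seq_along(pos)), chrom = "chr2",
                   pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
  v <- extract_element_sequences(df, genome, flank = flank)
  expect_equal(nrow(v), 25L)
  expect_true(all(nchar(v$ref_sequence) == 2 * flank + 1))
  expect_true(all(v$ref != v$alt))
  n_diff <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                   v$ref_sequence, v$alt_sequence)
  expect_true(all(n_diff == 1))
})

test_that("read_matrix types, imputes binding gaps by TF median, validates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tTF_A\tTF_B",
               "v1\t0.1\t0.5",
               "v2\t\t0.7",
               "v3\t0.3\t0.9"), path)
  expect_message(m <- read_matrix(path, "binding_ref"), "imputed 1")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m["v2", "TF_A"], 0.2)  # median of 0.1, 0.3

  path_counts <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tcell_type\tassay_ref\tctrl_ref\tassay_alt\tctrl_alt",
               "v1\tGM\t10\t10\t30\t10"), path_counts)
  cc <- read_matrix(path_counts, "counts")
  expect_s3_class(cc, "mpra_counts")
  expect_equal(cc$n3, 30)

  path_neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tcell_type\tassay_ref\tctrl_ref\tassay_alt\tctrl_alt",
               "v1\tGM\t10\t-1\t30\t10"), path_neg)
  expect_error(read_matrix(path_neg, "counts"), "negative count")

  path_dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tTF_A", "v1\t0.1", "v1\t0.2"), path_dup)
  expect_error(read_matrix(path_dup, "binding_ref"), "duplicate")
})

test_that("matrix and count TSVs round-trip to identical typed objects", {
  bsm <- make_tiny_bsm()
  d <- withr::local_tempdir()
  write_matrix(bsm$scores_ref, file.path(d, "ref.tsv"), id_col = "variant_id")
  write_matrix(bsm$scores_alt, file.path(d, "alt.tsv"), id_col = "variant_id")
  bsm2 <- read_binding_scores(file.path(d, "ref.tsv"), file.path(d, "alt.tsv"))
  expect_equal(bsm2$scores_ref, bsm$scores_ref, tolerance = 1e-12)
  expect_equal(bsm2$scores_alt, bsm$scores_alt, tolerance = 1e-12)

  counts <- make_counts_df(list("v1", "GM", 10, 10, 30, 10),
                           list("v2", "GM", 5.5, 8, 2, 9))
  write_counts(counts, file.path(d, "counts.tsv"))
  counts2 <- read_matrix(file.path(d, "counts.tsv"), "counts")
  expect_equal(as.data.frame(counts2), as.data.frame(counts), tolerance = 1e-12)

  v <- data.frame(variant_id = "rs1", chrom = "chr1", pos = 100L, ref = "A",
                  alt = "G", stringsAsFactors = FALSE)
  write_variants(gram:::new_gram_variants(v), file.path(d, "vars.tsv"))
  v2 <- read_variants(file.path(d, "vars.tsv"))
  expect_equal(as.data.frame(v2), v, ignore_attr = TRUE)
})

test_that("model bundles round-trip through disk and align schemas by TF id", {
  tm <- tiny_trained_model()
  bundle <- tm$bundle
  ds <- tm$sim$dataset
  d <- withr::local_tempdir()
  save_bundle(bundle, file.path(d, "bundle"))
  loaded <- load_bundle(file.path(d, "bundle"))

  vids <- variant_ids(ds$bsm)[1:10]
  orig <- predict_gram(bundle, ds$bsm, ds$expression, variants = vids)
  roundtrip <- predict_gram(loaded, ds$bsm, ds$expression, variants = vids)
  expect_identical(orig$M, roundtrip$M)

  # permuting TF columns must not change predictions (schema matched by id)
  perm <- sample(seq_along(tf_ids(ds$bsm)))
  bsm_perm <- binding_scores(ds$bsm$scores_ref[, perm], ds$bsm$scores_alt[, perm])
  permuted <- predict_gram(loaded, bsm_perm, ds$expression, variants = vids)
  expect_identical(orig$M, permuted$M)
})

test_that("loading a corrupted bundle fails loudly", {
  tm <- tiny_trained_model()
  d <- withr::local_tempdir()
  save_bundle(tm$bundle, file.path(d, "b"))
  mf <- file.path(d, "b", "manifest.json")
  manifest <- jsonlite::read_json(mf)
  manifest$step3_coefficients <- NULL
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE)
  expect_error(load_bundle(file.path(d, "b")), "step3 coefficients")

  manifest2 <- jsonlite::read_json(mf)
  manifest2$format_version <- "0.9"
  jsonlite::write_json(manifest2, mf, auto_unbox = TRUE)
  expect_error(load_bundle(file.path(d, "b")), "version mismatch")
})
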