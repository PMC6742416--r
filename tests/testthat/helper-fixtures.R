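# Shared fixture builders. Everything is generated in code at test time;
# heavier trained objects are cached per session via lazy accessors.

make_tiny_bsm <- function(V = 4, N = 3, seed = 42) {
  vids <- paste0("v", seq_len(V))
  tfs <- paste0("TF_", LETTERS[seq_len(N)])
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    ref <- matrix(rnorm(V * N), V, N, dimnames = list(vids, tfs))
    alt <- ref + matrix(rnorm(V * N, 0, 0.5), V, N)
    binding_scores(ref, alt)
  })
}

make_counts_df <- function(...) {
  rows <- list(...)
  mpra_counts(do.call(rbind, lapply(rows, function(r) {
    data.frame(variant_id = r[[1]], cell_type = r[[2]],
               n1 = r[[3]], n2 = r[[4]], n3 = r[[5]], n4 = r[[6]],
               stringsAsFactors = FALSE)
  })))
}

# A small synthetic genome with known bases for sequence-extraction tests.
make_tiny_genome <- function(len = 400, seed = 7) {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  c(chr1 = s, chr2 = s)
}

genome_base_at <- function(genome, chrom, pos) substr(genome[[chrom]], pos, pos)

# Small trained models shared by scoring-oriented tests (lazily built once).
.tiny_model_cache <- new.env(parent = emptyenv())
tiny_trained_model <- function() {
  if (is.null(.tiny_model_cache$bundle)) {
    cfg <- simulation_config(V = 250, N = 12, n_signal_tfs = 3, seed = 5)
    mc <- gram_config(seed = 5, n_trees = 150, step3_cv_k = 5)
    sim <- simulate_gram_dataset(cfg, model_config = mc)
    .tiny_model_cache$sim <- sim
    .tiny_model_cache$bundle <- train_full(sim$dataset)
  }
  list(sim = .tiny_model_cache$sim, bundle = .tiny_model_cache$bundle)
}

# A fully expression-gated, activity-enriched scenario: the signal TFs gate
# the effect completely and elements are enriched for signal-TF binding, as
# assayed libraries are. Used by cell-type-specificity checks.
gated_trained_model <- function() {
  if (is.null(.tiny_model_cache$gated_bundle)) {
    cfg <- simulation_config(V = 400, N = 12, n_signal_tfs = 3,
                             expression_coupling = 1, expr_on_prob = 0.5,
                             signal_binding_mean = 1,
                             cell_types = paste0("cell", LETTERS[1:4]), seed = 5)
    mc <- gram_config(seed = 5, n_trees = 200, step3_cv_k = 5)
    sim <- simulate_gram_dataset(cfg, model_config = mc)
    .tiny_model_cache$gated_sim <- sim
    .tiny_model_cache$gated_bundle <- train_full(sim$dataset)
  }
  list(sim = .tiny_model_cache$gated_sim, bundle = .tiny_model_cache$gated_bundle)
}
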