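## Synthetic-data generator. Emits binding-score matrices with a sparse
## signal-TF structure, cell-type expression profiles that gate those
## signals, and MPRA count tables whose allelic skew is driven by the gated
## binding deltas -- plus the latent ground truth, so every downstream stage
## has a recovery oracle.

#' Simulation configuration
#'
#' The defaults define the package's "strong-signal" study condition: 2000
#' variants scored against 30 TFs of which 5 carry signal, two cell types,
#' and read depths typical of a well-powered MPRA.
#'
#' @param V number of variants.
#' @param N number of TFs.
#' @param n_signal_tfs number of signal-carrying TFs (0 for a null design).
#' @param cell_types character vector of cell-type names.
#' @param effect_size slope from summed gated signal-TF binding to latent
#'   log2 regulatory activity.
#' @param skew_effect SD of the alt-minus-ref binding delta on signal TFs
#'   that a variant hit receives (0 for a null design).
#' @param expression_coupling in \[0, 1\]: how strongly cell-type expression
#'   gates the signal (0 = no gating, 1 = fully proportional).
#' @param count_depth mean control read count.
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @param p_hit probability that a variant perturbs any given TF.
#' @param background_delta_sd SD of non-signal binding deltas.
#' @param signal_binding_mean baseline mean binding score of the signal TFs
#'   (0 = unselected elements; positive values emulate a library enriched
#'   for elements bound by the signal TFs, as assayed variant sets are).
#' @param expr_on_prob probability that a signal TF is expressed ("on") in a
#'   given cell type.
#' @param seed base seed; the generator derives sub-seeds from it.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(V = 2000, N = 30, n_signal_tfs = 5,
                              cell_types = c("cellA", "cellB"),
                              effect_size = 1, skew_effect = 2,
                              expression_coupling = 0.5,
                              count_depth = 100, dispersion = 0.1,
                              p_hit = 0.25, background_delta_sd = 0.2,
                              signal_binding_mean = 0,
                              expr_on_prob = 0.8, seed = 1) {
  assert_that(n_signal_tfs >= 0 && n_signal_tfs <= N,
              "need 0 <= n_signal_tfs <= N")
  assert_that(count_depth > 0, "count_depth must be positive")
  assert_that(expression_coupling >= 0 && expression_coupling <= 1,
              "expression_coupling must be in [0, 1]")
  structure(list(V = V, N = N, n_signal_tfs = n_signal_tfs,
                 cell_types = cell_types, effect_size = effect_size,
                 skew_effect = skew_effect,
                 expression_coupling = expression_coupling,
                 count_depth = count_depth, dispersion = dispersion,
                 p_hit = p_hit, background_delta_sd = background_delta_sd,
                 signal_binding_mean = signal_binding_mean,
                 expr_on_prob = expr_on_prob, seed = seed),
            class = "sim_config")
}

#' A named null/strong scenario configuration
#'
#' `"strong"` is the generator's default condition; `"null"` removes all
#' signal (no signal TFs, zero skew effect) so downstream labels carry no
#' information about the features.
#'
#' @param scenario `"strong"` or `"null"`.
#' @param ... overrides passed to [simulation_config()].
#' @return a `sim_config`.
#' @export
simulation_scenario <- function(scenario = c("strong", "null"), ...) {
  scenario <- match.arg(scenario)
  base <- if (scenario == "null") {
    simulation_config(n_signal_tfs = 0, skew_effect = 0, ...)
  } else {
    simulation_config(...)
  }
  base
}

sim_variant_ids <- function(V) sprintf("var%04d", seq_len(V))
sim_tf_ids <- function(N) sprintf("TF%03d", seq_len(N))

#' Simulate per-allele TF binding scores
#'
#' Reference scores are standard-normal; each (variant, TF) pair is perturbed
#' with probability `p_hit`, receiving an alt-allele delta whose SD is
#' `skew_effect` for signal TFs and `background_delta_sd` otherwise. The
#' first `n_signal_tfs` TF ids are the signal TFs.
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed (default derived from the config).
#' @return list with `bsm` (a `binding_scores`) and `truth` (list with
#'   `signal_tfs`, `delta` matrix, `hit` mask).
#' @export
simulate_binding <- function(config, seed = config$seed) {
  V <- config$V; N <- config$N
  vids <- sim_variant_ids(V); tfs <- sim_tf_ids(N)
  signal_tfs <- head(tfs, config$n_signal_tfs)
  out <- with_seed(seed, {
    ref <- matrix(rnorm(V * N), V, N, dimnames = list(vids, tfs))
    if (length(signal_tfs) > 0 && (config$signal_binding_mean %||% 0) != 0) {
      ref[, signal_tfs] <- ref[, signal_tfs] + config$signal_binding_mean
    }
    hit <- matrix(rbinom(V * N, 1, config$p_hit) == 1, V, N,
                  dimnames = list(vids, tfs))
    sd_per_tf <- ifelse(tfs %in% signal_tfs, config$skew_effect,
                        config$background_delta_sd)
    delta <- matrix(rnorm(V * N), V, N, dimnames = list(vids, tfs))
    delta <- sweep(delta, 2, sd_per_tf, `*`) * hit
    list(ref = ref, delta = delta, hit = hit)
  })
  list(bsm = binding_scores(out$ref, out$ref + out$delta,
                            assay_type = rep("SELEX", N)),
       truth = list(signal_tfs = signal_tfs, delta = out$delta, hit = out$hit))
}

#' Simulate cell-type TF expression profiles
#'
#' All cell types are drawn from the same law: signal TFs are "on"
#' (log-scale mean 6) with probability `expr_on_prob` and otherwise nearly
#' silent (mean 1.5); non-signal TFs are always expressed around the same
#' level. Differential on/off states across cell types are what make the
#' expression modifier arm learnable.
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed.
#' @return list with `expression` (an `expression_profiles` matrix, cell
#'   types x TFs) and `truth` (`on` logical matrix for signal TFs).
#' @export
simulate_expression <- function(config, seed = config$seed + 1) {
  tfs <- sim_tf_ids(config$N)
  cells <- config$cell_types
  signal_tfs <- head(tfs, config$n_signal_tfs)
  out <- with_seed(seed, {
    e <- matrix(pmax(rnorm(length(cells) * config$N, 6, 1), 0),
                length(cells), config$N, dimnames = list(cells, tfs))
    on <- matrix(TRUE, length(cells), length(signal_tfs),
                 dimnames = list(cells, signal_tfs))
    for (tf in signal_tfs) {
      state <- rbinom(length(cells), 1, config$expr_on_prob) == 1
      on[, tf] <- state
      e[, tf] <- pmax(ifelse(state, rnorm(length(cells), 6, 0.5),
                             rnorm(length(cells), 1.5, 0.5)), 0)
    }
    list(e = e, on = on)
  })
  list(expression = expression_profiles(out$e), truth = list(on = out$on))
}

## Expression gate in [1 - coupling, 1]: proportional to expression level,
## saturating at the nominal "on" level of 6.
expression_gate <- function(expr_row, coupling) {
  (1 - coupling) + coupling * pmin(expr_row / 6, 1)
}

#' Simulate MPRA count tables from binding and expression
#'
#' The latent log2 activity of an allele in a cell is the expression-gated
#' sum of its signal-TF binding scores times `effect_size`; assay counts are
#' negative-binomial around `depth * 2^activity`, controls around `depth`.
#' Ground-truth emVAR status is defined on the latent (noise-free) allelic
#' skew, so label noise is controlled only by depth and dispersion.
#'
#' @param config a [simulation_config()].
#' @param binding result of [simulate_binding()].
#' @param expression result of [simulate_expression()].
#' @param seed RNG seed.
#' @param skew_threshold emVAR threshold on the latent |log2 skew|.
#' @return list with `counts` (an `mpra_counts` data frame over variant x
#'   cell type) and `truth` (data frame with `latent_skew`, `is_emvar`,
#'   `active_ref`, `active_alt` per row).
#' @export
simulate_mpra_counts <- function(config, binding, expression,
                                 seed = config$seed + 2,
                                 skew_threshold = abs(log2(1.5))) {
  bsm <- binding$bsm
  expr <- expression$expression
  vids <- variant_ids(bsm)
  cells <- rownames(expr)
  signal_tfs <- binding$truth$signal_tfs
  n_sig <- length(signal_tfs)
  latent_z <- function(scores, gates) {
    if (n_sig == 0) return(rep(0, nrow(scores)))
    drop(scores[, signal_tfs, drop = FALSE] %*% gates) *
      config$effect_size / sqrt(n_sig)
  }
  draw_counts <- function(mu, n) {
    if (config$dispersion > 0) rnbinom(n, mu = mu, size = 1 / config$dispersion)
    else rpois(n, mu)
  }
  rows <- list()
  with_seed(seed, {
    for (cell in cells) {
      gates <- if (n_sig > 0) {
        expression_gate(expr[cell, signal_tfs], config$expression_coupling)
      } else numeric(0)
      z_ref <- latent_z(bsm$scores_ref, gates)
      z_alt <- latent_z(bsm$scores_alt, gates)
      fold_ref <- 2^pmin(pmax(z_ref, -6), 6)
      fold_alt <- 2^pmin(pmax(z_alt, -6), 6)
      d <- config$count_depth
      rows[[cell]] <- data.frame(
        variant_id = vids, cell_type = cell,
        n1 = draw_counts(d * fold_ref, length(vids)),
        n2 = draw_counts(rep(d, length(vids)), length(vids)),
        n3 = draw_counts(d * fold_alt, length(vids)),
        n4 = draw_counts(rep(d, length(vids)), length(vids)),
        latent_skew = z_alt - z_ref,
        active_ref = fold_ref > 1.5,
        active_alt = fold_alt > 1.5,
        stringsAsFactors = FALSE)
    }
  })
  all_rows <- do.call(rbind, rows)
  rownames(all_rows) <- NULL
  truth <- data.frame(variant_id = all_rows$variant_id,
                      cell_type = all_rows$cell_type,
                      latent_skew = all_rows$latent_skew,
                      is_emvar = abs(all_rows$latent_skew) > skew_threshold,
                      active_ref = all_rows$active_ref,
                      active_alt = all_rows$active_alt,
                      stringsAsFactors = FALSE)
  counts <- mpra_counts(all_rows[, c("variant_id", "cell_type", "n1", "n2", "n3", "n4")])
  list(counts = counts, truth = truth)
}

#' Simulate a complete training dataset
#'
#' Chains binding, expression and count simulation and assembles a
#' [gram_dataset()]. emVAR labels come from the latent ground truth when it
#' contains both classes (`label_source = "latent"`, the default for signal
#' designs) and otherwise from the observed counts -- a null design has no
#' latent positives, so only observed calls are usable there.
#'
#' @param config a [simulation_config()].
#' @param label_source `"latent"`, `"observed"`, or `"auto"` (default:
#'   latent when the latent truth has both classes).
#' @param model_config a [gram_config()] for label derivation.
#' @return list with the `dataset`, the generator pieces (`binding`,
#'   `expression_sim`, `mpra`) and the `truth` tables.
#' @export
simulate_gram_dataset <- function(config = simulation_config(),
                                  label_source = c("auto", "latent", "observed"),
                                  model_config = gram_config(seed = config$seed)) {
  label_source <- match.arg(label_source)
  binding <- simulate_binding(config)
  expr <- simulate_expression(config)
  mpra <- simulate_mpra_counts(config, binding, expr,
                               skew_threshold = model_config$skew_threshold)
  use_latent <- switch(label_source,
                       latent = TRUE, observed = FALSE,
                       auto = length(unique(mpra$truth$is_emvar)) == 2)
  emvar <- if (use_latent) {
    mpra$truth[, c("variant_id", "cell_type", "is_emvar")]
  } else NULL
  dataset <- gram_dataset(binding$bsm, expr$expression, mpra$counts,
                          emvar_labels = emvar, config = model_config)
  list(dataset = dataset, binding = binding, expression_sim = expr,
       mpra = mpra, truth = list(binding = binding$truth,
                                 expression = expr$truth,
                                 labels = mpra$truth),
       label_source = if (use_latent) "latent" else "observed")
}

#' Simulate an eQTL fine-mapping cohort with one planted causal variant
#'
#' Generates a region of candidate variants scored against the same TF
#' schema as a simulation config, per-sample expression profiles, genotype
#' dosages, and per-sample target-gene expression. Exactly one variant (the
#' planted causal) carries a large binding delta on a signal TF and drives
#' its target gene's expression through its dosage; all other variants carry
#' only background deltas on non-signal TFs.
#'
#' @param config a [simulation_config()] (defines the TF schema).
#' @param n_variants number of region variants.
#' @param n_samples number of cohort samples.
#' @param causal_delta binding delta of the planted causal variant.
#' @param maf minor-allele frequency for genotype dosages.
#' @param seed RNG seed.
#' @return a `gram_cohort` list: `region`, `variant_ids`, `bsm`,
#'   `genotypes` (samples x variants), `expression` (samples x TFs),
#'   `eqtl_targets` (variant -> gene), `target_expression` (samples x genes)
#'   and `causal_variant`.
#' @export
simulate_cohort <- function(config = simulation_config(), n_variants = 50,
                            n_samples = 60, causal_delta = 3, maf = 0.3,
                            seed = config$seed) {
  tfs <- sim_tf_ids(config$N)
  signal_tfs <- head(tfs, max(config$n_signal_tfs, 1))
  vids <- sprintf("rsim%04d", seq_len(n_variants))
  sids <- sprintf("sample%03d", seq_len(n_samples))
  genes <- sprintf("gene_%s", vids)
  out <- with_seed(seed, {
    ref <- matrix(rnorm(n_variants * config$N), n_variants, config$N,
                  dimnames = list(vids, tfs))
    delta <- matrix(rnorm(n_variants * config$N, 0, config$background_delta_sd) *
                      (rbinom(n_variants * config$N, 1, config$p_hit)),
                    n_variants, config$N, dimnames = list(vids, tfs))
    delta[, signal_tfs] <- 0   # background never touches signal TFs here
    causal <- sample(vids, 1)
    delta[causal, signal_tfs[1]] <- causal_delta
    e <- matrix(pmax(rnorm(n_samples * config$N, 6, 1), 0), n_samples, config$N,
                dimnames = list(sids, tfs))
    e[, signal_tfs] <- pmax(rnorm(n_samples * length(signal_tfs), 6, 0.5), 0)
    geno <- matrix(rbinom(n_samples * n_variants, 2, maf), n_samples, n_variants,
                   dimnames = list(sids, vids))
    tgt <- matrix(rnorm(n_samples * n_variants, 0, 1), n_samples, n_variants,
                  dimnames = list(sids, genes))
    tgt[, paste0("gene_", causal)] <- geno[, causal] + rnorm(n_samples, 0, 0.5)
    list(ref = ref, delta = delta, causal = causal, e = e, geno = geno, tgt = tgt)
  })
  structure(list(region = "chrS:1-1000000",
                 variant_ids = vids,
                 bsm = binding_scores(out$ref, out$ref + out$delta),
                 genotypes = out$geno,
                 expression = expression_profiles(out$e),
                 eqtl_targets = setNames(genes, vids),
                 target_expression = out$tgt,
                 causal_variant = out$causal),
            class = "gram_cohort")
}

#' Write the full synthetic fixture set to a directory
#'
#' Emits the variant list, both binding-score layers, expression profiles,
#' MPRA counts and the latent truth table as plain TSV files.
#'
#' @param sim result of [simulate_gram_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bsm <- sim$dataset$bsm
  write_matrix(bsm$scores_ref, file.path(dir, "binding_ref.tsv"), id_col = "variant_id")
  write_matrix(bsm$scores_alt, file.path(dir, "binding_alt.tsv"), id_col = "variant_id")
  write_matrix(unclass(sim$dataset$expression), file.path(dir, "expression.tsv"),
               id_col = "sample_id")
  write_counts(sim$dataset$counts, file.path(dir, "counts.tsv"))
  data.table::fwrite(sim$truth$labels, file.path(dir, "truth.tsv"), sep = "\t")
  invisible(dir)
}
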