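# End-to-end orchestration: simulate -> pairs -> featurize -> train ->
# evaluate -> compare -> interpret, with a reproducibility manifest.

#' Desk-scale SMALL-only synthetic configuration
#'
#' A compact configuration restricted to the SMALL distance class, used by
#' the end-to-end pipeline smoke run.
#'
#' @param seed Integer seed.
#' @param n_snps Number of SNPs.
#' @return A `synthetic_config`.
#' @export
small_only_config <- function(seed = 1L, n_snps = 60L) {
  synthetic_config(seed = seed, n_chroms = 2L, chrom_len = 200000L,
                   n_snps = n_snps, pairs_per_snp = 3L,
                   distance_range = c(300L, 9500L))
}

#' Run the full pipeline on a synthetic dataset
#'
#' Generates data, builds and balances pairs, featurizes the SMALL class,
#' trains direction and slope models, evaluates on a held-out split,
#' categorizes CpGs under case vs control accessibility, runs the
#' functional-region activation comparison, and writes all outputs plus a
#' manifest (inputs, seeds, output hashes) to `out_dir`. Identical seeds
#' yield identical manifests.
#'
#' @param out_dir Output directory.
#' @param seed Integer master seed.
#' @param sim_config A `synthetic_config` (SMALL-only by default).
#' @param hidden,max_epochs,batch_size Model size/budget for the run.
#' @return Invisibly, a list with the trained models, metrics, category
#'   table, region comparison, and manifest.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         sim_config = small_only_config(seed),
                         hidden = 8L, max_epochs = 3L, batch_size = 32L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(out_dir, "data")
  sim <- synthetic_generate(sim_config, data_dir)

  records <- read_meqtl_table(sim$files$meqtl, genome = sim$genome)
  pairs <- build_pairs(records)
  pairs <- balance_by_chromosome(pairs, seed = seed)
  pairs_file <- file.path(out_dir, "pairs.tsv")
  write.table(pairs, pairs_file, sep = "\t", quote = FALSE, row.names = FALSE)

  small <- pairs[pairs$size_class == "SMALL", , drop = FALSE]
  plan <- plan_cuts("SMALL")
  feats <- featurize_pairs(small, sim$genome, sim$atac_control, plan)
  small <- small[feats$kept, , drop = FALSE]

  split <- split_pairs(small, "HOLDOUT", seed = seed)
  y_dir <- direction_to_target(small$direction_label)
  y_slope <- small$slope
  shape <- dim(feats$x)[2:3]

  cls_cfg <- model_config("CLASSIFY", recurrent_hidden = hidden,
                          fc_sizes = c(16L, 8L), max_epochs = max_epochs,
                          batch_size = batch_size, seed = seed)
  cls <- train_model(build_model(cls_cfg, shape),
                     feats$x[split$train, , , drop = FALSE], y_dir[split$train],
                     feats$x[split$val, , , drop = FALSE], y_dir[split$val])
  reg_cfg <- model_config("REGRESS", recurrent_hidden = hidden,
                          fc_sizes = c(16L, 8L), max_epochs = max_epochs,
                          batch_size = batch_size, seed = seed + 1L)
  reg <- train_model(build_model(reg_cfg, shape),
                     feats$x[split$train, , , drop = FALSE], y_slope[split$train],
                     feats$x[split$val, , , drop = FALSE], y_slope[split$val])

  cls_met <- classification_metrics(
    predict_model(cls, feats$x[split$test, , , drop = FALSE]), y_dir[split$test])
  reg_met <- regression_metrics(
    predict_model(reg, feats$x[split$test, , , drop = FALSE]), y_slope[split$test])
  metrics <- data.frame(metric = c(names(cls_met), names(reg_met)),
                        task = c(rep("CLASSIFY", length(cls_met)),
                                 rep("REGRESS", length(reg_met))),
                        value = unlist(c(cls_met, reg_met), use.names = FALSE))
  metrics_file <- file.path(out_dir, "metrics.tsv")
  write.table(metrics, metrics_file, sep = "\t", quote = FALSE, row.names = FALSE)

  # condition comparison on the test pairs
  test_pairs <- small[split$test, , drop = FALSE]
  slopes <- lapply(seq_len(nrow(test_pairs)), function(i)
    predict_conditions(reg, test_pairs[i, , drop = FALSE], sim$atac_case,
                       sim$atac_control, sim$genome, plan))
  compare <- data.frame(
    snp_id = test_pairs$snp_id, cpg_id = test_pairs$cpg_id,
    slope_case = vapply(slopes, `[[`, numeric(1), "slope_case"),
    slope_control = vapply(slopes, `[[`, numeric(1), "slope_control"))
  compare$delta <- abs(compare$slope_case - compare$slope_control)
  compare$category <- categorize_affect(compare$slope_case, compare$slope_control)
  compare_file <- file.path(out_dir, "compare.tsv")
  write.table(format(compare, digits = 8), compare_file, sep = "\t",
              quote = FALSE, row.names = FALSE)

  # hidden-state vs functional-region comparison on a handful of windows
  n_prof <- min(20L, nrow(test_pairs))
  windows <- lapply(seq_len(n_prof), function(i)
    extract_window(sim$genome, sim$atac_control,
                   test_pairs[i, , drop = FALSE], plan))
  prof <- activation_profile(cls, feats$x[split$test[seq_len(n_prof)], , ,
                                          drop = FALSE], windows, plan)
  regions <- compare_regions(prof, sim$regions)
  interpret_file <- file.path(out_dir, "interpret.tsv")
  write.table(format(regions, digits = 8), interpret_file, sep = "\t",
              quote = FALSE, row.names = FALSE)

  outputs <- c(sim$files$meqtl, sim$files$genome, pairs_file, metrics_file,
               compare_file, interpret_file)
  manifest <- list(
    seed = seed,
    sim_config = unclass(sim_config),
    model = list(hidden = hidden, max_epochs = max_epochs,
                 batch_size = batch_size),
    n_pairs = nrow(pairs), n_small = nrow(small),
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(sim = sim, pairs = pairs, classify = cls, regress = reg,
                 metrics = metrics, compare = compare, regions = regions,
                 manifest = manifest))
}
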