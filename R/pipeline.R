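#' Prepare classifier inputs from ASV datasets and alignment hits
#'
#' Runs the full profiling stage for each cohort: coverage and rare-ASV
#' filtering, ASV-to-genome mapping and multi-taxonomic assignment from the
#' hit table, genus-level taxonomic feature aggregation, a neighbor-joining
#' midpoint-rooted tree over the cohort's ASVs, and CPI/PAD profiles.
#'
#' @param datasets named list of [asv_dataset()] objects.
#' @param hits alignment hit table (ASVs vs reference 16S sequences).
#' @param reference a `"reference_collection"`.
#' @param min_reads coverage threshold (samples at or below it are dropped).
#' @param scale,drop_threshold top-hit selection parameters.
#' @param carrier_threshold PAD carrier probability cutoff.
#' @param filter_asvs apply the rare-ASV filter (default TRUE).
#' @return named list per cohort with elements `taxonomy`, `phenotype` (CPI),
#'   `pad` and `labels`, as consumed by [train_and_evaluate()].
#' @export
prepare_ml_inputs <- function(datasets, hits, reference, min_reads = 15000,
                              scale = 4, drop_threshold = 0.85,
                              carrier_threshold = 0.6, filter_asvs = TRUE) {
  lookup <- reference$lineage[reference$genome_of[names(reference$seqs)], ,
                              drop = FALSE]
  rownames(lookup) <- names(reference$seqs)
  mappings <- map_all_asvs(hits, reference$genome_of, scale, drop_threshold)
  mtas <- assign_mta(hits, lookup, scale, drop_threshold)
  p_all <- phenotype_probability(mappings, reference$bpm)

  out <- lapply(datasets, function(ds) {
    ds <- filter_by_coverage(ds, min_reads)
    if (filter_asvs) ds <- filter_asv_table(ds)
    tree <- midpoint_root(build_tree(ds$rep_seqs))
    taxonomy <- suppressMessages(
      aggregate_genus_features(ds$abundance, mtas))
    cpi <- compute_cpi(ds, p_all)
    pad <- compute_pad(ds, p_all, tree, carrier_threshold)
    list(taxonomy = taxonomy, phenotype = cpi, pad = pad,
         labels = ds$labels)
  })
  names(out) <- names(datasets)
  out
}

#' End-to-end planted-effect recovery benchmark
#'
#' Generates a full synthetic study from one master seed, optionally plants
#' a case enrichment of a broadly distributed phenotype, runs the complete
#' classifier suite for the phenotype predictor set, and reports the stable
#' predictors. With a strong planted effect the target phenotype should be
#' recovered as a stable predictor with positive (case-enriched) direction;
#' with no effect the classifiers should perform at chance and yield
#' (almost) no stable predictors.
#'
#' The planted target is chosen deterministically from the generated
#' reference as the first random-type (phylogenetically unclustered)
#' phenotype with genome carrier prevalence in `[0.4, 0.6]` - a phenotype
#' that is a legitimate candidate feature (mid-range CPI, high PAD) rather
#' than a clade marker.
#'
#' @param seed master seed.
#' @param effect_lfc log-fold enrichment of carrier ASVs in case samples;
#'   `NULL` runs the zero-effect (null) scenario.
#' @param contrast case group (default `"CD"`).
#' @param scenario_args named list overriding [synthetic_scenario()] defaults.
#' @param n_iterations_single,n_iterations_l1o,n_sub,top_k classifier suite
#'   sizes, see [enumerate_configs()].
#' @return list with `target` (planted phenotype or `NA`), `recovered`
#'   (logical), `stable` (stable predictor table), `suite` (full
#'   [run_variant_suite()] output) and `truth`.
#' @export
run_planted_recovery <- function(seed, effect_lfc = log(4), contrast = "CD",
                                 scenario_args = list(),
                                 n_iterations_single = 10,
                                 n_iterations_l1o = 3, n_sub = 10,
                                 top_k = 20) {
  base <- do.call(synthetic_scenario, c(list(seed = seed), scenario_args))
  ref <- generate_reference(base)

  target <- NA_character_
  effects <- list()
  if (!is.null(effect_lfc)) {
    prev <- colMeans(unclass(ref$bpm))
    cand <- names(prev)[ref$phenotype_type == "random" &
                          prev >= 0.4 & prev <= 0.6]
    if (length(cand) == 0)
      stop("no mid-prevalence random phenotype available as planted target")
    target <- cand[1]
    effects <- list(planted_effect(target, "phenotype", "enrich",
                                   lfc = effect_lfc, status = contrast))
  }
  scen <- do.call(synthetic_scenario,
                  c(list(seed = seed, planted_effects = effects),
                    scenario_args))
  gen <- generate_datasets(scen, ref)
  hits <- generate_hits(gen$asv_seqs, ref$seqs)
  inputs <- prepare_ml_inputs(gen$datasets, hits, ref)
  suite <- run_variant_suite(inputs, predictor_set = "phenotype",
                             contrast = contrast,
                             seed = derive_seed(seed, 7),
                             n_iterations_single = n_iterations_single,
                             n_iterations_l1o = n_iterations_l1o,
                             n_sub = n_sub, top_k = top_k)
  stable <- identify_stable_predictors(suite$variant_importances,
                                       suite$group_diffs)
  recovered <- !is.na(target) && target %in% stable$feature &&
    stable$direction[stable$feature == target] == 1L
  list(target = target, recovered = recovered, stable = stable,
       suite = suite, truth = gen$truth)
}
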