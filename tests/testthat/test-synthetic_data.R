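small_scenario <- function(...) {
  defaults <- list(n_genomes = 30, n_phenotypes = 10, n_asvs = 40,
                   seq_length = 120, n_datasets = 2,
                   group_sizes = c(HC = 12, CD = 8, UC = 6))
  do.call(synthetic_scenario, utils::modifyList(defaults, list(...)))
}

test_that("zero substitution rate yields identical sequences", {
  ref <- generate_reference(small_scenario(substitution_rate = 0, seed = 5))
  expect_length(unique(unname(ref$seqs)), 1L)
})

test_that("clustered phenotypes are carried by a connected clade", {
  ref <- generate_reference(small_scenario(clustered_frac = 1, seed = 7))
  for (ph in colnames(ref$bpm)) {
    carriers <- rownames(ref$bpm)[unclass(ref$bpm)[, ph] == 1]
    expect_gte(length(carriers), 2)
    expect_true(ape::is.monophyletic(ref$tree, carriers))
  }
})

test_that("random phenotype carrier fractions stay in Bernoulli bounds", {
  scen <- synthetic_scenario(n_genomes = 200, n_phenotypes = 30,
                             clustered_frac = 0, seed = 9)
  ref <- generate_reference(scen)
  frac <- colMeans(unclass(ref$bpm))
  # carrier probabilities are drawn from [0.25, 0.75]; allow a 99.9% binomial
  # margin at n = 200 around the extremes
  margin <- 3.3 * sqrt(0.25 * 0.75 / 200)
  expect_true(all(frac > 0.25 - margin & frac < 0.75 + margin))
  expect_true(all(ref$phenotype_type == "random"))
})

test_that("generated abundances close to 1 and labels match group sizes", {
  scen <- small_scenario(seed = 11)
  gen <- generate_datasets(scen, generate_reference(scen))
  expect_length(gen$datasets, 2)
  for (ds in gen$datasets) {
    expect_equal(unname(rowSums(ds$abundance)), rep(1, nrow(ds$abundance)),
                 tolerance = 1e-12)
    expect_equal(as.vector(table(ds$labels)[c("HC", "CD", "UC")]),
                 c(12, 8, 6))
  }
})

test_that("zero effects leave case and control exchangeable; planted effects shift them", {
  scen <- small_scenario(seed = 13)
  ref <- generate_reference(scen)
  gen0 <- generate_datasets(scen, ref)
  # no planted effect: no affected sets recorded
  expect_length(gen0$truth$affected, 0)

  genus <- ref$lineage[gen0$truth$source_genome, "genus"]
  target <- names(sort(table(genus), decreasing = TRUE))[1]
  scen1 <- small_scenario(
    seed = 13, group_sizes = c(HC = 60, CD = 60, UC = 2),
    planted_effects = list(planted_effect(target, "genus", "deplete",
                                          lfc = log(8), status = "CD")))
  gen1 <- generate_datasets(scen1, ref)
  affected <- gen1$truth$affected[[1]]
  expect_gt(length(affected), 0)
  ds <- gen1$datasets[[1]]
  case_mean <- mean(rowSums(ds$abundance[ds$labels == "CD", affected,
                                         drop = FALSE]))
  ctrl_mean <- mean(rowSums(ds$abundance[ds$labels == "HC", affected,
                                         drop = FALSE]))
  expect_lt(case_mean, ctrl_mean / 2)
})

test_that("planted phenotype enrichment raises case CPI (recomputation oracle)", {
  scen <- small_scenario(seed = 17, group_sizes = c(HC = 50, CD = 50, UC = 2))
  ref <- generate_reference(scen)
  prev <- colMeans(unclass(ref$bpm))
  target <- names(prev)[prev > 0.3 & prev < 0.7][1]
  scen1 <- small_scenario(
    seed = 17, group_sizes = c(HC = 50, CD = 50, UC = 2),
    planted_effects = list(planted_effect(target, "phenotype", "enrich",
                                          lfc = log(6), status = "CD")))
  gen <- generate_datasets(scen1, ref)
  # ground-truth carriage from each ASV's source genome
  p_true <- matrix(unclass(ref$bpm)[gen$truth$source_genome, target],
                   ncol = 1,
                   dimnames = list(names(gen$truth$source_genome), target))
  ds <- gen$datasets[[1]]
  cpi <- compute_cpi(ds, p_true)
  expect_gt(mean(cpi[ds$labels == "CD", 1]), mean(cpi[ds$labels == "HC", 1]))
})

test_that("hit generation recovers sources, unassigned ASVs and ties", {
  refs <- c(`gA|1` = strrep("ACGT", 25), `gB|1` = strrep("TGCA", 25))
  # unmutated copy of gA
  hits <- generate_hits(c(q1 = strrep("ACGT", 25)), refs)
  best <- hits[which.max(hits$identity), ]
  expect_equal(best$subject_id, "gA|1")
  expect_equal(best$identity, 1)

  # ASV far from everything: no hit passes the drop threshold
  scrambled <- paste(rep(c("A", "T"), 50), collapse = "")
  hits2 <- generate_hits(c(q2 = scrambled), refs, min_report = 0)
  expect_equal(nrow(select_top_hits(hits2)), 0L)

  # equidistant two-base compromise between two near-identical references
  r1 <- strrep("A", 100)
  r2 <- paste0(strrep("A", 98), "CC")
  q <- paste0(strrep("A", 98), "CA")        # one mismatch to each
  hits3 <- generate_hits(c(q3 = q), c(`g1|1` = r1, `g2|1` = r2))
  m <- map_asv_to_genomes(hits3, c(`g1|1` = "g1", `g2|1` = "g2"))
  expect_equal(m, c(g1 = 0.5, g2 = 0.5))
})

test_that("a synthetic study materializes in pipeline-readable formats", {
  dir <- withr::local_tempdir()
  scen <- small_scenario(seed = 19)
  write_synthetic_study(scen, dir)
  ref <- load_reference_collection(
    file.path(dir, "reference", "reference_16S.fasta"),
    file.path(dir, "reference", "lineage.tsv"),
    file.path(dir, "reference", "bpm.tsv"),
    file.path(dir, "reference", "bpm_categories.tsv"))
  expect_s3_class(ref, "reference_collection")
  hits <- read_hits(file.path(dir, "hits.tsv"))
  expect_true(all(c("query_id", "subject_id", "identity") %in% colnames(hits)))
  a <- as.matrix(read.delim(file.path(dir, "D1_abundance.tsv"),
                            row.names = 1, check.names = FALSE))
  expect_equal(unname(rowSums(a)), rep(1, nrow(a)), tolerance = 1e-6)
  tree <- ape::read.tree(file.path(dir, "reference", "true_tree.nwk"))
  expect_setequal(tree$tip.label, unique(unname(ref$genome_of)))
})
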