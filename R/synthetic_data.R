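#' Synthetic study scenario
#'
#' Parameters of the synthetic benchmark: a reference collection evolved
#' along a birth-death phylogeny, binary phenotypes that are either
#' phylogenetically clustered (assigned to a clade) or random (i.i.d.
#' Bernoulli), and multiple case/control cohorts of ASVs drawn as mutated
#' copies of reference 16S sequences with log-normal abundance noise,
#' cohort-level batch offsets and optional planted case effects.
#'
#' The defaults describe a three-cohort study sized to run the full
#' 28-configuration classifier suite in minutes: 150 reference genomes, 300
#' ASVs and 60 healthy / 30 CD / 30 UC samples per cohort, with 250-bp
#' 16S-like sequences whose root-to-tip divergence (0.25 substitutions per
#' site) keeps within-clade alignment identities above the 0.85 drop
#' threshold while spreading distant clades far enough apart for meaningful
#' phylogenetic diversity.
#'
#' @param n_genomes number of reference genomes.
#' @param n_phenotypes number of binary phenotypes.
#' @param clustered_frac fraction of phenotypes assigned to a clade (high
#'   phylogenetic signal); the rest are Bernoulli with per-phenotype carrier
#'   probability drawn uniformly from `[0.25, 0.75]`.
#' @param tree_height root-to-tip height of the (ultrametric) genome tree in
#'   expected substitutions per site.
#' @param seq_length length of the simulated 16S fragments (bp).
#' @param substitution_rate scale on branch lengths during sequence
#'   simulation (0 makes all sequences identical).
#' @param second_copy_frac fraction of genomes carrying a second identical
#'   16S copy.
#' @param n_datasets number of cohorts.
#' @param group_sizes named vector of per-cohort sample counts by status.
#' @param n_asvs number of ASVs in the shared pool.
#' @param asv_mutations expected number of point mutations separating an ASV
#'   from its source genome's 16S sequence (Poisson).
#' @param sigma_base,sigma_batch,sigma_noise standard deviations of the
#'   log-normal abundance model: per-ASV baseline, per-cohort batch offset
#'   and per-sample noise.
#' @param read_depth mean per-sample read count (negative binomial, size 20).
#' @param planted_effects list of [planted_effect()] specifications.
#' @param seed master seed; all randomness derives from it.
#' @return a list of class `"synthetic_scenario"`.
#' @export
synthetic_scenario <- function(n_genomes = 150, n_phenotypes = 94,
                               clustered_frac = 0.5, tree_height = 0.25,
                               seq_length = 250, substitution_rate = 1,
                               second_copy_frac = 0.3, n_datasets = 3,
                               group_sizes = c(HC = 60, CD = 30, UC = 30),
                               n_asvs = 300, asv_mutations = 2,
                               sigma_base = 1, sigma_batch = 0.6,
                               sigma_noise = 1, read_depth = 30000,
                               planted_effects = list(), seed = 1) {
  stopifnot(n_genomes >= 4, n_phenotypes >= 1, n_datasets >= 1,
            all(group_sizes >= 1), seq_length >= 10, n_asvs >= 2,
            substitution_rate >= 0)
  structure(as.list(environment()), class = "synthetic_scenario")
}

#' Planted case effect
#'
#' Describes a multiplicative abundance effect applied to case samples
#' before renormalization: either all ASVs whose source genome carries a
#' phenotype (`target_type = "phenotype"`) or all ASVs originating from a
#' genus (`target_type = "genus"`) are enriched or depleted by the given
#' log-fold change. Compositional closure shifts off-target features
#' slightly, as in real data.
#'
#' @param target phenotype id or genus name.
#' @param target_type `"phenotype"` or `"genus"`.
#' @param direction `"enrich"` or `"deplete"`.
#' @param lfc log-fold change (natural log), finite and positive.
#' @param status case group the effect applies to (`"CD"` or `"UC"`).
#' @return a list of class `"planted_effect"`.
#' @export
planted_effect <- function(target, target_type = c("phenotype", "genus"),
                           direction = c("enrich", "deplete"),
                           lfc = log(4), status = "CD") {
  target_type <- match.arg(target_type)
  direction <- match.arg(direction)
  stopifnot(is.finite(lfc), lfc > 0, status %in% c("CD", "UC"))
  structure(list(target = target, target_type = target_type,
                 direction = direction, lfc = lfc, status = status),
            class = "planted_effect")
}

#' Generate a synthetic reference collection
#'
#' Simulates the genome phylogeny (pure-birth, rescaled to
#' `tree_height`), evolves 16S-like sequences along it under a Jukes-Cantor
#' model, derives a rank lineage by cutting the cophenetic distances at fixed
#' depths, and assigns binary phenotypes: clustered phenotypes are carried by
#' all tips of a randomly chosen clade (8-50% of genomes), random phenotypes
#' are i.i.d. Bernoulli draws.
#'
#' @param scenario a [synthetic_scenario()].
#' @return a `"reference_collection"` (as from [load_reference_collection()])
#'   with extra elements `tree` (the true genome phylogeny) and
#'   `phenotype_type` (named vector, `"clustered"` or `"random"`).
#' @export
generate_reference <- function(scenario) {
  local_seed(derive_seed(scenario$seed, 101))
  n <- scenario$n_genomes
  tree <- ape::rphylo(n, birth = 1, death = 0)
  tree$tip.label <- sprintf("g%03d", seq_len(n))
  depth <- max(ape::node.depth.edgelength(tree)[seq_len(n)])
  tree$edge.length <- tree$edge.length / depth * scenario$tree_height

  seqs1 <- simulate_sequences(tree, scenario$seq_length,
                              scenario$substitution_rate)
  copy2 <- sample(tree$tip.label, round(scenario$second_copy_frac * n))
  seqs <- c(stats::setNames(seqs1, paste0(names(seqs1), "|1")),
            stats::setNames(seqs1[copy2], paste0(copy2, "|2")))
  genome_of <- sub("\\|.*$", "", names(seqs))
  names(genome_of) <- names(seqs)

  lineage <- lineage_from_tree(tree)

  n_clustered <- round(scenario$n_phenotypes * scenario$clustered_frac)
  n_random <- scenario$n_phenotypes - n_clustered
  m <- matrix(0L, n, scenario$n_phenotypes,
              dimnames = list(tree$tip.label,
                              sprintf("phen%03d", seq_len(scenario$n_phenotypes))))
  clade_tips <- internal_clades(tree, min_frac = 0.08, max_frac = 0.5)
  ptype <- character(scenario$n_phenotypes)
  for (k in seq_len(scenario$n_phenotypes)) {
    if (k <= n_clustered) {
      tips <- clade_tips[[sample(length(clade_tips), 1)]]
      m[tips, k] <- 1L
      ptype[k] <- "clustered"
    } else {
      m[, k] <- stats::rbinom(n, 1, stats::runif(1, 0.25, 0.75))
      ptype[k] <- "random"
    }
  }
  categories <- stats::setNames(
    rep(c("vitamin synthesis", "amino-acid synthesis",
          "amino-acid degradation", "sugar utilization", "SCFA production",
          "GH family"), length.out = scenario$n_phenotypes),
    colnames(m))
  names(ptype) <- colnames(m)

  structure(list(seqs = seqs, genome_of = genome_of, lineage = lineage,
                 bpm = bpm(m, categories), tree = tree,
                 phenotype_type = ptype),
            class = "reference_collection")
}

# Jukes-Cantor sequence simulation along a tree; rate 0 short-circuits to a
# single random root sequence shared by all tips.
simulate_sequences <- function(tree, seq_length, rate) {
  bases <- c("a", "c", "g", "t")
  if (rate == 0) {
    root <- paste(sample(bases, seq_length, replace = TRUE), collapse = "")
    return(stats::setNames(rep(toupper(root), length(tree$tip.label)),
                           tree$tip.label))
  }
  sim <- phangorn::simSeq(tree, l = seq_length, type = "DNA", rate = rate)
  m <- toupper(as.character(sim))
  stats::setNames(apply(m, 1, paste, collapse = ""), rownames(m))[tree$tip.label]
}

# Rank lineage derived from average-linkage clustering of cophenetic
# distances, cut at fixed fractions of the maximum distance.
lineage_from_tree <- function(tree) {
  d <- stats::as.dist(ape::cophenetic.phylo(tree))
  hc <- stats::hclust(d, method = "average")
  cuts <- c(phylum = 0.8, class = 0.6, order = 0.45, family = 0.3,
            genus = 0.18)
  out <- data.frame(domain = rep("Bacteria", length(tree$tip.label)),
                    row.names = tree$tip.label)
  for (r in names(cuts)) {
    grp <- stats::cutree(hc, h = cuts[[r]] * max(d))
    out[[r]] <- sprintf("%s%02d", tools::toTitleCase(r), grp[rownames(out)])
  }
  out$species <- paste0(out$genus, "_sp_", rownames(out))
  out
}

# Tip sets of internal nodes whose clade size falls in [min_frac, max_frac]
# of the tips.
internal_clades <- function(tree, min_frac, max_frac) {
  n <- length(tree$tip.label)
  clades <- ape::prop.part(tree)
  labs <- attr(clades, "labels")
  sets <- lapply(clades, function(idx) labs[idx])
  sizes <- lengths(sets)
  sets[sizes >= max(2, min_frac * n) & sizes <= max_frac * n]
}

#' Generate synthetic case/control cohorts
#'
#' Draws a shared pool of ASVs as point-mutated copies of reference 16S
#' sequences, then builds each cohort from a log-normal abundance model:
#' per-ASV baseline plus a per-cohort batch offset plus per-sample noise,
#' exponentiated and closed to relative abundances. Planted effects multiply
#' the raw abundances of their target ASVs in case samples before closure.
#' Read counts are negative-binomial around `read_depth`.
#'
#' @param scenario a [synthetic_scenario()].
#' @param reference the matching [generate_reference()] output.
#' @return list with `datasets` (list of [asv_dataset()]), `asv_seqs` (the
#'   ASV pool), and `truth` (per-ASV source genome, per-effect affected ASV
#'   sets, and the effect list).
#' @export
generate_datasets <- function(scenario, reference) {
  local_seed(derive_seed(scenario$seed, 202))
  genomes <- unique(unname(reference$genome_of))
  n_asv <- scenario$n_asvs
  source_genome <- sample(genomes, n_asv, replace = TRUE)
  asv_ids <- sprintf("ASV%04d", seq_len(n_asv))
  names(source_genome) <- asv_ids
  base_seq <- reference$seqs[paste0(source_genome, "|1")]
  asv_seqs <- vapply(seq_len(n_asv), function(i) {
    mutate_sequence(base_seq[[i]], stats::rpois(1, scenario$asv_mutations))
  }, character(1))
  names(asv_seqs) <- asv_ids

  affected <- lapply(scenario$planted_effects, function(ef) {
    hit <- if (ef$target_type == "phenotype") {
      unclass(reference$bpm)[source_genome, ef$target] == 1
    } else {
      reference$lineage[source_genome, "genus"] == ef$target
    }
    asv_ids[hit]
  })

  base_log <- stats::rnorm(n_asv, 0, scenario$sigma_base)
  statuses <- rep(names(scenario$group_sizes), scenario$group_sizes)
  datasets <- lapply(seq_len(scenario$n_datasets), function(d) {
    batch <- stats::rnorm(n_asv, 0, scenario$sigma_batch)
    ids <- sprintf("D%d_S%03d", d, seq_along(statuses))
    labels <- stats::setNames(statuses, ids)
    a <- t(vapply(seq_along(ids), function(s) {
      raw <- exp(base_log + batch + stats::rnorm(n_asv, 0, scenario$sigma_noise))
      for (k in seq_along(scenario$planted_effects)) {
        ef <- scenario$planted_effects[[k]]
        if (labels[[s]] == ef$status) {
          mult <- exp(if (ef$direction == "enrich") ef$lfc else -ef$lfc)
          raw[asv_ids %in% affected[[k]]] <-
            raw[asv_ids %in% affected[[k]]] * mult
        }
      }
      raw / sum(raw)
    }, numeric(n_asv)))
    dimnames(a) <- list(ids, asv_ids)
    reads <- stats::setNames(stats::rnbinom(length(ids), mu = scenario$read_depth,
                                            size = 20), ids)
    asv_dataset(a, asv_seqs, labels, reads, dataset_id = paste0("D", d))
  })
  names(datasets) <- vapply(datasets, `[[`, character(1), "dataset_id")
  list(datasets = datasets, asv_seqs = asv_seqs,
       truth = list(source_genome = source_genome, affected = affected,
                    effects = scenario$planted_effects))
}

mutate_sequence <- function(seq, k) {
  if (k == 0) return(seq)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), min(k, length(chars)))
  chars[pos] <- vapply(chars[pos], function(b)
    sample(setdiff(bases, b), 1), character(1))
  paste(chars, collapse = "")
}

#' Generate an alignment hit table for synthetic data
#'
#' Computes all-vs-all identity fractions between equal-length ASV and
#' reference 16S sequences (exact Hamming identities; the synthetic model
#' has no indels) and returns hits above a reporting floor. Because each ASV
#' is a lightly mutated copy of its source genome's sequence, its best hit
#' is that genome whenever the mutation distance is smallest.
#'
#' @param asv_seqs named character vector of ASV sequences.
#' @param reference_seqs named character vector of reference 16S sequences.
#' @param min_report identities below this are omitted from the table
#'   (default 0.7, well under the 0.85 drop threshold).
#' @return data.frame with columns `query_id`, `subject_id`, `identity`.
#' @export
generate_hits <- function(asv_seqs, reference_seqs, min_report = 0.7) {
  m <- identity_matrix(asv_seqs, reference_seqs)
  idx <- which(m >= min_report, arr.ind = TRUE)
  data.frame(query_id = rownames(m)[idx[, 1]],
             subject_id = colnames(m)[idx[, 2]],
             identity = m[idx],
             stringsAsFactors = FALSE)
}

#' Write a synthetic scenario to pipeline input files
#'
#' Materializes a generated reference collection and cohort set in exactly
#' the formats the pipeline consumes: reference FASTA/lineage/BPM TSVs, one
#' abundance TSV, rep-seq FASTA and label row per cohort, a hit table, the
#' true tree in Newick, and a ground-truth JSON describing the planted
#' effects.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_synthetic_study <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- generate_reference(scenario)
  gen <- generate_datasets(scenario, ref)
  write_reference_collection(ref, file.path(dir, "reference"))
  ape::write.tree(ref$tree, file.path(dir, "reference", "true_tree.nwk"))
  labels <- do.call(rbind, lapply(gen$datasets, function(ds)
    data.frame(sample_id = names(ds$labels), dataset_id = ds$dataset_id,
               status = unname(ds$labels),
               read_count = unname(ds$read_counts))))
  utils::write.table(labels, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (ds in gen$datasets)
    write_matrix_tsv(ds$abundance,
                     file.path(dir, paste0(ds$dataset_id, "_abundance.tsv")))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(gen$asv_seqs),
                              file.path(dir, "asv_seqs.fasta"))
  hits <- generate_hits(gen$asv_seqs, ref$seqs)
  utils::write.table(hits, file.path(dir, "hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(
    effects = lapply(seq_along(scenario$planted_effects), function(k)
      c(unclass(scenario$planted_effects[[k]]),
        list(affected_asvs = gen$truth$affected[[k]]))),
    source_genome = as.list(gen$truth$source_genome))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE)
  }
  invisible(dir)
}
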