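#' ASV dataset container
#'
#' Bundles one cohort's ASV relative-abundance matrix with its representative
#' sequences, per-sample read counts and clinical labels.
#'
#' @param abundance samples x ASVs matrix of relative abundances; every row
#'   must sum to 1 (tolerance 1e-9).
#' @param rep_seqs named character vector of representative sequences covering
#'   every abundance column.
#' @param labels named character vector, sample id -> clinical status
#'   (`"HC"`, `"CD"` or `"UC"`).
#' @param read_counts named non-negative numeric vector of per-sample total
#'   reads.
#' @param dataset_id cohort label.
#' @return a list of class `"asv_dataset"`.
#' @export
asv_dataset <- function(abundance, rep_seqs, labels, read_counts,
                        dataset_id = "dataset") {
  abundance <- as.matrix(abundance)
  stopifnot(!is.null(rownames(abundance)), !is.null(colnames(abundance)))
  sums <- rowSums(abundance)
  if (any(abs(sums - 1) > 1e-9))
    stop("per-sample abundances must sum to 1; offending samples: ",
         paste(utils::head(rownames(abundance)[abs(sums - 1) > 1e-9]),
               collapse = ", "))
  miss_seq <- setdiff(colnames(abundance), names(rep_seqs))
  if (length(miss_seq))
    stop("ASVs without representative sequence: ",
         paste(utils::head(miss_seq), collapse = ", "))
  samples <- rownames(abundance)
  if (!all(samples %in% names(labels)))
    stop("samples without clinical label")
  if (!all(samples %in% names(read_counts)))
    stop("samples without read count")
  if (any(read_counts[samples] < 0)) stop("negative read counts")
  bad <- setdiff(unique(labels[samples]), c("HC", "CD", "UC"))
  if (length(bad)) stop("unknown clinical status: ", paste(bad, collapse = ", "))
  structure(list(dataset_id = dataset_id,
                 abundance = abundance,
                 rep_seqs = rep_seqs[colnames(abundance)],
                 labels = labels[samples],
                 read_counts = read_counts[samples]),
            class = "asv_dataset")
}

#' @export
print.asv_dataset <- function(x, ...) {
  cat(sprintf("ASV dataset '%s': %d samples x %d ASVs\n", x$dataset_id,
              nrow(x$abundance), ncol(x$abundance)))
  print(table(x$labels))
  invisible(x)
}

#' Filter rare ASVs from a dataset
#'
#' Retains ASVs satisfying at least one of three prevalence/abundance
#' criteria: present (abundance > 0) in more than `presence_frac` of samples;
#' dataset-average abundance above `mean_abund`; or maximum abundance above
#' `max_abund`. Per-sample abundances are renormalized to sum 1 afterwards,
#' so downstream indices keep their fraction-of-cells interpretation.
#'
#' @param dataset an [asv_dataset()].
#' @param presence_frac prevalence threshold as a fraction of samples
#'   (default 0.005, i.e. >0.5% of samples).
#' @param mean_abund dataset-mean abundance threshold (default 0.0025).
#' @param max_abund maximum-abundance threshold (default 0.005).
#' @return the filtered, renormalized [asv_dataset()].
#' @export
filter_asv_table <- function(dataset, presence_frac = 0.005,
                             mean_abund = 0.0025, max_abund = 0.005) {
  a <- dataset$abundance
  prevalence <- colMeans(a > 0)
  keep <- prevalence > presence_frac |
    colMeans(a) > mean_abund |
    apply(a, 2, max) > max_abund
  if (!any(keep))
    stop("ASV filtering removed every ASV; dataset '", dataset$dataset_id,
         "' is degenerate")
  a <- a[, keep, drop = FALSE]
  a <- a / rowSums(a)
  asv_dataset(a, dataset$rep_seqs[colnames(a)], dataset$labels,
              dataset$read_counts, dataset$dataset_id)
}

#' Drop samples below a coverage threshold
#'
#' Keeps samples whose total read count strictly exceeds `min_reads`.
#'
#' @param dataset an [asv_dataset()].
#' @param min_reads coverage threshold; samples with `read_counts <= min_reads`
#'   are dropped.
#' @return the filtered [asv_dataset()].
#' @export
filter_by_coverage <- function(dataset, min_reads) {
  keep <- dataset$read_counts > min_reads
  if (!any(keep))
    stop("coverage filtering removed every sample in dataset '",
         dataset$dataset_id, "'")
  a <- dataset$abundance[keep, , drop = FALSE]
  asv_dataset(a, dataset$rep_seqs, dataset$labels[rownames(a)],
              dataset$read_counts[rownames(a)], dataset$dataset_id)
}

#' Per-ASV phenotype carriage probabilities
#'
#' For each mapped ASV and each phenotype, computes the probability that a
#' cell of that ASV carries the phenotype as the mapping-weighted average of
#' the 0/1 phenotype calls of its reference genomes:
#' `p_i = sum_g w_g * BPM[g, phenotype]`.
#'
#' @param mappings named list of genome weight vectors (from
#'   [map_all_asvs()]).
#' @param bpm a [bpm()] matrix.
#' @return mapped-ASVs x phenotypes matrix of probabilities in `[0, 1]`.
#' @export
phenotype_probability <- function(mappings, bpm) {
  if (length(mappings) == 0L)
    return(matrix(numeric(0), 0, ncol(bpm),
                  dimnames = list(NULL, colnames(bpm))))
  genomes <- unique(unlist(lapply(mappings, names)))
  missing <- setdiff(genomes, rownames(bpm))
  if (length(missing))
    stop("mapped genomes absent from BPM: ", paste(missing, collapse = ", "))
  w <- matrix(0, length(mappings), length(genomes),
              dimnames = list(names(mappings), genomes))
  for (i in seq_along(mappings))
    w[i, names(mappings[[i]])] <- mappings[[i]]
  w %*% unclass(bpm)[genomes, , drop = FALSE]
}

#' Community phenotype index
#'
#' Computes the CPI matrix: for each sample and phenotype, the expected
#' fraction of community cells carrying the phenotype,
#' `CPI = sum_i p_i * A_i`, summing over mapped ASVs (`A_i` the ASV's
#' relative abundance). Unmapped ASVs contribute 0 but keep their share of
#' the abundance denominator, so unknown cells dilute the index.
#'
#' @param dataset an [asv_dataset()] or a samples x ASVs abundance matrix.
#' @param p_matrix ASVs x phenotypes probability matrix (from
#'   [phenotype_probability()]).
#' @return samples x phenotypes CPI matrix with values in `[0, 1]`.
#' @export
compute_cpi <- function(dataset, p_matrix) {
  a <- if (inherits(dataset, "asv_dataset")) dataset$abundance else dataset
  mapped <- intersect(colnames(a), rownames(p_matrix))
  a[, mapped, drop = FALSE] %*% p_matrix[mapped, , drop = FALSE]
}

#' Build a phylogeny from representative sequences
#'
#' Small-scale built-in tree construction: equal-length (pre-aligned)
#' sequences are converted to Jukes-Cantor distances and a neighbor-joining
#' tree, which is then midpoint-rooted. For real data built with external
#' alignment/tree tools, import the Newick tree with [ape::read.tree()] and
#' root it with [midpoint_root()] instead.
#'
#' @param rep_seqs named character vector of two or more equal-length
#'   sequences.
#' @return a rooted `phylo` tree whose tips are the sequence names.
#' @export
build_tree <- function(rep_seqs) {
  if (length(rep_seqs) < 2L) stop("tree construction requires >= 2 sequences")
  if (length(unique(nchar(rep_seqs))) != 1L)
    stop("built-in tree construction expects equal-length (aligned) ",
         "sequences; align externally and import the Newick tree instead")
  m <- do.call(rbind, strsplit(tolower(rep_seqs), ""))
  rownames(m) <- names(rep_seqs)
  d <- ape::dist.dna(ape::as.DNAbin(m), model = "JC69",
                     pairwise.deletion = TRUE)
  d[!is.finite(d)] <- max(d[is.finite(d)], 1) * 2
  tr <- if (length(rep_seqs) == 2L) {
    structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
                   edge.length = rep(as.numeric(d[1]) / 2, 2),
                   tip.label = names(rep_seqs), Nnode = 1L),
              class = "phylo")
  } else {
    ape::nj(d)
  }
  midpoint_root(tr)
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest tip-to-tip path. Negative
#' neighbor-joining branch lengths are clamped to zero first.
#'
#' @param tree a `phylo` tree (rooted or unrooted).
#' @return a rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  tree$edge.length[tree$edge.length < 0] <- 0
  phangorn::midpoint(tree)
}

#' Faith's phylogenetic diversity of a tip set
#'
#' Total branch length of the minimal subtree connecting the given tips and
#' the root of the tree (the root-inclusive form of Faith's PD). The empty
#' tip set has PD 0; a single tip yields its root-to-tip path length.
#'
#' @param tree a rooted `phylo` tree.
#' @param tips character vector of tip labels (subset of `tree$tip.label`).
#' @return non-negative numeric PD value.
#' @export
faith_pd <- function(tree, tips) {
  if (length(tips) == 0L) return(0)
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stop("tips absent from tree: ", paste(unknown, collapse = ", "))
  if (!ape::is.rooted(tree)) stop("faith_pd() requires a rooted tree")
  inc <- edge_tip_incidence(tree)
  idx <- match(tips, tree$tip.label)
  hit <- Matrix::rowSums(inc[, idx, drop = FALSE]) > 0
  sum(tree$edge.length[hit])
}

# Sparse edges x tips incidence: inc[e, t] = 1 iff tip t descends from edge e.
# Cached on the tree via an attribute-free environment keyed by object identity
# is fragile in R, so callers that need it repeatedly should precompute it.
edge_tip_incidence <- function(tree) {
  ntip <- length(tree$tip.label)
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  root <- ntip + 1L
  # parent edge index of each node (0 for root)
  parent_edge <- integer(max(tree$edge))
  parent_edge[child] <- seq_along(child)
  i <- integer(0); j <- integer(0)
  for (t in seq_len(ntip)) {
    node <- t
    while (node != root) {
      e <- parent_edge[node]
      i <- c(i, e)
      j <- c(j, t)
      node <- parent[e]
    }
  }
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(nrow(tree$edge), ntip))
}

#' Phenotype alpha diversity
#'
#' For each sample and phenotype, computes Faith's phylogenetic diversity of
#' the carrier sub-community: the ASVs present in the sample (abundance > 0)
#' whose carriage probability strictly exceeds `carrier_threshold`. Samples
#' without any carrier have PAD 0. High PAD indicates that a phenotype's CPI
#' is contributed by a phylogenetically broad set of organisms.
#'
#' @param dataset an [asv_dataset()] or samples x ASVs abundance matrix.
#' @param p_matrix ASVs x phenotypes probability matrix.
#' @param tree rooted `phylo` tree containing every mapped ASV as a tip.
#' @param carrier_threshold carriage probability cutoff (default 0.6, strict).
#' @return samples x phenotypes PAD matrix.
#' @export
compute_pad <- function(dataset, p_matrix, tree, carrier_threshold = 0.6) {
  a <- if (inherits(dataset, "asv_dataset")) dataset$abundance else dataset
  mapped <- intersect(colnames(a), rownames(p_matrix))
  unknown <- setdiff(mapped, tree$tip.label)
  if (length(unknown))
    stop("mapped ASVs absent from tree: ",
         paste(utils::head(unknown), collapse = ", "))
  inc <- edge_tip_incidence(tree)
  elen <- tree$edge.length
  out <- matrix(0, nrow(a), ncol(p_matrix),
                dimnames = list(rownames(a), colnames(p_matrix)))
  present <- a[, mapped, drop = FALSE] > 0
  tip_idx <- match(mapped, tree$tip.label)
  for (k in seq_len(ncol(p_matrix))) {
    carrier <- p_matrix[mapped, k] > carrier_threshold
    if (!any(carrier)) next
    sub <- Matrix::t(inc[, tip_idx[carrier], drop = FALSE])
    # samples x edges: does any present carrier descend from the edge?
    hit <- ((present[, carrier, drop = FALSE] * 1) %*% sub) > 0
    out[, k] <- as.numeric(hit %*% elen)
  }
  out
}

#' Build CPI and PAD profiles for one dataset
#'
#' Convenience wrapper running [phenotype_probability()], [compute_cpi()] and
#' [compute_pad()] for one cohort.
#'
#' @param dataset an [asv_dataset()] (already filtered).
#' @param mappings ASV -> genome weights (from [map_all_asvs()]).
#' @param bpm a [bpm()] matrix.
#' @param tree rooted tree over the dataset's ASVs; `NULL` skips PAD.
#' @param carrier_threshold passed to [compute_pad()].
#' @return list with elements `cpi`, `pad` (or `NULL`) and `p_matrix`.
#' @export
build_profiles <- function(dataset, mappings, bpm, tree = NULL,
                           carrier_threshold = 0.6) {
  p <- phenotype_probability(mappings, bpm)
  cpi <- compute_cpi(dataset, p)
  pad <- if (is.null(tree)) NULL else
    compute_pad(dataset, p, tree, carrier_threshold)
  list(cpi = cpi, pad = pad, p_matrix = p)
}
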