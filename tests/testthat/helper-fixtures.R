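# Shared fixtures and independent oracles.

# Brute-force interval filter: the top-hit selection rule applied literally,
# hit by hit.
brute_select <- function(hits, scale, drop_threshold) {
  m <- max(hits$identity)
  if (m <= drop_threshold) return(hits[0, , drop = FALSE])
  keep <- logical(nrow(hits))
  for (r in seq_len(nrow(hits))) {
    f <- hits$identity[r]
    keep[r] <- (f >= m - (1 - m) / scale) && (f <= m) && (f > drop_threshold)
  }
  hits[keep, , drop = FALSE]
}

# Brute-force Faith's PD: union of the edges on each tip's root path, found
# independently via ape::nodepath.
brute_pd <- function(tree, tips) {
  if (length(tips) == 0) return(0)
  root <- length(tree$tip.label) + 1L
  edges <- unique(do.call(rbind, lapply(tips, function(tp) {
    path <- ape::nodepath(tree, from = root, to = match(tp, tree$tip.label))
    cbind(path[-length(path)], path[-1])
  })))
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  sum(tree$edge.length[key %in% paste(edges[, 1], edges[, 2])])
}

make_hits <- function(identities, query = "q1") {
  data.frame(query_id = rep(query, length(identities)),
             subject_id = sprintf("s%d", seq_along(identities)),
             identity = identities, stringsAsFactors = FALSE)
}

# Small lineage lookup keyed by subject id.
toy_lineage <- function(ids, genus, species,
                        family = rep("Bacteroidaceae", length(ids))) {
  data.frame(domain = "Bacteria", phylum = "Bacteroidota",
             family = family, genus = genus, species = species,
             row.names = ids)
}

# Tiny ASV dataset with n_filler absorbing the abundance remainder.
toy_dataset <- function(abundance, labels = NULL, reads = NULL,
                        id = "toy") {
  if (is.null(labels))
    labels <- stats::setNames(rep("HC", nrow(abundance)), rownames(abundance))
  if (is.null(reads))
    reads <- stats::setNames(rep(20000, nrow(abundance)), rownames(abundance))
  seqs <- stats::setNames(strrep("ACGT", 10)[rep(1, ncol(abundance))],
                          colnames(abundance))
  asv_dataset(abundance, seqs, labels, reads, id)
}

# Labels vector fixtures from per-status group sizes.
labels_from_counts <- function(counts, prefix) {
  stats::setNames(rep(names(counts), counts),
                  sprintf("%s_%04d", prefix, seq_len(sum(counts))))
}
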