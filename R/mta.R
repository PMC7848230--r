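#' Top-hit selection for multi-taxonomic assignment
#'
#' Given all alignment hits of one ASV query, keeps hits whose identity
#' fraction `F` lies in the closed interval `[M - (1 - M)/S, M]`, where `M` is
#' the best hit's identity, and strictly exceeds the drop threshold `D`. The
#' scale parameter `S` narrows the accepted identity interval as the best hit
#' approaches 1 (at `M = 1` only perfect hits pass). A query whose best hit
#' does not exceed `D` is unassigned and yields an empty selection.
#'
#' @param hits data.frame with columns `query_id`, `subject_id`, `identity`
#'   (identity as a fraction of 1), all rows sharing one `query_id`.
#' @param scale interval scale `S` (default 4).
#' @param drop_threshold identity drop threshold `D` in `[0, 1]` (default 0.85).
#' @return the selected rows of `hits` (possibly zero rows).
#' @export
select_top_hits <- function(hits, scale = 4, drop_threshold = 0.85) {
  stopifnot(is.data.frame(hits),
            all(c("query_id", "subject_id", "identity") %in% colnames(hits)),
            scale > 0, drop_threshold >= 0, drop_threshold <= 1)
  if (nrow(hits) == 0L) return(hits)
  if (length(unique(hits$query_id)) > 1L)
    stop("select_top_hits() expects hits of a single query; got: ",
         paste(unique(hits$query_id), collapse = ", "))
  f <- hits$identity
  if (any(f < 0 | f > 1)) stop("identity values must lie in [0, 1]")
  m <- max(f)
  if (m <= drop_threshold) return(hits[0, , drop = FALSE])
  lower <- m - (1 - m) / scale
  hits[f >= lower & f > drop_threshold, , drop = FALSE]
}

#' Read an alignment hit table
#'
#' Reads a TSV of alignment hits. The native layout has columns `query_id`,
#' `subject_id`, `identity` (fraction of 1); `outfmt6 = TRUE` accepts the
#' first three columns of a blast-style tabular file (`qseqid`, `sseqid`,
#' `pident`) with percent identities.
#'
#' @param path file path.
#' @param percent divide identities by 100 on load (implied by `outfmt6`).
#' @param outfmt6 the file is headerless aligner output.
#' @return data.frame with columns `query_id`, `subject_id`, `identity`.
#' @export
read_hits <- function(path, percent = FALSE, outfmt6 = FALSE) {
  if (outfmt6) {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    df <- df[, 1:3]
    colnames(df) <- c("query_id", "subject_id", "identity")
    percent <- TRUE
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("query_id", "subject_id", "identity") %in% colnames(df)))
  }
  df$identity <- as.numeric(df$identity)
  if (percent) df$identity <- df$identity / 100
  df
}

#' Build a multi-taxonomic assignment from selected hits
#'
#' Resolves each selected hit's subject to a taxonomic lineage and collapses
#' them into a single multi-taxonomic assignment (MTA): at each rank, the
#' unique non-empty names across hits, sorted lexicographically and joined by
#' `/`. Deeper ranks are retained even when ambiguous, so two species of one
#' genus yield e.g. genus `"Bacteroides"` and species `"ovatus/vulgatus"`.
#' All lineages in the assignment carry equal weight.
#'
#' @param selected_hits nonempty data.frame of hits (from
#'   [select_top_hits()]).
#' @param lineage_lookup data.frame with subject ids as rownames and one
#'   column per rank (domain first); empty strings mark missing ranks.
#' @return list of class `"mta"`: `lineages` (unique lineage matrix, one row
#'   per distinct lineage, equal weights), `string_form` (named character
#'   vector, one slash-joined string per rank).
#' @export
build_mta <- function(selected_hits, lineage_lookup) {
  if (nrow(selected_hits) == 0L) stop("build_mta() requires at least one hit")
  unresolved <- setdiff(selected_hits$subject_id, rownames(lineage_lookup))
  if (length(unresolved))
    stop("subjects without lineage: ", paste(unresolved, collapse = ", "))
  lin <- as.matrix(lineage_lookup[selected_hits$subject_id, , drop = FALSE])
  lin[is.na(lin)] <- ""
  lin <- unique(lin)
  string_form <- apply(lin, 2, function(v) {
    paste(sort(unique(v[nzchar(v)])), collapse = "/")
  })
  structure(list(lineages = lin, string_form = string_form), class = "mta")
}

#' Assign MTAs to every query in a hit table
#'
#' Applies [select_top_hits()] and [build_mta()] per query. Queries whose best
#' hit does not pass the drop threshold are unassigned and absent from the
#' result.
#'
#' @param hits full hit table (many queries).
#' @param lineage_lookup as in [build_mta()].
#' @inheritParams select_top_hits
#' @return named list of `"mta"` objects, one per assigned query.
#' @export
assign_mta <- function(hits, lineage_lookup, scale = 4, drop_threshold = 0.85) {
  out <- lapply(split(hits, hits$query_id), function(h) {
    sel <- select_top_hits(h, scale, drop_threshold)
    if (nrow(sel) == 0L) NULL else build_mta(sel, lineage_lookup)
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Map an ASV to reference genomes
#'
#' Applies the same interval top-hit selection as the MTA procedure to hits
#' against reference 16S sequences and assigns equal weights across the
#' *distinct* genomes among the selected hits (multiple 16S copies of one
#' genome count once, so copy number does not bias the mapping).
#'
#' @param hits hits of one query against reference 16S sequences.
#' @param genome_of named character vector resolving subject ids to genome ids.
#' @inheritParams select_top_hits
#' @return named numeric vector of equal genome weights summing to 1, or
#'   `NULL` when no hit passes selection (ASV unassigned).
#' @export
map_asv_to_genomes <- function(hits, genome_of, scale = 4,
                               drop_threshold = 0.85) {
  sel <- select_top_hits(hits, scale, drop_threshold)
  if (nrow(sel) == 0L) return(NULL)
  unresolved <- setdiff(sel$subject_id, names(genome_of))
  if (length(unresolved))
    stop("subjects without genome id: ", paste(unresolved, collapse = ", "))
  genomes <- unique(unname(genome_of[sel$subject_id]))
  stats::setNames(rep(1 / length(genomes), length(genomes)), genomes)
}

#' Map every ASV in a hit table to reference genomes
#'
#' @param hits full hit table (many queries).
#' @inheritParams map_asv_to_genomes
#' @return named list of genome weight vectors, one per mapped query;
#'   unassigned queries are absent.
#' @export
map_all_asvs <- function(hits, genome_of, scale = 4, drop_threshold = 0.85) {
  out <- lapply(split(hits, hits$query_id), map_asv_to_genomes,
                genome_of = genome_of, scale = scale,
                drop_threshold = drop_threshold)
  out[!vapply(out, is.null, logical(1))]
}

#' Global-alignment identity between two sequences
#'
#' Deterministic identity fraction of a Needleman-Wunsch global alignment
#' (match +1, mismatch -1, gap opening 2, gap extension 1), defined as the
#' number of matching columns divided by the total number of alignment
#' columns. Intended as a small-scale stand-in for an external aligner's
#' percent identity.
#'
#' @param query_seq,subject_seq nucleotide strings.
#' @return identity fraction in `[0, 1]`.
#' @export
naive_identity <- function(query_seq, subject_seq) {
  stopifnot(nzchar(query_seq), nzchar(subject_seq))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query_seq), Biostrings::DNAString(subject_seq),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 2, gapExtension = 1)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

# Fast all-vs-all identity for equal-length sequence sets via one-hot
# cross-products (no indels assumed). Rows queries, columns subjects.
identity_matrix <- function(query_seqs, subject_seqs) {
  lens <- unique(c(nchar(query_seqs), nchar(subject_seqs)))
  if (length(lens) != 1L)
    stop("identity_matrix() requires equal-length sequences")
  onehot <- function(seqs) {
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    out <- matrix(0L, nrow(m), ncol(m) * 4L)
    for (k in seq_along(c("A", "C", "G", "T"))) {
      base <- c("A", "C", "G", "T")[k]
      out[, (seq_len(ncol(m)) - 1L) * 4L + k] <- (m == base) + 0L
    }
    rownames(out) <- names(seqs)
    out
  }
  q <- onehot(query_seqs)
  s <- onehot(subject_seqs)
  tcrossprod(q, s) / lens
}

#' Aggregate ASV abundances onto genus-level MTA features
#'
#' Sums ASV relative abundances per distinct genus-rank MTA string. Slash-
#' joined multi-genus strings are features in their own right: `"A"` and
#' `"A/B"` are different features. ASVs without an assignment (or with an
#' empty genus string) are excluded from the feature table with a message;
#' their abundance is not redistributed.
#'
#' @param asv_table samples x ASVs abundance matrix.
#' @param mta_per_asv named list of `"mta"` objects (from [assign_mta()]).
#' @param rank rank whose MTA string names the features (default `"genus"`).
#' @return samples x features abundance matrix.
#' @export
aggregate_genus_features <- function(asv_table, mta_per_asv, rank = "genus") {
  if (ncol(asv_table) == 0L) return(asv_table)
  feat <- vapply(mta_per_asv, function(m) {
    if (!rank %in% names(m$string_form))
      stop("rank '", rank, "' absent from MTA string form")
    m$string_form[[rank]]
  }, character(1))
  feat <- feat[nzchar(feat)]
  dropped <- setdiff(colnames(asv_table), names(feat))
  if (length(dropped))
    message(length(dropped), " ASV(s) without a ", rank,
            "-level assignment excluded from feature table")
  keep <- intersect(colnames(asv_table), names(feat))
  sub <- asv_table[, keep, drop = FALSE]
  groups <- factor(feat[keep])
  out <- sapply(levels(groups), function(g) {
    rowSums(sub[, groups == g, drop = FALSE])
  })
  if (is.null(dim(out)))
    out <- matrix(out, nrow = nrow(asv_table), ncol = length(levels(groups)),
                  dimnames = list(rownames(asv_table), levels(groups)))
  out
}
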