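#' Binary phenotype matrix
#'
#' Constructs a validated genomes x phenotypes matrix of 0/1 pathway calls.
#' Each row is a reference genome, each column a binary metabolic phenotype
#' (e.g. butyrate production, a vitamin biosynthesis pathway, a glycosyl
#' hydrolase family). An optional category annotation assigns each phenotype
#' to one of the standard groups (vitamin synthesis, amino-acid synthesis,
#' amino-acid degradation, sugar utilization, SCFA production, GH family).
#'
#' @param x numeric matrix with genome ids as rownames and phenotype ids as
#'   colnames; all entries must be 0 or 1.
#' @param category optional named character vector mapping phenotype ids to
#'   category labels.
#' @return an integer matrix of class `"bpm"` with a `"category"` attribute.
#' @export
bpm <- function(x, category = NULL) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || (ncol(x) > 0 && is.null(colnames(x))))
    stop("BPM requires genome ids as rownames and phenotype ids as colnames")
  if (is.null(colnames(x))) colnames(x) <- character(0)
  if (anyDuplicated(rownames(x)))
    stop("duplicate genome ids in BPM: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate phenotype ids in BPM: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  bad <- which(!(x %in% c(0, 1)))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(x))
    stop(sprintf("non-binary BPM cell [genome %s, phenotype %s]: %s",
                 rownames(x)[ij[1]], colnames(x)[ij[2]], x[bad[1]]))
  }
  storage.mode(x) <- "integer"
  if (!is.null(category)) {
    missing_cat <- setdiff(colnames(x), names(category))
    if (length(missing_cat))
      stop("phenotypes without category annotation: ",
           paste(missing_cat, collapse = ", "))
    attr(x, "category") <- category[colnames(x)]
  }
  class(x) <- c("bpm", class(x))
  x
}

#' @export
print.bpm <- function(x, ...) {
  cat(sprintf("Binary phenotype matrix: %d genomes x %d phenotypes\n",
              nrow(x), ncol(x)))
  cat <- attr(x, "category")
  if (!is.null(cat)) {
    tab <- table(cat)
    cat_line <- paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")
    base::cat("categories:", cat_line, "\n")
  }
  invisible(x)
}

#' Load a reference genome collection
#'
#' Reads the three files that define the reference knowledge base: a FASTA of
#' 16S rRNA gene sequences (one or more copies per genome), a lineage table
#' and a binary phenotype matrix. Sequence headers use `<genome_id>|<copy>`
#' ids (a header without `|` is taken as the genome id itself); everything
#' after the first whitespace is ignored. The lineage table is a TSV with a
#' `genome_id` column followed by one column per taxonomic rank, ordered from
#' domain to species; empty cells mark missing ranks. The BPM table is a TSV
#' with `genome_id` rows and one 0/1 column per phenotype; an optional sidecar
#' TSV (`phenotype_id`, `category`) carries category annotations.
#'
#' All validation failures (non-binary cells, BPM rows without a genome,
#' sequences with characters outside `A/C/G/T/N`) are collected and reported
#' together with their coordinates.
#'
#' @param genomes_fasta path to the 16S FASTA.
#' @param lineage_table path to the lineage TSV.
#' @param bpm_table path to the BPM TSV.
#' @param category_table optional path to the phenotype category sidecar TSV.
#' @return a list of class `"reference_collection"` with elements `seqs`
#'   (named character vector of sequences), `genome_of` (sequence id ->
#'   genome id), `lineage` (data.frame, rownames genome ids, one column per
#'   rank) and `bpm` (a [bpm()] matrix).
#' @export
load_reference_collection <- function(genomes_fasta, lineage_table, bpm_table,
                                      category_table = NULL) {
  for (f in c(genomes_fasta, lineage_table, bpm_table, category_table))
    if (!file.exists(f)) stop("file not found: ", f)
  ss <- Biostrings::readDNAStringSet(genomes_fasta)
  seq_ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  names(seqs) <- seq_ids
  genome_of <- sub("\\|.*$", "", seq_ids)
  names(genome_of) <- seq_ids

  lin <- utils::read.delim(lineage_table, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  if (!"genome_id" %in% colnames(lin))
    stop("lineage table must contain a 'genome_id' column")
  rownames(lin) <- lin$genome_id
  lin$genome_id <- NULL

  bpm_raw <- utils::read.delim(bpm_table, row.names = 1, check.names = FALSE)
  category <- NULL
  if (!is.null(category_table)) {
    ct <- utils::read.delim(category_table, stringsAsFactors = FALSE)
    category <- stats::setNames(ct$category, ct$phenotype_id)
  }

  errors <- character()
  if (anyDuplicated(seq_ids))
    errors <- c(errors, paste("duplicate sequence ids:",
                              paste(unique(seq_ids[duplicated(seq_ids)]), collapse = ", ")))
  bad_seq <- grepl("[^ACGTN]", seqs) | !nzchar(seqs)
  if (any(bad_seq))
    errors <- c(errors, paste("invalid sequences (empty or non-ACGTN):",
                              paste(seq_ids[bad_seq], collapse = ", ")))
  genome_ids <- unique(genome_of)
  no_lineage <- setdiff(genome_ids, rownames(lin))
  if (length(no_lineage))
    errors <- c(errors, paste("genomes without lineage:",
                              paste(no_lineage, collapse = ", ")))
  orphan <- setdiff(rownames(bpm_raw), genome_ids)
  if (length(orphan))
    errors <- c(errors, paste("BPM rows without a reference genome:",
                              paste(orphan, collapse = ", ")))
  m <- as.matrix(bpm_raw)
  nb <- which(!(m %in% c(0, 1)))
  for (idx in nb) {
    ij <- arrayInd(idx, dim(m))
    errors <- c(errors, sprintf("non-binary BPM cell [genome %s, phenotype %s]: %s",
                                rownames(m)[ij[1]], colnames(m)[ij[2]], m[idx]))
  }
  if (length(errors))
    stop("reference collection validation failed:\n  ",
         paste(errors, collapse = "\n  "))

  structure(list(seqs = seqs, genome_of = genome_of, lineage = lin,
                 bpm = bpm(m, category)),
            class = "reference_collection")
}

#' @export
print.reference_collection <- function(x, ...) {
  cat(sprintf("Reference collection: %d genomes, %d 16S sequences, %d ranks\n",
              length(unique(x$genome_of)), length(x$seqs), ncol(x$lineage)))
  print(x$bpm)
  invisible(x)
}

#' Write a reference collection to disk
#'
#' Inverse of [load_reference_collection()]; writes the FASTA, lineage TSV,
#' BPM TSV and (when categories are present) the category sidecar TSV.
#'
#' @param ref a `reference_collection`.
#' @param dir output directory, created if needed.
#' @return invisibly, the named vector of file paths written.
#' @export
write_reference_collection <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genomes_fasta = file.path(dir, "reference_16S.fasta"),
             lineage_table = file.path(dir, "lineage.tsv"),
             bpm_table = file.path(dir, "bpm.tsv"),
             category_table = file.path(dir, "bpm_categories.tsv"))
  ss <- Biostrings::DNAStringSet(ref$seqs)
  Biostrings::writeXStringSet(ss, paths["genomes_fasta"])
  lin <- cbind(genome_id = rownames(ref$lineage), ref$lineage)
  utils::write.table(lin, paths["lineage_table"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(ref$bpm, paths["bpm_table"], id_col = "genome_id")
  category <- attr(ref$bpm, "category")
  if (!is.null(category)) {
    utils::write.table(data.frame(phenotype_id = names(category),
                                  category = unname(category)),
                       paths["category_table"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    paths <- paths[names(paths) != "category_table"]
  }
  invisible(paths)
}

#' Merge a metabolic BPM with a GH-family BPM
#'
#' Column-concatenates two binary phenotype matrices over the same genome set
#' (e.g. the pathway-based matrix and the glycosyl-hydrolase-family matrix),
#' preserving category annotations.
#'
#' @param metabolic,gh [bpm()] matrices with identical genome id sets and
#'   disjoint phenotype ids.
#' @return a [bpm()] matrix with `ncol(metabolic) + ncol(gh)` columns.
#' @export
merge_bpm <- function(metabolic, gh) {
  if (!setequal(rownames(metabolic), rownames(gh)))
    stop("BPMs cover different genome sets; cannot merge")
  overlap <- intersect(colnames(metabolic), colnames(gh))
  if (length(overlap))
    stop("overlapping phenotype ids: ", paste(overlap, collapse = ", "))
  gh2 <- gh[rownames(metabolic), , drop = FALSE]
  cat1 <- attr(metabolic, "category")
  cat2 <- attr(gh, "category")
  category <- NULL
  if (!is.null(cat1) || !is.null(cat2)) {
    if (is.null(cat1)) cat1 <- stats::setNames(rep(NA_character_, ncol(metabolic)),
                                               colnames(metabolic))
    if (is.null(cat2)) cat2 <- stats::setNames(rep(NA_character_, ncol(gh)),
                                               colnames(gh))
    category <- c(cat1, cat2)
  }
  bpm(cbind(unclass(metabolic), unclass(gh2)), category)
}

# Shared TSV writer for matrices with an explicit id column.
write_matrix_tsv <- function(m, path, id_col = "sample_id") {
  df <- data.frame(rownames(m), as.data.frame(unclass(m), check.names = FALSE),
                   check.names = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# Shared TSV reader: first column is the id column.
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
}
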