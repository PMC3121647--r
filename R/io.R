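# Readers and writers for the plain-text interchange formats: gene tables,
# pair tables, BLAST tabular hits and the report files. TSV dialect:
# tab-separated, header line, UTF-8, "#" comment lines.

#' Read a gene table
#'
#' Expects tab-separated columns `genome`, `gene` and optionally `rank` and
#' `strand`. Strand is parsed but ignored by all algorithms. When `rank` is
#' absent, dense ranks are assigned from row order within each genome.
#'
#' @param path Path to the TSV file.
#' @return A data.frame suitable for [layered_graph()].
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop_input("gene table '%s' does not exist", path)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(c("genome", "gene"), names(tab))
  if (length(miss) > 0L)
    stop_input("gene table '%s' misses column(s): %s", path,
               paste(miss, collapse = ", "))
  tab
}

#' Read a correspondence pair table
#'
#' The first two columns are taken as gene-id pairs; symmetric duplicates are
#' collapsed by [layered_graph()].
#'
#' @param path Path to the TSV file.
#' @return A two-column character matrix (zero rows for an empty table).
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path)) stop_input("pair table '%s' does not exist", path)
  first <- readLines(path, n = 50L)
  has_rows <- sum(!grepl("^#", first) & nzchar(first)) > 1L
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || !has_rows)
    return(cbind(gene1 = character(0), gene2 = character(0)))
  if (ncol(tab) < 2L) stop_input("pair table '%s' needs two columns", path)
  cbind(gene1 = as.character(tab[[1L]]), gene2 = as.character(tab[[2L]]))
}

#' Write a gene table / pair table
#'
#' @param graph A [layered_graph()] (or, for `write_pair_table`, a two-column
#'   matrix or data.frame of pairs).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_gene_table <- function(graph, path) {
  stopifnot(inherits(graph, "layered_graph"))
  tab <- data.frame(genome = graph$genome_names[graph$genes$genome],
                    gene = graph$genes$gene, rank = graph$genes$rank,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_table
#' @param pairs Two-column matrix or data.frame of gene-id pairs.
#' @export
write_pair_table <- function(pairs, path) {
  pm <- normalize_pairs(pairs)
  utils::write.table(as.data.frame(pm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read BLAST tabular hits plus a protein-length table
#'
#' Reads NCBI tabular output (outfmt-6-like, 12 columns, no header) and joins
#' the query/subject protein lengths from a two-column length table
#' (`gene`, `length`), since lengths are not part of the tabular hit line.
#'
#' @param path Path to the BLAST tabular file.
#' @param lengths_path Path to the TSV length table, or a data.frame.
#' @return A data.frame of hits with the columns used by
#'   [filter_blast_pairs()].
#' @export
read_blast_table <- function(path, lengths_path) {
  if (!file.exists(path)) stop_input("BLAST table '%s' does not exist", path)
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_openings", "q_start", "q_end", "s_start",
            "s_end", "p_value", "bit_score")
  hits <- utils::read.delim(path, header = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
  if (ncol(hits) < 12L)
    stop_input("BLAST table '%s' has %d columns; 12 expected", path, ncol(hits))
  names(hits)[1:12] <- cols
  len <- if (is.data.frame(lengths_path)) lengths_path else {
    if (!file.exists(lengths_path))
      stop_input("length table '%s' does not exist", lengths_path)
    utils::read.delim(lengths_path, stringsAsFactors = FALSE)
  }
  if (ncol(len) < 2L) stop_input("length table needs columns gene, length")
  lens <- setNames(as.integer(len[[2L]]), as.character(len[[1L]]))
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), names(lens))
  if (length(unknown) > 0L)
    stop_input("no protein length for gene '%s'", unknown[1L])
  hits$query_length <- unname(lens[hits$query_id])
  hits$subject_length <- unname(lens[hits$subject_id])
  hits
}

#' Filter BLAST hits into a correspondence relation
#'
#' Keeps a hit when `p_value <= max_p`, `percent_identity >= min_identity`
#' and the alignment covers at least `min_coverage` of the smaller of the two
#' proteins (`alignment_length / min(query_length, subject_length)`). The
#' defaults (`1e-10`, `40`, `0.80`) are the conventional thresholds for
#' building a similarity-based gene correspondence from all-against-all
#' BLASTP. The result is symmetrised and deduplicated; self hits are dropped.
#'
#' @param hits Data.frame with columns `query_id`, `subject_id`, `p_value`,
#'   `percent_identity`, `alignment_length`, `query_length`,
#'   `subject_length` (as produced by [read_blast_table()]).
#' @param max_p Maximum p-value (or e-value) retained.
#' @param min_identity Minimum percent identity in `[0, 100]`.
#' @param min_coverage Minimum alignment coverage of the smaller protein,
#'   in `(0, 1]`.
#' @return A two-column character matrix of unordered gene pairs.
#' @export
filter_blast_pairs <- function(hits, max_p = 1e-10, min_identity = 40,
                               min_coverage = 0.80) {
  if (!is.finite(max_p) || !is.finite(min_identity) || !is.finite(min_coverage))
    stop_input("thresholds must be finite")
  if (min_coverage <= 0 || min_coverage > 1)
    stop_input("min_coverage must be in (0, 1]")
  empty <- cbind(gene1 = character(0), gene2 = character(0))
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  need <- c("query_id", "subject_id", "p_value", "percent_identity",
            "alignment_length", "query_length", "subject_length")
  miss <- setdiff(need, names(hits))
  if (length(miss) > 0L)
    stop_input("hit table misses column(s): %s", paste(miss, collapse = ", "))
  smaller <- pmin(hits$query_length, hits$subject_length)
  keep <- hits$p_value <= max_p &
    hits$percent_identity >= min_identity &
    hits$alignment_length / smaller >= min_coverage &
    hits$query_id != hits$subject_id
  if (!any(keep)) return(empty)
  canonical_pairs(hits$query_id[keep], hits$subject_id[keep])
}

#' Derive a gene table from a GFF3 file
#'
#' Reads one genome's GFF3 annotation and orders its gene features by start
#' coordinate to assign ranks. Requires the `rtracklayer` package.
#'
#' @param path Path to a GFF3 file.
#' @param genome Genome name to place in the `genome` column.
#' @param feature_type Feature type to keep (default `"gene"`).
#' @param id_attribute Attribute holding the gene id (default `"ID"`).
#' @return A data.frame with columns `genome`, `gene`, `rank`.
#' @export
gff_gene_table <- function(path, genome, feature_type = "gene",
                           id_attribute = "ID") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop_input("gff_gene_table() requires the rtracklayer package")
  gr <- as.data.frame(rtracklayer::import(path))
  gr <- gr[as.character(gr$type) == feature_type, , drop = FALSE]
  if (nrow(gr) == 0L)
    stop_input("no '%s' features in '%s'", feature_type, path)
  ids <- as.character(gr[[id_attribute]])
  ord <- order(gr$seqnames, gr$start)
  data.frame(genome = genome, gene = ids[ord], rank = seq_along(ord),
             stringsAsFactors = FALSE)
}
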