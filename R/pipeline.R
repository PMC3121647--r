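#' Run the full detection pipeline on input files
#'
#' Parses the gene table and the correspondence input (pair table, or BLAST
#' tabular plus a protein-length table filtered with
#' [filter_blast_pairs()]), builds the layered data graph, runs the synton
#' partition (engine or, for verification, the brute-force oracle path),
#' applies the optional size and maximality filters, and writes the report
#' files into `out_dir`:
#'
#' * `syntons.tsv`, `syntons.json` — one row/record per synton with cover,
#'   spine count, per-genome gene lists and rank spans;
#' * `spines.tsv` — all member spines, one column per genome, `"*"` marking
#'   don't-care slots;
#' * `projections.bed` — BED-like per-genome spans (1-based ranks, inclusive);
#' * `pair_max_size.tsv` — per correspondence pair, the spine count of the
#'   largest synton containing both genes;
#' * `summary.json` — parameters and counts, including the per-genome number
#'   of genes involved in syntons.
#'
#' @param gene_table Path to the gene TSV (columns `genome`, `gene`,
#'   optional `rank`, `strand`).
#' @param pair_table Path to the two-column pair TSV (or `NULL` when BLAST
#'   input is used).
#' @param blast_table,length_table Paths to BLAST tabular hits and the
#'   `gene`/`length` TSV; used when `pair_table` is `NULL`.
#' @param out_dir Output directory (created if missing).
#' @param q Quorum.
#' @param delta_gap Gap radius.
#' @param mode Aggregation mode (`"clique"`, `"cc"`, `"quasi"`).
#' @param gamma Quasi-clique degree fraction.
#' @param min_size Minimum spines per synton.
#' @param maximal_only Apply the subsumption filter.
#' @param circular Character vector of genome names with circular
#'   chromosomes.
#' @param oracle Force the brute-force oracle path (explicit enumeration +
#'   definition-driven refinement) instead of the engine.
#' @param max_p,min_identity,min_coverage BLAST filter thresholds.
#' @return Invisibly, a list with the `graph`, the `partition` and the
#'   `summary` list.
#' @export
run_pipeline <- function(gene_table, pair_table = NULL, blast_table = NULL,
                         length_table = NULL, out_dir = ".",
                         q = 2L, delta_gap = 1L, mode = "clique",
                         gamma = NULL, min_size = 1L, maximal_only = FALSE,
                         circular = character(0), oracle = FALSE,
                         max_p = 1e-10, min_identity = 40,
                         min_coverage = 0.80) {
  genes <- read_gene_table(gene_table)
  pairs <- if (!is.null(pair_table)) {
    read_pair_table(pair_table)
  } else if (!is.null(blast_table)) {
    if (is.null(length_table))
      stop_input("BLAST input needs a protein length table")
    filter_blast_pairs(read_blast_table(blast_table, length_table),
                       max_p = max_p, min_identity = min_identity,
                       min_coverage = min_coverage)
  } else {
    stop_input("either pair_table or blast_table must be given")
  }
  genome_names <- unique(as.character(genes$genome))
  circ <- genome_names %in% circular
  graph <- layered_graph(genes, pairs, delta_gap = delta_gap,
                         circular = circ)
  agg <- aggregator(mode, gamma = gamma)
  part <- if (oracle) {
    p0 <- oracle_partition(build_pnam(enumerate_spines(graph, agg, q),
                                      graph), q)
    p0 <- filter_min_size(p0, min_size)
    if (maximal_only) maximal_syntons(p0) else p0
  } else {
    otfq_partition(graph, q = q, aggregator = agg, min_size = min_size,
                   maximal_only = maximal_only)
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_synton_report(part, graph, file.path(out_dir, "syntons.tsv"))
  write_synton_json(part, graph, file.path(out_dir, "syntons.json"))
  all_spines <- unlist(lapply(part, `[[`, "spines"), recursive = FALSE)
  spines_to_tsv(all_spines, graph, file.path(out_dir, "spines.tsv"))
  write_synton_bed(part, graph, file.path(out_dir, "projections.bed"))
  utils::write.table(max_synton_size_per_pair(part, graph),
                     file.path(out_dir, "pair_max_size.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  involved <- vapply(seq_len(graph$n), function(i) {
    gs <- unique(unlist(lapply(part, function(s)
      if (i %in% s$cover) unlist(lapply(s$spines, function(sp)
        slot_genes(sp[i]))) else character(0))))
    length(gs)
  }, integer(1))
  summary <- list(
    schema = "synton-run/1",
    parameters = list(q = q, delta_gap = delta_gap, mode = agg$mode,
                      gamma = agg$gamma, min_size = min_size,
                      maximal_only = maximal_only, oracle = oracle),
    n_genomes = graph$n,
    n_genes = nrow(graph$genes),
    n_pairs = nrow(graph$pairs),
    n_syntons = length(part),
    n_spines = length(all_spines),
    largest_synton = if (length(part) > 0L)
      max(vapply(part, function(s) length(s$spines), integer(1))) else 0L,
    genes_involved = as.list(setNames(involved, graph$genome_names))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(list(graph = graph, partition = part, summary = summary))
}
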