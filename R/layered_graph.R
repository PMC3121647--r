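#' Build a layered data graph from ordered genomes and a correspondence relation
#'
#' The layered data graph is the joint representation of the primary data:
#' each genome is an interval graph on gene ranks (two genes of one genome are
#' neighbours when their rank distance is at most `delta_gap`), and genes of
#' different genomes are linked by the pairwise correspondence relation `S`
#' (typically thresholded sequence similarity or orthology; many-to-many and
#' not necessarily transitive). Intra-genome adjacency is implicit via the
#' interval rule and never materialised.
#'
#' Gene ranks must be unique positive integers within a genome; they need not
#' be dense (gene tables filtered to a gene subset keep their original
#' coordinates' order but may skip ranks). When a genome is given as a plain
#' character vector of gene ids, dense ranks `1..L` are assigned from the
#' order of the vector. For circular genomes the rank distance wraps around,
#' using `L = max(rank)` positions.
#'
#' @param genomes Either a named list of character vectors (gene ids in
#'   chromosomal order), or a data.frame with columns `genome`, `gene` and
#'   optionally `rank` (and `strand`, which is parsed but ignored by all
#'   algorithms). Gene ids must be unique across all genomes.
#' @param pairs The correspondence relation: a two-column data.frame or matrix
#'   of gene-id pairs (symmetric; stored once per unordered pair), or `NULL`
#'   for the empty relation.
#' @param delta_gap Integer gap radius `>= 1`: genes `u`, `v` of one genome
#'   are neighbours iff their rank distance is `<= delta_gap`, so
#'   `delta_gap = 1` means strict adjacency (no intervening gene) and
#'   `delta_gap = g` tolerates up to `g - 1` intervening genes.
#' @param circular Logical, recycled to the number of genomes: whether each
#'   chromosome is circular.
#' @return An object of class `layered_graph` with elements `genes` (gene
#'   table), `n`, `genome_names`, `lengths` (rank span per genome),
#'   `circular`, `pairs` (canonical two-column matrix), `adj` (adjacency list
#'   of `S`) and `delta_gap`.
#' @examples
#' g <- layered_graph(
#'   genomes = list(G1 = c("a1", "b1"), G2 = c("a2", "b2"), G3 = "a3"),
#'   pairs = rbind(c("a1", "a2"), c("a1", "a3"), c("a2", "a3"), c("b1", "b2")),
#'   delta_gap = 1
#' )
#' g
#' @seealso [interval_edge()], [enumerate_spines()], [otfq_partition()]
#' @export
layered_graph <- function(genomes, pairs = NULL, delta_gap = 1L,
                          circular = FALSE) {
  if (!is.numeric(delta_gap) || length(delta_gap) != 1L || delta_gap < 1 ||
      delta_gap != round(delta_gap))
    stop_input("delta_gap must be a single integer >= 1 (got %s)",
               deparse(delta_gap))
  delta_gap <- as.integer(delta_gap)

  tab <- normalize_gene_table(genomes)
  genome_names <- levels(tab$genome_f)
  n <- length(genome_names)
  if (n < 2L) stop_input("at least 2 genomes are required (got %d)", n)
  if (anyDuplicated(tab$gene))
    stop_input("gene id '%s' occurs in more than one row; gene ids must be unique",
               tab$gene[duplicated(tab$gene)][1L])
  genome_idx <- as.integer(tab$genome_f)
  for (i in seq_len(n)) {
    rk <- tab$rank[genome_idx == i]
    if (anyDuplicated(rk))
      stop_input("duplicate rank %d within genome '%s'",
                 rk[duplicated(rk)][1L], genome_names[i])
  }
  ord <- order(genome_idx, tab$rank)
  genes <- data.frame(gene   = tab$gene[ord],
                      genome = genome_idx[ord],
                      rank   = as.integer(tab$rank[ord]),
                      stringsAsFactors = FALSE)

  circular <- rep_len(as.logical(circular), n)
  lengths <- vapply(seq_len(n),
                    function(i) max(genes$rank[genes$genome == i]), integer(1))

  genome_of <- setNames(genes$genome, genes$gene)
  rank_of <- setNames(genes$rank, genes$gene)

  pm <- normalize_pairs(pairs)
  if (nrow(pm) > 0L) {
    unknown <- setdiff(c(pm[, 1L], pm[, 2L]), genes$gene)
    if (length(unknown) > 0L)
      stop_input("correspondence pair references unknown gene id '%s'",
                 unknown[1L])
    self <- pm[, 1L] == pm[, 2L]
    if (any(self))
      stop_input("self pair for gene '%s' is not allowed", pm[self, 1L][1L])
    intra <- genome_of[pm[, 1L]] == genome_of[pm[, 2L]]
    if (any(intra))
      stop_input("intra-genome pair ('%s', '%s') is not allowed",
                 pm[intra, 1L][1L], pm[intra, 2L][1L])
  }

  adj <- make_adjacency(genes$gene, pm)

  structure(list(genes = genes, n = n, genome_names = genome_names,
                 lengths = lengths, circular = circular, pairs = pm,
                 adj = adj, genome_of = genome_of, rank_of = rank_of,
                 delta_gap = delta_gap),
            class = "layered_graph")
}

normalize_gene_table <- function(genomes) {
  if (is.data.frame(genomes)) {
    need <- c("genome", "gene")
    miss <- setdiff(need, names(genomes))
    if (length(miss) > 0L)
      stop_input("gene table misses column(s): %s", paste(miss, collapse = ", "))
    gf <- factor(as.character(genomes$genome),
                 levels = unique(as.character(genomes$genome)))
    gene <- as.character(genomes$gene)
    if ("rank" %in% names(genomes) && !all(is.na(genomes$rank))) {
      rank <- as.integer(genomes$rank)
      if (anyNA(rank) || any(rank < 1L))
        stop_input("ranks must be positive integers")
    } else {
      # dense ranks from row order within each genome
      rank <- stats::ave(seq_along(gene), gf, FUN = seq_along)
    }
    data.frame(gene = gene, genome_f = gf, rank = as.integer(rank),
               stringsAsFactors = FALSE)
  } else if (is.list(genomes)) {
    if (is.null(names(genomes)) || any(names(genomes) == ""))
      names(genomes) <- paste0("G", seq_along(genomes))
    do.call(rbind, lapply(seq_along(genomes), function(i) {
      ids <- as.character(genomes[[i]])
      if (length(ids) < 1L)
        stop_input("genome '%s' is empty", names(genomes)[i])
      data.frame(gene = ids,
                 genome_f = factor(rep(names(genomes)[i], length(ids)),
                                   levels = names(genomes)),
                 rank = seq_along(ids), stringsAsFactors = FALSE)
    }))
  } else {
    stop_input("genomes must be a named list of gene-id vectors or a data.frame")
  }
}

normalize_pairs <- function(pairs) {
  if (is.null(pairs))
    return(cbind(gene1 = character(0), gene2 = character(0)))
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  if (length(pairs) == 0L)
    return(cbind(gene1 = character(0), gene2 = character(0)))
  if (!is.matrix(pairs) || ncol(pairs) < 2L)
    stop_input("pairs must have two columns of gene ids")
  canonical_pairs(as.character(pairs[, 1L]), as.character(pairs[, 2L]))
}

make_adjacency <- function(gene_ids, pm) {
  adj <- vector("list", length(gene_ids))
  names(adj) <- gene_ids
  if (nrow(pm) > 0L) {
    ends <- c(pm[, 1L], pm[, 2L])
    other <- c(pm[, 2L], pm[, 1L])
    sp <- split(other, ends)
    adj[names(sp)] <- lapply(sp, function(x) sort(unique(x)))
  }
  adj
}

#' @export
print.layered_graph <- function(x, ...) {
  cat(sprintf("layered data graph: %d genomes, %d genes, %d correspondence pairs\n",
              x$n, nrow(x$genes), nrow(x$pairs)))
  cat(sprintf("  delta_gap = %d\n", x$delta_gap))
  for (i in seq_len(x$n))
    cat(sprintf("  %s: %d genes, rank span %d%s\n", x$genome_names[i],
                sum(x$genes$genome == i), x$lengths[i],
                if (x$circular[i]) " (circular)" else ""))
  invisible(x)
}

#' Are two genes neighbours on their chromosome?
#'
#' Implements the intra-layer interval rule: genes `u` and `v` of the same
#' genome are neighbours when their rank distance is at most `delta_gap`.
#' For circular genomes the distance wraps: `min(|dr|, L - |dr|)`. A gene is
#' its own neighbour (distance 0).
#'
#' @param graph A [layered_graph()].
#' @param u,v Gene ids on the same genome.
#' @param delta_gap Gap radius; defaults to the graph's value.
#' @return `TRUE` or `FALSE`.
#' @export
interval_edge <- function(graph, u, v, delta_gap = graph$delta_gap) {
  stopifnot(inherits(graph, "layered_graph"))
  for (g in c(u, v)) {
    if (!g %in% names(graph$genome_of))
      stop_usage("unknown gene id '%s'", g)
  }
  gi <- graph$genome_of[[u]]
  if (gi != graph$genome_of[[v]])
    stop_usage("genes '%s' and '%s' are on different genomes", u, v)
  d <- rank_distance(graph$rank_of[[u]], graph$rank_of[[v]],
                     graph$lengths[gi], graph$circular[gi])
  d <= delta_gap
}
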