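# Spines: the vertices of the (partial) network alignment multigraph. A spine
# assigns to each genome either a don't-care mark "*" or a non-empty set of
# that genome's genes, and is represented as a character vector of length n
# whose slots are "*" or comma-joined, sorted gene ids. Singleton slots in
# clique / quasi-clique aggregation; connected-component aggregation may put
# several genes of one genome in a slot.

DC <- "*"

spine_slot <- function(genes) paste(sort(genes), collapse = ",")

slot_genes <- function(slot) {
  if (slot == DC) character(0) else strsplit(slot, ",", fixed = TRUE)[[1L]]
}

spine_key <- function(spine) paste(spine, collapse = "\t")

#' Create an aggregation rule for multi-genome spines
#'
#' The aggregator is the topology constraint turning the pairwise
#' correspondence relation `S` into multi-genome spines: `"clique"` requires
#' all covered genes to be pairwise `S`-related, `"cc"` (connected component)
#' only requires them to form a connected subgraph of `S`, and `"quasi"`
#' (gamma-quasi-clique) requires every covered gene to be `S`-related to at
#' least `gamma * (k - 1)` of the `k - 1` other covered genes.
#'
#' @param mode `"clique"`, `"cc"` (alias `"connected_component"`) or
#'   `"quasi"` (alias `"quasi_clique"`).
#' @param gamma Minimum degree fraction in `(0, 1]`; required for (and only
#'   meaningful with) `mode = "quasi"`.
#' @return An object of class `aggregator`.
#' @export
aggregator <- function(mode = c("clique", "cc", "quasi", "connected_component",
                                "quasi_clique"),
                       gamma = NULL) {
  mode <- match.arg(mode)
  mode <- switch(mode, connected_component = "cc", quasi_clique = "quasi", mode)
  if (mode == "quasi") {
    if (is.null(gamma) || !is.numeric(gamma) || length(gamma) != 1L ||
        gamma <= 0 || gamma > 1)
      stop_input("quasi-clique aggregation needs gamma in (0, 1]")
  } else if (!is.null(gamma)) {
    stop_input("gamma is only meaningful for quasi-clique aggregation")
  }
  structure(list(mode = mode, gamma = if (mode == "quasi") gamma else NULL),
            class = "aggregator")
}

#' @export
print.aggregator <- function(x, ...) {
  cat("aggregator:", x$mode,
      if (x$mode == "quasi") sprintf("(gamma = %g)", x$gamma) else "", "\n")
  invisible(x)
}

#' Cover and covered layers of a spine
#'
#' `spine_cover()` returns the set of genes of a spine that are not don't-care
#' marks; `spine_layers()` returns the indices of the covered genomes
#' (the layer set `I`).
#'
#' @param spine A spine: character vector with one slot per genome, each
#'   either `"*"` or a (comma-joined) set of gene ids.
#' @return `spine_cover()`: a character vector of gene ids;
#'   `spine_layers()`: an integer vector of genome indices.
#' @examples
#' spine_cover(c("a1", "*", "a3"))   # "a1" "a3"
#' spine_layers(c("a1", "*", "a3"))  # 1 3
#' @export
spine_cover <- function(spine) {
  unlist(lapply(spine[spine != DC], slot_genes), use.names = FALSE)
}

#' @rdname spine_cover
#' @export
spine_layers <- function(spine) which(spine != DC)

# number of S-edges from gene g into the gene set `others`
degree_within <- function(graph, g, others) {
  sum(others %in% graph$adj[[g]])
}

# exact aggregation test on a set of covered genes
aggregation_holds <- function(graph, genes, agg) {
  k <- length(genes)
  if (k <= 1L) return(TRUE)
  if (agg$mode == "cc") {
    sub <- igraph::make_graph(edges = character(0), isolates = genes,
                              directed = FALSE)
    keep <- graph$pairs[, 1L] %in% genes & graph$pairs[, 2L] %in% genes
    if (any(keep))
      sub <- igraph::add_edges(sub, t(graph$pairs[keep, , drop = FALSE]))
    return(igraph::components(sub)$no == 1L)
  }
  gamma <- if (agg$mode == "clique") 1 else agg$gamma
  eps <- 1e-9
  for (g in genes) {
    if (degree_within(graph, g, setdiff(genes, g)) < gamma * (k - 1L) - eps)
      return(FALSE)
  }
  TRUE
}

#' Is a candidate tuple a valid spine?
#'
#' Checks the two defining clauses: the quorum (at least `q` covered genomes,
#' hence at most `n - q` don't-care slots) and the aggregation rule on the
#' covered genes (don't-care slots are ignored by the rule).
#'
#' @param spine Candidate spine (see [spine_cover()] for the representation).
#' @param graph A [layered_graph()].
#' @param agg An [aggregator()].
#' @param q Quorum, an integer with `2 <= q <= n`.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_spine <- function(spine, graph, agg, q) {
  stopifnot(inherits(graph, "layered_graph"), inherits(agg, "aggregator"))
  if (length(spine) != graph$n)
    stop_usage("spine has %d slots; %d genomes in the graph",
               length(spine), graph$n)
  layers <- spine_layers(spine)
  for (i in layers) {
    gs <- slot_genes(spine[i])
    if (length(gs) == 0L) return(FALSE)
    if (!all(gs %in% names(graph$genome_of)) ||
        !all(graph$genome_of[gs] == i))
      stop_usage("slot %d of spine contains genes not on genome %d", i, i)
  }
  if (length(layers) < q) return(FALSE)
  aggregation_holds(graph, spine_cover(spine), agg)
}

#' Enumerate all spines of a layered data graph
#'
#' Explicit enumeration used by the brute-force oracle path (small instances).
#' In clique mode, all tuples with one gene per covered layer, at least `q`
#' covered layers and pairwise `S`-related genes are returned — sub-cliques of
#' a larger clique are distinct spines. In quasi-clique mode the per-gene
#' degree rule replaces the pairwise one. In connected-component mode there is
#' one spine per connected component of `S` spanning at least `q` genomes;
#' its slot `i` holds all the component's genes on genome `i`.
#'
#' @inheritParams is_valid_spine
#' @param spine_cap Guard against combinatorial explosion: the enumeration
#'   aborts with a resource error when the candidate space (or, in clique
#'   mode, the clique count) exceeds this cap.
#' @return A list of spines in canonical (lexicographic) order.
#' @examples
#' g <- layered_graph(list(G1 = c("a1", "b1"), G2 = c("a2", "b2"), G3 = "a3"),
#'                    rbind(c("a1","a2"), c("a1","a3"), c("a2","a3"),
#'                          c("b1","b2")))
#' length(enumerate_spines(g, aggregator("clique"), q = 2))  # 5
#' @export
enumerate_spines <- function(graph, agg, q, spine_cap = 2e6) {
  stopifnot(inherits(graph, "layered_graph"), inherits(agg, "aggregator"))
  check_quorum(graph, q)
  spines <- switch(agg$mode,
                   cc = enumerate_cc_spines(graph, q),
                   enumerate_tuple_spines(graph, agg, q, spine_cap))
  spines[order(vapply(spines, spine_key, character(1)))]
}

check_quorum <- function(graph, q) {
  if (!is.numeric(q) || length(q) != 1L || q != round(q) || q < 2L ||
      q > graph$n)
    stop_input("quorum q must be an integer with 2 <= q <= n = %d", graph$n)
}

enumerate_cc_spines <- function(graph, q) {
  if (nrow(graph$pairs) == 0L) return(list())
  sg <- igraph::graph_from_edgelist(graph$pairs, directed = FALSE)
  comp <- igraph::components(sg)
  members <- split(igraph::V(sg)$name, comp$membership)
  out <- list()
  for (genes in members) {
    layers <- sort(unique(unname(graph$genome_of[genes])))
    if (length(layers) < q) next
    spine <- rep(DC, graph$n)
    for (i in layers)
      spine[i] <- spine_slot(genes[graph$genome_of[genes] == i])
    out[[length(out) + 1L]] <- spine
  }
  out
}

# clique and quasi-clique: one gene (or don't-care) per layer. Only genes with
# at least one S edge can be covered (every covered gene needs degree >= 1
# because k >= q >= 2 and gamma > 0), so the candidate space is restricted to
# S-active genes.
enumerate_tuple_spines <- function(graph, agg, q, spine_cap) {
  active <- names(graph$adj)[lengths(graph$adj) > 0L]
  if (length(active) == 0L) return(list())
  if (agg$mode == "clique")
    return(enumerate_clique_spines(graph, q, active, spine_cap))
  by_layer <- lapply(seq_len(graph$n),
                     function(i) sort(active[graph$genome_of[active] == i]))
  sizes <- lengths(by_layer) + 1L
  if (prod(sizes) > spine_cap)
    stop_resource(paste0("spine candidate space (%.3g tuples) exceeds the cap ",
                         "(%.3g); raise spine_cap or the quorum"),
                  prod(sizes), spine_cap)
  # index 0 codes the don't-care slot
  idx <- as.matrix(do.call(expand.grid,
                           lapply(sizes, function(s) 0:(s - 1L))))
  covered_n <- rowSums(idx > 0L)
  idx <- idx[covered_n >= q, , drop = FALSE]
  if (nrow(idx) == 0L) return(list())
  covered_n <- covered_n[covered_n >= q]
  gid <- setNames(seq_along(active), active)
  A <- matrix(FALSE, length(active), length(active))
  pr <- cbind(gid[graph$pairs[, 1L]], gid[graph$pairs[, 2L]])
  pr <- pr[!is.na(pr[, 1L]) & !is.na(pr[, 2L]), , drop = FALSE]
  A[pr] <- TRUE
  A[pr[, 2:1, drop = FALSE]] <- TRUE
  # map layer-local index to global gene index (0 stays 0)
  glob <- matrix(0L, nrow(idx), graph$n)
  for (i in seq_len(graph$n)) {
    li <- idx[, i]
    glob[li > 0L, i] <- gid[by_layer[[i]][li[li > 0L]]]
  }
  deg <- matrix(0L, nrow(idx), graph$n)
  for (i in seq_len(graph$n - 1L)) {
    for (j in (i + 1L):graph$n) {
      both <- glob[, i] > 0L & glob[, j] > 0L
      if (!any(both)) next
      rel <- A[cbind(glob[both, i], glob[both, j])]
      deg[both, i] <- deg[both, i] + rel
      deg[both, j] <- deg[both, j] + rel
    }
  }
  gamma <- agg$gamma
  eps <- 1e-9
  need <- gamma * (covered_n - 1L) - eps
  ok <- rep(TRUE, nrow(idx))
  for (i in seq_len(graph$n))
    ok <- ok & (glob[, i] == 0L | deg[, i] >= need)
  glob <- glob[ok, , drop = FALSE]
  lapply(seq_len(nrow(glob)), function(r) {
    spine <- rep(DC, graph$n)
    cov <- glob[r, ] > 0L
    spine[cov] <- active[glob[r, cov]]
    spine
  })
}

enumerate_clique_spines <- function(graph, q, active, spine_cap) {
  if (nrow(graph$pairs) == 0L) return(list())
  sg <- igraph::graph_from_edgelist(graph$pairs, directed = FALSE)
  cl <- igraph::cliques(sg, min = q)
  if (length(cl) > spine_cap)
    stop_resource("clique count (%d) exceeds the cap (%.3g); raise the quorum",
                  length(cl), spine_cap)
  lapply(cl, function(vs) {
    genes <- igraph::V(sg)$name[vs]
    spine <- rep(DC, graph$n)
    spine[graph$genome_of[genes]] <- genes
    spine
  })
}

#' Serialise spines
#'
#' `spines_to_tsv()` writes one spine per row with one column per genome and
#' `"*"` for don't-care slots; `spines_to_json()` writes records
#' `{"layers": [...genes or null...]}`.
#'
#' @param spines List of spines.
#' @param graph A [layered_graph()] (provides genome names).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
spines_to_tsv <- function(spines, graph, path) {
  m <- do.call(rbind, lapply(spines, identity))
  if (is.null(m)) m <- matrix(character(0), 0L, graph$n)
  colnames(m) <- graph$genome_names
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname spines_to_tsv
#' @export
spines_to_json <- function(spines, graph, path) {
  recs <- lapply(spines, function(s) {
    list(layers = lapply(seq_along(s), function(i) {
      if (s[i] == DC) NULL else slot_genes(s[i])
    }))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
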