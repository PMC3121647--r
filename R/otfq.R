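# The production path: depth-first, on-the-fly construction and partitioning
# of the (partial) network alignment multigraph. Genomes are added one layer
# at a time; the current class of partial spines is alternately SPLIT
# (partitioned into per-colour connected components, don't-care members
# replicated into every part) and EXPANDed (each member extended by its
# terminals on the next genome and, budget permitting, by a don't-care slot).
# The full multigraph is never materialised: per-colour connectivity is
# computed by rank-window clustering of the occupied slot ranks.

#' Engine configuration
#'
#' @param q Quorum: minimum number of genomes a spine (hence a synton) must
#'   cover; `n - q` bounds the don't-care slots per spine.
#' @param delta_gap Gap radius of the interval rule (see [layered_graph()]);
#'   `NULL` keeps the graph's value.
#' @param aggregator An [aggregator()].
#' @param min_size Minimum synton size, counted in spines per synton.
#' @param maximal_only Keep only syntons maximal under gene-set subsumption
#'   (see [maximal_syntons()]).
#' @param spine_cap Resource guard: maximum number of live partial spines.
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(q = 2L, delta_gap = NULL,
                          aggregator = synton::aggregator("clique"),
                          min_size = 1L, maximal_only = FALSE,
                          spine_cap = 2e6) {
  if (!is.numeric(min_size) || min_size < 1L)
    stop_input("min_size must be >= 1")
  structure(list(q = as.integer(q), delta_gap = delta_gap,
                 aggregator = aggregator, min_size = as.integer(min_size),
                 maximal_only = isTRUE(maximal_only), spine_cap = spine_cap),
            class = "engine_config")
}

# A search class: layer i (colours 1..i processed) and a list of partial
# spines over layers 1..i (slots i+1..n undefined).
new_class <- function(layer, members) list(layer = layer, members = members)

#' Initialise the depth-first search
#'
#' Returns one class per connected component of the first genome's interval
#' graph (members are 1-slot tuples of its genes) plus, when `q < n`, one
#' extra class whose sole member is the don't-care 1-tuple (so blocks missing
#' from genome 1 can still be found).
#'
#' @param graph A [layered_graph()].
#' @param cfg An [engine_config()].
#' @return A list of search classes.
#' @export
initialize_classes <- function(graph, cfg) {
  g1 <- graph$genes[graph$genes$genome == 1L, , drop = FALSE]
  comp <- components_by_rank(as.list(g1$rank), graph$lengths[1L],
                             graph$circular[1L], effective_delta(graph, cfg))
  classes <- lapply(unname(split(g1$gene, comp)), function(genes)
    new_class(1L, lapply(genes, function(g) g)))
  if (cfg$q < graph$n)
    classes <- c(classes, list(new_class(1L, list(DC))))
  classes
}

effective_delta <- function(graph, cfg) {
  if (is.null(cfg$delta_gap)) graph$delta_gap else as.integer(cfg$delta_gap)
}

# per-colour component membership of a member subset, by rank clustering
member_colour_components <- function(members, j, graph, delta) {
  ranks <- lapply(members, function(m) slot_ranks(graph, m[j]))
  components_by_rank(ranks, graph$lengths[j], graph$circular[j], delta)
}

#' Split a search class on its processed colours
#'
#' For each colour `j <= layer` in turn, the members covered at `j` are
#' partitioned into connected components of colour-`j` adjacency (interval
#' rule on the slot-`j` genes). If some colour yields more than one
#' component, one class per component is returned, each augmented with all
#' members having a don't-care at `j` (this duplication across branches is
#' deliberate; it is resolved in [finalize_classes()]). If no colour splits
#' the class it is stable and is returned unchanged as a length-1 list.
#'
#' @param C A search class (see [initialize_classes()]).
#' @param graph A [layered_graph()].
#' @param cfg An [engine_config()].
#' @return A list of search classes (length 1 iff stable).
#' @export
split_class <- function(C, graph, cfg) {
  delta <- effective_delta(graph, cfg)
  for (j in seq_len(C$layer)) {
    covered <- which(vapply(C$members, function(m) m[j] != DC, logical(1)))
    if (length(covered) < 2L) next
    memb <- member_colour_components(C$members[covered], j, graph, delta)
    if (length(unique(memb)) == 1L) next
    dcs <- C$members[setdiff(seq_along(C$members), covered)]
    return(lapply(unname(split(covered, memb)), function(part)
      new_class(C$layer, c(C$members[part], dcs))))
  }
  list(C)
}

# terminals of a member on genome `layer`: genes that can extend the partial
# spine without excluding every valid completion. For cliques the extended
# prefix must itself be a clique (exact necessary condition). For
# quasi-cliques the exact degree rule on a prefix is NOT necessary (missing
# relations may be compensated on later genomes), so the provably safe bound
# deg_prefix(w) + r >= gamma * (k_prefix + r - 1) is used instead, with r the
# number of remaining genomes; for gamma = 1 it reduces to the clique rule.
member_terminals <- function(member, layer, graph, cfg) {
  covered <- spine_cover(member)
  agg <- cfg$aggregator
  layer_genes <- function(ids) ids[graph$genome_of[ids] == layer]
  if (length(covered) == 0L) {
    active <- names(graph$adj)[lengths(graph$adj) > 0L]
    return(sort(layer_genes(active)))
  }
  if (agg$mode == "clique") {
    cand <- layer_genes(Reduce(intersect, graph$adj[covered]))
    return(sort(cand))
  }
  # quasi-clique
  active <- names(graph$adj)[lengths(graph$adj) > 0L]
  cand <- sort(layer_genes(active))
  r <- graph$n - layer
  gamma <- agg$gamma
  eps <- 1e-9
  keep <- vapply(cand, function(t) {
    ext <- c(covered, t)
    k <- length(ext)
    all(vapply(ext, function(w)
      degree_within(graph, w, setdiff(ext, w)) + r >=
        gamma * (k + r - 1L) - eps, logical(1)))
  }, logical(1))
  cand[keep]
}

# can the member still become valid if extended by a don't-care here?
dc_feasible <- function(member, layer, graph, cfg) {
  agg <- cfg$aggregator
  if (agg$mode == "clique") return(TRUE)
  covered <- spine_cover(member)
  if (length(covered) == 0L) return(TRUE)
  r <- graph$n - layer
  k <- length(covered)
  gamma <- agg$gamma
  eps <- 1e-9
  all(vapply(covered, function(w)
    degree_within(graph, w, setdiff(covered, w)) + r >=
      gamma * (k + r - 1L) - eps, logical(1)))
}

#' Expand a stable class to the next genome
#'
#' Each member `v` of a class stable at layer `i < n` is extended by every
#' terminal gene of genome `i + 1` compatible with the aggregation rule, and
#' by a don't-care slot when `v`'s don't-care count is below the budget
#' `n - q`. Members with no extension at all are dropped (dead branch).
#'
#' @inheritParams split_class
#' @return The layer-`i + 1` search class (possibly with zero members).
#' @export
expand_class <- function(C, graph, cfg) {
  nxt <- C$layer + 1L
  budget <- graph$n - cfg$q
  out <- list()
  for (m in C$members) {
    terms <- member_terminals(m, nxt, graph, cfg)
    for (t in terms) out[[length(out) + 1L]] <- c(m, t)
    if (sum(m == DC) < budget && dc_feasible(m, nxt, graph, cfg))
      out[[length(out) + 1L]] <- c(m, DC)
  }
  if (length(out) > 1L) {
    keys <- vapply(out, spine_key, character(1))
    out <- out[!duplicated(keys)]
  }
  new_class(nxt, out)
}

#' Finalize the stable layer-n classes into a synton partition
#'
#' Drops members violating the quorum or the exact aggregation rule on the
#' full tuple, splits each class by covered-layer signature, re-refines each
#' group by per-colour connectivity, deduplicates syntons across branches and
#' asserts the partition property (no spine in two distinct syntons).
#'
#' @param stable List of stable layer-`n` search classes.
#' @param graph A [layered_graph()].
#' @param cfg An [engine_config()].
#' @return A `synton_partition` (before size/maximality filtering).
#' @export
finalize_classes <- function(stable, graph, cfg) {
  delta <- effective_delta(graph, cfg)
  syntons <- list()
  seen <- character(0)
  for (C in stable) {
    ok <- vapply(C$members, function(m)
      is_valid_spine(m, graph, cfg$aggregator, cfg$q), logical(1))
    members <- C$members[ok]
    if (length(members) == 0L) next
    sig <- vapply(members, function(m)
      paste(spine_layers(m), collapse = ","), character(1))
    for (group in unname(split(seq_along(members), sig))) {
      I <- spine_layers(members[[group[1L]]])
      parts <- refine_parts(group, I, function(part, i)
        member_colour_components(members[part], i, graph, delta))
      for (part in parts) {
        sp <- members[part]
        keys <- sort(vapply(sp, spine_key, character(1)))
        id <- paste(keys, collapse = "\n")
        if (id %in% seen) next
        seen <- c(seen, id)
        syntons[[length(syntons) + 1L]] <- list(spines = sp, cover = I)
      }
    }
  }
  all_keys <- unlist(lapply(syntons, function(s)
    vapply(s$spines, spine_key, character(1))))
  if (anyDuplicated(all_keys))
    stop_internal("partition property violated: spine assigned to two syntons")
  new_partition(syntons, graph, cfg$q)
}

#' Exact synton partition via the on-the-fly engine
#'
#' Computes the synton partition of the (partial) network alignment
#' multigraph without materialising it: a depth-first recursion alternates
#' [split_class()] until stability and [expand_class()] to the next genome,
#' and the stable layer-`n` classes are consolidated by
#' [finalize_classes()]. The result equals the definition-driven
#' [oracle_partition()] of the explicitly enumerated multigraph, restricted
#' to syntons with at least `min_size` spines.
#'
#' Connected-component aggregation bypasses the incremental expansion: the
#' spines are whole components of the correspondence relation, precomputed,
#' and only the split/finalize machinery is applied to them.
#'
#' @param graph A [layered_graph()].
#' @param q Quorum (`2 <= q <= n`).
#' @param aggregator An [aggregator()].
#' @param min_size Minimum spines per reported synton.
#' @param maximal_only Keep only maximal syntons under subsumption.
#' @param delta_gap Override the graph's gap radius (`NULL`: keep).
#' @param spine_cap Resource guard on live partial spines; exceeding it
#'   raises a resource error advising a higher quorum.
#' @return A `synton_partition`.
#' @examples
#' fx <- otfq_fixture("F2")
#' otfq_partition(fx$graph, q = fx$q)
#' @export
otfq_partition <- function(graph, q = 2L,
                           aggregator = synton::aggregator("clique"),
                           min_size = 1L, maximal_only = FALSE,
                           delta_gap = NULL, spine_cap = 2e6) {
  stopifnot(inherits(graph, "layered_graph"))
  check_quorum(graph, q)
  cfg <- engine_config(q = q, delta_gap = delta_gap, aggregator = aggregator,
                       min_size = min_size, maximal_only = maximal_only,
                       spine_cap = spine_cap)
  part <- if (cfg$aggregator$mode == "cc") {
    spines <- enumerate_spines(with_delta(graph, cfg), cfg$aggregator, q,
                               spine_cap)
    finalize_classes(list(new_class(graph$n, spines)),
                     with_delta(graph, cfg), cfg)
  } else {
    otfq_search(graph, cfg)
  }
  part <- filter_min_size(part, cfg$min_size)
  if (cfg$maximal_only) part <- maximal_syntons(part)
  part
}

with_delta <- function(graph, cfg) {
  if (!is.null(cfg$delta_gap)) graph$delta_gap <- as.integer(cfg$delta_gap)
  graph
}

otfq_search <- function(graph, cfg) {
  stack <- initialize_classes(graph, cfg)
  finals <- list()
  live <- sum(vapply(stack, function(C) length(C$members), integer(1)))
  while (length(stack) > 0L) {
    C <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    parts <- split_class(C, graph, cfg)
    if (length(parts) > 1L) {
      stack <- c(stack, parts)
    } else if (C$layer < graph$n) {
      NC <- expand_class(C, graph, cfg)
      if (length(NC$members) > 0L) {
        live <- live + length(NC$members)
        if (live > cfg$spine_cap)
          stop_resource(paste0("live partial spine count exceeds the cap ",
                               "(%.3g); consider a higher quorum"),
                        cfg$spine_cap)
        stack <- c(stack, list(NC))
      }
    } else {
      finals <- c(finals, list(C))
    }
  }
  finalize_classes(finals, with_delta(graph, cfg), cfg)
}
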