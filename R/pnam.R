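# Explicit (partial) network alignment multigraph and the definition-driven
# synton partition. This is the brute-force oracle path: every colour edge is
# materialised pairwise and connectivity questions are answered with igraph
# components, independently of the on-the-fly engine.

slot_ranks <- function(graph, slot) {
  unname(graph$rank_of[slot_genes(slot)])
}

#' Colour edge between two spines
#'
#' Spines `u` and `v` are joined by an edge of colour `i` when both are
#' covered at layer `i` and some gene of `u`'s slot `i` is a neighbour
#' (interval rule, [interval_edge()]) of some gene of `v`'s slot `i`. Two
#' spines sharing an identical gene at slot `i` are joined (distance 0).
#'
#' @param u,v Spines (`u != v`).
#' @param i Layer (genome) index.
#' @param graph A [layered_graph()].
#' @return `TRUE` or `FALSE`.
#' @export
colour_edge <- function(u, v, i, graph) {
  if (u[i] == DC || v[i] == DC) return(FALSE)
  ru <- slot_ranks(graph, u[i])
  rv <- slot_ranks(graph, v[i])
  d <- outer(ru, rv, function(a, b)
    rank_distance(a, b, graph$lengths[i], graph$circular[i]))
  min(d) <= graph$delta_gap
}

#' Materialise the partial network alignment multigraph
#'
#' Builds the explicit PNAM over a validated spine set: vertices are the
#' spines; for each genome `i` a colour-`i` edge set joins spines whose
#' slot-`i` genes are neighbours. All edges are materialised by pairwise
#' [colour_edge()] tests — this is the oracle path and is only meant for
#' desk-scale instances.
#'
#' @param spines List of spines (e.g. from [enumerate_spines()]).
#' @param graph A [layered_graph()].
#' @param spine_cap Resource guard on the vertex count.
#' @return An object of class `pnam` with elements `spines`, `edges` (one
#'   two-column index matrix per colour) and `graph`.
#' @export
build_pnam <- function(spines, graph, spine_cap = 2e6) {
  stopifnot(inherits(graph, "layered_graph"))
  keys <- vapply(spines, spine_key, character(1))
  spines <- spines[!duplicated(keys)][order(unique(keys))]
  m <- length(spines)
  if (m > spine_cap)
    stop_resource("PNAM vertex count (%d) exceeds the cap (%.3g)", m, spine_cap)
  edges <- vector("list", graph$n)
  for (i in seq_len(graph$n)) {
    covered <- which(vapply(spines, function(s) s[i] != DC, logical(1)))
    el <- matrix(integer(0), 0L, 2L)
    if (length(covered) >= 2L) {
      ranks <- lapply(spines[covered], function(s) slot_ranks(graph, s[i]))
      if (all(lengths(ranks) == 1L)) {
        r <- unlist(ranks)
        m <- length(r)
        chunk <- 2000L
        starts <- seq.int(1L, m, by = chunk)
        hits <- list()
        for (sa in starts) {
          ea <- min(sa + chunk - 1L, m)
          for (sb in starts) {
            eb <- min(sb + chunk - 1L, m)
            if (eb < sa) next
            d <- abs(outer(r[sa:ea], r[sb:eb], "-"))
            if (graph$circular[i]) d <- pmin(d, graph$lengths[i] - d)
            h <- which(d <= graph$delta_gap, arr.ind = TRUE)
            if (nrow(h) > 0L) {
              h[, 1L] <- h[, 1L] + sa - 1L
              h[, 2L] <- h[, 2L] + sb - 1L
              h <- h[h[, 1L] < h[, 2L], , drop = FALSE]
              if (nrow(h) > 0L) hits[[length(hits) + 1L]] <- h
            }
          }
        }
        hit <- if (length(hits) > 0L) do.call(rbind, hits) else
          matrix(integer(0), 0L, 2L)
      } else {
        m <- length(ranks)
        d <- matrix(0L, m, m)
        for (a in seq_len(m - 1L)) {
          for (b in (a + 1L):m) {
            dd <- abs(outer(ranks[[a]], ranks[[b]], "-"))
            if (graph$circular[i]) dd <- pmin(dd, graph$lengths[i] - dd)
            d[a, b] <- min(dd)
          }
        }
        hit <- which(upper.tri(d) & d <= graph$delta_gap, arr.ind = TRUE)
      }
      el <- cbind(covered[hit[, 1L]], covered[hit[, 2L]])
    }
    edges[[i]] <- el
  }
  structure(list(spines = spines, edges = edges, graph = graph),
            class = "pnam")
}

#' @export
print.pnam <- function(x, ...) {
  cat(sprintf("PNAM: %d spines; colour edge counts: %s\n",
              length(x$spines),
              paste(vapply(x$edges, nrow, integer(1)), collapse = ", ")))
  invisible(x)
}

# connected components of the vertex subset `idx` using the colour-i edges of
# the pnam restricted to that subset
pnam_colour_components <- function(pnam, idx, i) {
  el <- pnam$edges[[i]]
  keep <- el[, 1L] %in% idx & el[, 2L] %in% idx
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (any(keep)) {
    local <- matrix(match(el[keep, , drop = FALSE], idx), ncol = 2L)
    g <- igraph::add_edges(g, t(local))
  }
  igraph::components(g)$membership
}

#' Partition the PNAM vertices into syntons (oracle)
#'
#' Implements the synton definition directly: vertices are grouped by their
#' covered-layer signature `I` (cover uniformity); within each group the
#' coarsest partition into parts connected on every colour `i` in `I` is
#' computed by fixpoint refinement (repeatedly split a part into the
#' connected components of one colour restricted to the part, cycling colours
#' until stable). The parts are the syntons; they are pairwise disjoint and
#' cover all vertices.
#'
#' @param pnam A [build_pnam()] object.
#' @param q Quorum; vertices covering fewer than `q` layers are rejected.
#' @return An object of class `synton_partition`: a list of syntons, each a
#'   list with elements `spines` (canonically sorted list of spines) and
#'   `cover` (integer layer set `I`).
#' @export
oracle_partition <- function(pnam, q) {
  stopifnot(inherits(pnam, "pnam"))
  graph <- pnam$graph
  check_quorum(graph, q)
  covers <- lapply(pnam$spines, spine_layers)
  if (any(lengths(covers) < q))
    stop_input("PNAM contains a vertex covering fewer than q = %d layers", q)
  sig <- vapply(covers, paste, character(1), collapse = ",")
  groups <- split(seq_along(pnam$spines), sig)
  syntons <- list()
  for (idx in groups) {
    I <- covers[[idx[1L]]]
    parts <- refine_parts(idx, I, function(part, i)
      pnam_colour_components(pnam, part, i))
    for (part in parts)
      syntons[[length(syntons) + 1L]] <- list(spines = pnam$spines[part],
                                              cover = I)
  }
  new_partition(syntons, graph, q)
}

# generic fixpoint refinement: split parts into per-colour components until
# stable; comp_fun(part_indices, colour) returns component membership ids
refine_parts <- function(idx, colours, comp_fun) {
  work <- list(idx)
  done <- list()
  while (length(work) > 0L) {
    part <- work[[1L]]
    work <- work[-1L]
    split_found <- FALSE
    for (i in colours) {
      memb <- comp_fun(part, i)
      if (length(unique(memb)) > 1L) {
        work <- c(work, unname(split(part, memb)))
        split_found <- TRUE
        break
      }
    }
    if (!split_found) done[[length(done) + 1L]] <- part
  }
  done
}

new_partition <- function(syntons, graph, q) {
  # canonical form: spines sorted within syntons, syntons sorted by first key
  syntons <- lapply(syntons, function(s) {
    keys <- vapply(s$spines, spine_key, character(1))
    list(spines = s$spines[order(keys)], cover = sort(s$cover))
  })
  ord <- order(vapply(syntons, function(s)
    spine_key(s$spines[[1L]]), character(1)))
  structure(syntons[ord], class = "synton_partition",
            n = graph$n, q = as.integer(q),
            genome_names = graph$genome_names)
}

#' @export
print.synton_partition <- function(x, ...) {
  sizes <- vapply(x, function(s) length(s$spines), integer(1))
  cat(sprintf("synton partition: %d syntons (quorum %d, %d genomes)\n",
              length(x), attr(x, "q"), attr(x, "n")))
  if (length(x) > 0L) {
    covs <- vapply(x, function(s)
      paste(attr(x, "genome_names")[s$cover], collapse = "+"), character(1))
    df <- data.frame(synton = seq_along(x), n_spines = sizes, cover = covs)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Check a spine set against the synton definition
#'
#' A set of PNAM vertices is a synton when (i) all members share the same
#' covered-layer set `I` with `|I| >= q`, (ii) the set is connected on every
#' colour `i` in `I` using only edges among its own members, and (iii) it is
#' maximal: no other vertex of equal cover can be added without breaking a
#' connectivity condition.
#'
#' @param spines List of spines, all vertices of `pnam`.
#' @param pnam A [build_pnam()] object.
#' @param q Quorum.
#' @return `TRUE` or `FALSE`.
#' @export
is_synton <- function(spines, pnam, q) {
  stopifnot(inherits(pnam, "pnam"))
  keys <- vapply(pnam$spines, spine_key, character(1))
  idx <- match(vapply(spines, spine_key, character(1)), keys)
  if (anyNA(idx)) stop_usage("some spines are not vertices of the PNAM")
  if (length(idx) == 0L) return(FALSE)
  I <- spine_layers(spines[[1L]])
  if (length(I) < q) return(FALSE)
  same <- vapply(spines, function(s) identical(spine_layers(s), I), logical(1))
  if (!all(same)) return(FALSE)
  conn <- function(part) {
    all(vapply(I, function(i)
      length(unique(pnam_colour_components(pnam, part, i))) == 1L, logical(1)))
  }
  if (!conn(idx)) return(FALSE)
  # maximality among equal-cover vertices
  others <- setdiff(which(vapply(pnam$spines, function(s)
    identical(spine_layers(s), I), logical(1))), idx)
  for (v in others) {
    if (conn(c(idx, v))) return(FALSE)
  }
  TRUE
}

#' Export a PNAM as JSON
#'
#' Writes the vertex list and the per-colour edge lists (0-based vertex
#' indices) for debugging and external inspection.
#'
#' @param pnam A [build_pnam()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
pnam_to_json <- function(pnam, path) {
  obj <- list(
    schema = "synton-pnam/1",
    genomes = pnam$graph$genome_names,
    vertices = lapply(pnam$spines, function(s)
      lapply(seq_along(s), function(i)
        if (s[i] == DC) NULL else slot_genes(s[i]))),
    edges = lapply(pnam$edges, function(el) {
      if (nrow(el) == 0L) list() else
        lapply(seq_len(nrow(el)), function(r) el[r, ] - 1L)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
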