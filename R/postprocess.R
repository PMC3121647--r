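# Post-processing of synton partitions: subsumption/maximality filtering,
# size filtering, projection back onto the genomes, and the
# largest-synton-per-pair statistic.

#' Spine and synton subsumption
#'
#' A spine `u` is subsumed by `v` (`u` "below" `v`) when the genes covered by
#' `u` are a subset of the genes covered by `v`. Lifted to syntons: `C1` is
#' subsumed by `C2` when every spine of `C1` is subsumed by some spine of
#' `C2`. Both relations are reflexive and transitive.
#'
#' @param u,v Spines of equal length.
#' @return `TRUE` or `FALSE`.
#' @examples
#' spine_subsumes(c("a1", "*", "a3"), c("a1", "a2", "a3"))  # TRUE
#' @export
spine_subsumes <- function(u, v) {
  if (length(u) != length(v))
    stop_usage("spines have different slot counts")
  all(spine_cover(u) %in% spine_cover(v))
}

#' @rdname spine_subsumes
#' @param C1,C2 Syntons (elements of a `synton_partition`).
#' @export
synton_subsumes <- function(C1, C2) {
  all(vapply(C1$spines, function(u)
    any(vapply(C2$spines, function(v) spine_subsumes(u, v), logical(1))),
    logical(1)))
}

#' Maximal syntons under subsumption
#'
#' Although every synton of the partition is maximal in the connectivity
#' sense, its gene projection may be contained in another synton's (typically
#' a block on `k` genomes with the same boundaries as a block on `k + 1`
#' genomes). This final filter removes such redundancy: a synton is kept
#' unless it is strictly subsumed by another one (mutual subsumption keeps
#' both).
#'
#' @param P A `synton_partition`.
#' @return The filtered synton list (same class; no longer a full partition).
#' @export
maximal_syntons <- function(P) {
  stopifnot(inherits(P, "synton_partition"))
  if (length(P) <= 1L) return(P)
  keep <- rep(TRUE, length(P))
  for (i in seq_along(P)) {
    for (j in seq_along(P)) {
      if (i == j) next
      if (synton_subsumes(P[[i]], P[[j]]) && !synton_subsumes(P[[j]], P[[i]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  subset_partition(P, keep)
}

#' Filter syntons by size
#'
#' Keeps syntons with at least `m` spines.
#'
#' @param P A `synton_partition`.
#' @param m Minimum spine count, `>= 1`.
#' @return The filtered synton list (same class).
#' @export
filter_min_size <- function(P, m) {
  stopifnot(inherits(P, "synton_partition"))
  if (!is.numeric(m) || m < 1L) stop_input("min size must be >= 1")
  keep <- vapply(P, function(s) length(s$spines) >= m, logical(1))
  subset_partition(P, keep)
}

subset_partition <- function(P, keep) {
  out <- P[keep]
  attributes(out) <- attributes(P)[c("class", "n", "q", "genome_names")]
  out
}

#' Project a synton back onto the genomes
#'
#' For each covered genome, reports the synton's gene set (union of the
#' member spines' slot genes), its rank span, and the number of gap genes —
#' genes lying inside the span but not belonging to any spine of the synton.
#'
#' @param C A synton (element of a `synton_partition`).
#' @param graph A [layered_graph()].
#' @return A data.frame with one row per covered genome: `genome`,
#'   `n_genes`, `genes` (comma-joined, rank order), `span_min`, `span_max`,
#'   `n_gap`.
#' @export
project_synton <- function(C, graph) {
  stopifnot(inherits(graph, "layered_graph"))
  out <- lapply(C$cover, function(i) {
    genes <- unique(unlist(lapply(C$spines, function(s) slot_genes(s[i]))))
    rk <- unname(graph$rank_of[genes])
    genes <- genes[order(rk)]
    rk <- sort(rk)
    span <- range(rk)
    inside <- graph$genes$genome == i & graph$genes$rank >= span[1L] &
      graph$genes$rank <= span[2L]
    n_gap <- sum(inside) - length(genes)
    data.frame(genome = graph$genome_names[i], n_genes = length(genes),
               genes = paste(genes, collapse = ","),
               span_min = span[1L], span_max = span[2L], n_gap = n_gap,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Size of the largest synton containing each correspondence pair
#'
#' For every pair of the correspondence relation, records the spine count of
#' the largest synton whose spines contain both genes (in any of its spines),
#' or 0 when no synton contains both. Pairs with `max_size = 0` are excluded
#' from the output by default.
#'
#' @param P A `synton_partition`.
#' @param graph A [layered_graph()] (provides the relation).
#' @param keep_zero Keep pairs contained in no synton (`max_size = 0`)?
#' @return A data.frame with columns `gene1`, `gene2`, `max_size`.
#' @export
max_synton_size_per_pair <- function(P, graph, keep_zero = FALSE) {
  stopifnot(inherits(P, "synton_partition"), inherits(graph, "layered_graph"))
  pm <- graph$pairs
  if (nrow(pm) == 0L)
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      max_size = integer(0)))
  gene_sets <- lapply(P, function(s)
    unique(unlist(lapply(s$spines, spine_cover))))
  sizes <- vapply(P, function(s) length(s$spines), integer(1))
  max_size <- vapply(seq_len(nrow(pm)), function(r) {
    has <- vapply(gene_sets, function(gs)
      pm[r, 1L] %in% gs && pm[r, 2L] %in% gs, logical(1))
    if (any(has)) max(sizes[has]) else 0L
  }, integer(1))
  out <- data.frame(gene1 = pm[, 1L], gene2 = pm[, 2L], max_size = max_size,
                    stringsAsFactors = FALSE)
  if (!keep_zero) out <- out[out$max_size > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tabular synton report
#'
#' One row per synton: id, spine count, covered genomes, and per-genome gene
#' lists and rank spans (from [project_synton()]).
#'
#' @param P A `synton_partition`.
#' @param graph A [layered_graph()].
#' @return A data.frame.
#' @export
synton_report <- function(P, graph) {
  if (length(P) == 0L)
    return(data.frame(synton_id = integer(0), n_spines = integer(0),
                      cover = character(0), genome = character(0),
                      n_genes = integer(0), genes = character(0),
                      span_min = integer(0), span_max = integer(0),
                      n_gap = integer(0)))
  do.call(rbind, lapply(seq_along(P), function(k) {
    pr <- project_synton(P[[k]], graph)
    cbind(data.frame(synton_id = k, n_spines = length(P[[k]]$spines),
                     cover = paste(graph$genome_names[P[[k]]$cover],
                                   collapse = "+")),
          pr)
  }))
}

#' Write synton reports
#'
#' `write_synton_report()` writes the TSV of [synton_report()];
#' `write_synton_json()` writes a schema-versioned JSON mirror including the
#' member spines; `write_synton_bed()` writes a BED-like per-genome interval
#' export of the projections (1-based ranks, inclusive).
#'
#' @param P A `synton_partition`.
#' @param graph A [layered_graph()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_synton_report <- function(P, graph, path) {
  utils::write.table(synton_report(P, graph), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_synton_report
#' @export
write_synton_json <- function(P, graph, path) {
  obj <- list(
    schema = "synton-partition/1",
    quorum = attr(P, "q"),
    genomes = graph$genome_names,
    syntons = lapply(seq_along(P), function(k) {
      s <- P[[k]]
      list(id = k, n_spines = length(s$spines),
           cover = graph$genome_names[s$cover],
           spines = lapply(s$spines, function(sp)
             lapply(seq_along(sp), function(i)
               if (sp[i] == DC) NULL else slot_genes(sp[i]))))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_synton_report
#' @export
write_synton_bed <- function(P, graph, path) {
  rep <- synton_report(P, graph)
  if (nrow(rep) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = rep$genome, start = rep$span_min,
                    end = rep$span_max,
                    name = paste0("synton_", rep$synton_id))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
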