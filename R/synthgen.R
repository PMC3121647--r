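# Synthetic data: two small transcribed worked-example fixtures and a seeded
# generator of genomes + correspondence relation with planted, recoverable
# synteny blocks.

#' Worked-example fixtures
#'
#' Two tiny, fully specified instances used throughout the documentation and
#' tests. `"F1"` is a three-genome instance without don't-care slots
#' (quorum = n = 3): genomes `[a1, d1, b1, c1]`, `[a2, b2, c2]`,
#' `[a3, b3, c3]` and an 11-pair relation whose clique spines are
#' `(a1,a2,a3)`, `(b1,a2,a3)`, `(b1,b2,b3)`, `(c1,c2,c3)`; its partition has
#' two syntons (the singleton `{(a1,a2,a3)}` — cut off by the gap gene `d1` —
#' and the three remaining spines). `"F2"` is a quorum-2 instance: genomes
#' `[a1, b1]`, `[a2, b2]`, `[a3]` and relation
#' `{a1a2, a1a3, a2a3, b1b2}`, yielding five clique spines, four syntons
#' (the largest of two spines) and two maximal syntons.
#'
#' @param name `"F1"` or `"F2"`.
#' @return A list with elements `graph` (a [layered_graph()], `delta_gap = 1`),
#'   `q`, `aggregator`, `expected_spines` and `expected_partition` (the
#'   transcribed ground truth, built literally, not computed).
#' @export
otfq_fixture <- function(name = c("F1", "F2")) {
  name <- match.arg(name)
  if (name == "F1") {
    graph <- layered_graph(
      genomes = list(G1 = c("a1", "d1", "b1", "c1"),
                     G2 = c("a2", "b2", "c2"),
                     G3 = c("a3", "b3", "c3")),
      pairs = rbind(c("a1", "a2"), c("a1", "a3"), c("a2", "a3"),
                    c("b1", "a2"), c("b1", "a3"),
                    c("b1", "b2"), c("b1", "b3"), c("b2", "b3"),
                    c("c1", "c2"), c("c1", "c3"), c("c2", "c3")),
      delta_gap = 1L)
    q <- 3L
    spines <- list(c("a1", "a2", "a3"), c("b1", "a2", "a3"),
                   c("b1", "b2", "b3"), c("c1", "c2", "c3"))
    syntons <- list(
      list(spines = list(c("a1", "a2", "a3")), cover = 1:3),
      list(spines = list(c("b1", "a2", "a3"), c("b1", "b2", "b3"),
                         c("c1", "c2", "c3")), cover = 1:3))
  } else {
    graph <- layered_graph(
      genomes = list(G1 = c("a1", "b1"), G2 = c("a2", "b2"), G3 = "a3"),
      pairs = rbind(c("a1", "a2"), c("a1", "a3"), c("a2", "a3"),
                    c("b1", "b2")),
      delta_gap = 1L)
    q <- 2L
    spines <- list(c("a1", "a2", "a3"), c("a1", "a2", "*"),
                   c("a1", "*", "a3"), c("*", "a2", "a3"),
                   c("b1", "b2", "*"))
    syntons <- list(
      list(spines = list(c("a1", "a2", "a3")), cover = 1:3),
      list(spines = list(c("a1", "*", "a3")), cover = c(1L, 3L)),
      list(spines = list(c("*", "a2", "a3")), cover = 2:3),
      list(spines = list(c("a1", "a2", "*"), c("b1", "b2", "*")),
           cover = 1:2))
  }
  list(graph = graph, q = q, aggregator = aggregator("clique"),
       expected_spines = spines[order(vapply(spines, spine_key, character(1)))],
       expected_partition = new_partition(syntons, graph, q))
}

#' Configuration for the synthetic-instance generator
#'
#' Describes a set of background genomes with planted synteny blocks. Each
#' block is a set of gene families placed contiguously (optionally permuted
#' and interleaved with gap genes) on a subset of `block_genomes` genomes;
#' same-family genes across genomes are connected pairwise in the
#' correspondence relation. Edge dropout breaks transitivity (the relation is
#' then neither one-to-one nor transitive, as with thresholded sequence
#' similarity) and paralog copies create many-to-many correspondence.
#' Background genes carry globally unique family ids, so they can never join
#' a spine.
#'
#' @param n_genomes Number of genomes (`>= 2`).
#' @param genome_length Gene count per genome (scalar or vector).
#' @param n_blocks Number of planted blocks.
#' @param block_length Gene families per block (scalar or vector).
#' @param block_genomes Number of genomes carrying each block
#'   (scalar or vector, each `>= 2`).
#' @param permute Randomly permute the within-block gene order per genome?
#' @param gap_rate Probability of inserting one background gap gene after
#'   each within-block position, in `[0, 1]`.
#' @param dropout Probability of dropping each same-family correspondence
#'   edge, in `[0, 1]`.
#' @param paralog_rate Probability, per family, of adding one extra copy on a
#'   random carrier genome, in `[0, 1]`.
#' @param circular Circular flag for all genomes.
#' @param seed Mandatory integer seed; instances are fully reproducible.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_genomes = 3L, genome_length = 30L, n_blocks = 1L,
                         block_length = 5L, block_genomes = n_genomes,
                         permute = FALSE, gap_rate = 0, dropout = 0,
                         paralog_rate = 0, circular = FALSE, seed) {
  if (missing(seed) || !is.numeric(seed))
    stop_input("an integer seed is mandatory")
  for (r in c(gap_rate, dropout, paralog_rate)) {
    if (r < 0 || r > 1) stop_input("rates must lie in [0, 1]")
  }
  if (n_genomes < 2L) stop_input("need at least 2 genomes")
  if (any(block_genomes < 2L) || any(block_genomes > n_genomes))
    stop_input("block_genomes must lie in [2, n_genomes]")
  structure(list(n_genomes = as.integer(n_genomes),
                 genome_length = rep_len(as.integer(genome_length), n_genomes),
                 n_blocks = as.integer(n_blocks),
                 block_length = rep_len(as.integer(block_length),
                                        max(n_blocks, 1L)),
                 block_genomes = rep_len(as.integer(block_genomes),
                                         max(n_blocks, 1L)),
                 permute = isTRUE(permute), gap_rate = gap_rate,
                 dropout = dropout, paralog_rate = paralog_rate,
                 circular = isTRUE(circular), seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic instance with planted blocks
#'
#' Builds `n` genomes of background genes (unique families, no
#' correspondence) and plants the configured blocks: each block's gene
#' families are placed contiguously on its carrier genomes, in permuted order
#' when requested, with gap genes interleaved at `gap_rate`; blocks are
#' separated by at least three background genes so distinct blocks do not
#' merge at small gap radii. Same-family genes across genomes are connected
#' pairwise, minus dropout, plus paralog copies.
#'
#' @param cfg A [synth_config()].
#' @return A list with `genomes` (named list of gene-id vectors, rank order),
#'   `pairs` (two-column matrix), `blocks` (data.frame: `block`, `family`,
#'   `genome`, `gene` — the planted ground truth), `circular` and `config`.
#'   Build an analysis-ready graph with
#'   `layered_graph(x$genomes, x$pairs, delta_gap)`.
#' @examples
#' inst <- generate_instance(synth_config(n_genomes = 3, seed = 1))
#' g <- layered_graph(inst$genomes, inst$pairs, delta_gap = 1)
#' otfq_partition(g, q = 3)
#' @export
generate_instance <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(cfg$seed)

  sep <- 3L  # minimum background genes between planted segments
  n <- cfg$n_genomes
  # assign carriers per block
  carriers <- lapply(seq_len(cfg$n_blocks), function(b)
    sort(sample(n, cfg$block_genomes[b])))
  families <- lapply(seq_len(cfg$n_blocks), function(b)
    sprintf("B%dF%d", b, seq_len(cfg$block_length[b])))
  # paralog decisions: one extra copy of a family on one of its carriers
  paralog <- lapply(seq_len(cfg$n_blocks), function(b) {
    fams <- families[[b]]
    hit <- stats::runif(length(fams)) < cfg$paralog_rate
    if (!any(hit)) return(NULL)
    data.frame(family = fams[hit],
               genome = vapply(which(hit), function(i)
                 sample(carriers[[b]], 1L), integer(1)),
               stringsAsFactors = FALSE)
  })

  genomes <- vector("list", n)
  names(genomes) <- paste0("G", seq_len(n))
  blocks <- list()
  fam_members <- list()  # family -> gene ids

  for (g in seq_len(n)) {
    segs <- list()
    for (b in seq_len(cfg$n_blocks)) {
      if (!(g %in% carriers[[b]])) next
      fams <- families[[b]]
      if (cfg$permute) fams <- sample(fams)
      genes <- paste0(fams, "_g", g)
      # paralog copies ride inside the block segment
      pb <- paralog[[b]]
      if (!is.null(pb)) {
        extra <- pb$family[pb$genome == g]
        if (length(extra) > 0L) {
          pg <- paste0(extra, "_g", g, "p2")
          at <- sample(length(genes) + 1L, length(extra), replace = TRUE)
          for (e in seq_along(pg)) genes <- append(genes, pg[e], after = at[e] - 1L)
          fams <- c(fams, extra)
        }
      }
      # interleave gap genes (background) after each position but the last
      if (cfg$gap_rate > 0 && length(genes) > 1L) {
        out <- character(0)
        for (p in seq_along(genes)) {
          out <- c(out, genes[p])
          if (p < length(genes) && stats::runif(1) < cfg$gap_rate)
            out <- c(out, sprintf("GAP_b%d_g%d_p%d", b, g, p))
        }
        genes <- out
      }
      segs[[length(segs) + 1L]] <- genes
      blk_genes <- genes[!startsWith(genes, "GAP_")]
      blocks[[length(blocks) + 1L]] <- data.frame(
        block = b, family = sub("_g.*$", "", blk_genes), genome = g,
        gene = blk_genes, stringsAsFactors = FALSE)
      for (fg in blk_genes) {
        fam <- sub("_g.*$", "", fg)
        fam_members[[fam]] <- c(fam_members[[fam]], fg)
      }
    }
    seg_len <- sum(lengths(segs))
    n_bg <- cfg$genome_length[g] - seg_len
    need <- sep * (length(segs) + 1L)
    if (n_bg < need)
      stop_input("genome %d too short (%d) for its blocks (need >= %d genes)",
                 g, cfg$genome_length[g], seg_len + need)
    bg <- sprintf("BG_g%d_%03d", g, seq_len(n_bg))
    # distribute background genes into the len(segs)+1 slots, >= sep each
    nslot <- length(segs) + 1L
    extra_bg <- n_bg - sep * nslot
    add <- if (nslot == 1L) extra_bg else
      stats::rmultinom(1L, extra_bg, rep(1, nslot))[, 1L]
    sizes <- sep + add
    seq_genes <- character(0)
    used <- 0L
    for (s in seq_len(nslot)) {
      seq_genes <- c(seq_genes, bg[used + seq_len(sizes[s])])
      used <- used + sizes[s]
      if (s <= length(segs)) seq_genes <- c(seq_genes, segs[[s]])
    }
    genomes[[g]] <- seq_genes
  }

  # correspondence: all inter-genome same-family pairs, minus dropout
  p1 <- character(0); p2 <- character(0)
  genome_of_gene <- function(id) as.integer(sub("^.*_g(\\d+).*$", "\\1", id))
  for (fam in names(fam_members)) {
    mem <- fam_members[[fam]]
    if (length(mem) < 2L) next
    cmb <- utils::combn(mem, 2L)
    inter <- genome_of_gene(cmb[1L, ]) != genome_of_gene(cmb[2L, ])
    cmb <- cmb[, inter, drop = FALSE]
    if (ncol(cmb) == 0L) next
    keep <- stats::runif(ncol(cmb)) >= cfg$dropout
    p1 <- c(p1, cmb[1L, keep]); p2 <- c(p2, cmb[2L, keep])
  }
  pairs <- if (length(p1) > 0L) canonical_pairs(p1, p2) else
    cbind(gene1 = character(0), gene2 = character(0))

  blocks_df <- if (length(blocks) > 0L) do.call(rbind, blocks) else
    data.frame(block = integer(0), family = character(0),
               genome = integer(0), gene = character(0))
  list(genomes = genomes, pairs = pairs, blocks = blocks_df,
       circular = cfg$circular, config = cfg)
}
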