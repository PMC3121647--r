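# Random-instance plumbing shared by the property and equivalence suites.

# Erdős–Rényi style instance: n genomes of random length, each cross-genome
# gene pair related independently with the sampled density. Returns the
# drawn engine parameters alongside the graph inputs.
random_instance <- function(seed, n_range = 2:4, len_range = 8:30,
                            density_range = c(0.02, 0.3),
                            delta_choices = 1:3, circular_prob = 0.2) {
  set.seed(seed)
  n <- if (length(n_range) == 1L) n_range else sample(n_range, 1L)
  lens <- sample(len_range, n, replace = TRUE)
  density <- runif(1, density_range[1L], density_range[2L])
  delta <- if (length(delta_choices) == 1L) delta_choices else
    sample(delta_choices, 1L)
  q <- if (n == 2L) 2L else sample(2:n, 1L)
  circular <- runif(n) < circular_prob
  genomes <- lapply(seq_len(n), function(i)
    sprintf("g%d_%02d", i, seq_len(lens[i])))
  names(genomes) <- paste0("G", seq_len(n))
  ids <- unlist(genomes, use.names = FALSE)
  gmem <- rep(seq_len(n), lens)
  cross <- which(outer(gmem, gmem, "<") & outer(gmem, gmem, "!="),
                 arr.ind = TRUE)
  keep <- runif(nrow(cross)) < density
  pairs <- if (any(keep)) {
    cbind(ids[cross[keep, 1L]], ids[cross[keep, 2L]])
  } else NULL
  list(genomes = genomes, pairs = pairs, delta = delta, q = q, n = n,
       circular = circular)
}

instance_graph <- function(inst) {
  layered_graph(inst$genomes, inst$pairs, delta_gap = inst$delta,
                circular = inst$circular)
}

sample_aggregator <- function(seed) {
  set.seed(seed + 7L)
  mode <- sample(c("clique", "cc", "quasi"), 1L)
  if (mode == "quasi") {
    aggregator("quasi", gamma = sample(c(0.4, 0.5, 2 / 3, 0.8), 1L))
  } else {
    aggregator(mode)
  }
}

# canonical content signature of a partition / synton list: order-free,
# attribute-free, faithful for comparisons between engine and oracle
partition_sig <- function(P) {
  sort(vapply(P, function(s) {
    keys <- sort(vapply(s$spines, function(sp) paste(sp, collapse = "|"),
                        character(1)))
    paste(keys, collapse = ";")
  }, character(1)))
}

# spines identified by their covered gene sets (faithful: a spine is
# determined by its genes, slots follow from gene->genome membership);
# used for genome-order invariance
partition_gene_sig <- function(P) {
  sort(vapply(P, function(s) {
    keys <- sort(vapply(s$spines, function(sp)
      paste(sort(spine_cover(sp)), collapse = ","), character(1)))
    paste(keys, collapse = ";")
  }, character(1)))
}

oracle_of <- function(graph, agg, q) {
  oracle_partition(build_pnam(enumerate_spines(graph, agg, q), graph), q)
}
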