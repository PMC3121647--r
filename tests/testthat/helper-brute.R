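# Fully independent brute-force spine enumeration used to cross-check
# enumerate_spines(): exhaustive product over (genes-of-layer union
# don't-care) with a direct check of the quorum and aggregation clauses
# against the raw pair list. No package graph machinery beyond the inputs.
# Only for tiny instances.

brute_force_spines <- function(genomes, pairs, q, mode = "clique",
                               gamma = 1) {
  n <- length(genomes)
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "~")
  rel <- if (is.null(pairs) || nrow(pairs) == 0L) character(0) else
    pair_key(pairs[, 1L], pairs[, 2L])
  related <- function(a, b) pair_key(a, b) %in% rel
  out <- list()
  choices <- lapply(genomes, function(g) c("*", g))
  grid <- do.call(expand.grid, c(choices, stringsAsFactors = FALSE))
  for (r in seq_len(nrow(grid))) {
    tup <- as.character(grid[r, ])
    genes <- tup[tup != "*"]
    k <- length(genes)
    if (k < q) next
    ok <- if (mode == "cc") {
      # connectivity by naive closure over the related() predicate
      reached <- genes[1L]
      repeat {
        add <- genes[!genes %in% reached &
                       vapply(genes, function(x)
                         any(vapply(reached, function(y) related(x, y),
                                    logical(1))), logical(1))]
        if (length(add) == 0L) break
        reached <- c(reached, add)
      }
      length(reached) == k
    } else {
      all(vapply(genes, function(x)
        sum(vapply(setdiff(genes, x), function(y) related(x, y),
                   logical(1))) >= gamma * (k - 1L) - 1e-9, logical(1)))
    }
    if (ok) out[[length(out) + 1L]] <- tup
  }
  out
}
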