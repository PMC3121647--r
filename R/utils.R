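# Internal helpers: condition constructors and rank arithmetic.

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("synton_input_error", "synton_error")))
}

stop_resource <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("synton_resource_error", "synton_error")))
}

stop_internal <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("synton_internal_error", "synton_error")))
}

stop_usage <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("synton_usage_error", "synton_error")))
}

#' @importFrom stats setNames
NULL

# Distance between two ranks on one chromosome; wraps around for circular
# genomes (L = number of rank positions on the chromosome).
rank_distance <- function(r1, r2, L, circular) {
  d <- abs(r1 - r2)
  if (circular) pmin(d, L - d) else d
}

# Connected components of a set of "members", each occupying one or more rank
# positions on the same chromosome, under the interval rule (two members are
# adjacent when some pair of their ranks is <= delta apart; a shared rank
# counts, distance 0). Only occupied ranks matter: consecutive occupied ranks
# at distance <= delta chain their members together, which is exactly graph
# connectivity under the member-adjacency relation.
# ranks_list: list of non-empty integer vectors. Returns integer component ids.
components_by_rank <- function(ranks_list, L, circular, delta) {
  m <- length(ranks_list)
  if (m == 0L) return(integer(0))
  all_ranks <- sort(unique(unlist(ranks_list)))
  nr <- length(all_ranks)
  # cluster occupied ranks: break where the gap exceeds delta
  if (nr == 1L) {
    cluster <- 1L
  } else {
    brk <- c(FALSE, diff(all_ranks) > delta)
    cluster <- cumsum(brk) + 1L
  }
  ncl <- cluster[nr]
  # circular wrap: first and last occupied rank may be close around the origin
  if (circular && ncl > 1L && (all_ranks[1L] + L - all_ranks[nr]) <= delta) {
    cluster[cluster == ncl] <- 1L
    ncl <- max(cluster)
  }
  cluster_of_rank <- setNames(cluster, all_ranks)
  # union-find over clusters: a member spanning several clusters merges them
  parent <- seq_len(ncl)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  member_cl <- vector("list", m)
  for (k in seq_len(m)) {
    cls <- unique(unname(cluster_of_rank[as.character(ranks_list[[k]])]))
    member_cl[[k]] <- cls
    if (length(cls) > 1L) {
      r <- find(cls[1L])
      for (c2 in cls[-1L]) {
        r2 <- find(c2)
        if (r2 != r) parent[r2] <- r
      }
    }
  }
  roots <- vapply(seq_len(ncl), find, integer(1))
  comp_id <- match(roots, unique(roots))
  vapply(member_cl, function(cls) comp_id[cls[1L]], integer(1))
}

# canonical two-column character matrix of unordered pairs, deduplicated
canonical_pairs <- function(g1, g2) {
  a <- pmin(g1, g2)
  b <- pmax(g1, g2)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  cbind(gene1 = a[keep], gene2 = b[keep])
}
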