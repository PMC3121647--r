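test_that("interval rule: strict adjacency, self-neighbourhood, circular wrap", {
  fx <- otfq_fixture("F1")
  # a1 (rank 1) and b1 (rank 3) are separated by the gap gene d1
  expect_false(interval_edge(fx$graph, "a1", "b1", delta_gap = 1))
  expect_true(interval_edge(fx$graph, "a1", "b1", delta_gap = 2))
  expect_true(interval_edge(fx$graph, "a1", "a1"))
  expect_error(interval_edge(fx$graph, "a1", "a2"),
               class = "synton_usage_error")

  circ <- layered_graph(
    list(G1 = sprintf("x%02d", 1:10), G2 = c("y1", "y2")),
    pairs = rbind(c("x01", "y1")), circular = c(TRUE, FALSE))
  expect_true(interval_edge(circ, "x01", "x10", delta_gap = 1))
  expect_false(interval_edge(circ, "x01", "x05", delta_gap = 3))
})

test_that("interval rule is symmetric and monotone in the gap radius", {
  set.seed(11)
  g <- layered_graph(list(G1 = sprintf("u%02d", 1:12),
                          G2 = sprintf("v%02d", 1:9)),
                     pairs = rbind(c("u01", "v01")),
                     circular = c(TRUE, FALSE))
  ids <- sprintf("u%02d", 1:12)
  for (rep in 1:50) {
    uv <- sample(ids, 2L)
    d1 <- sample(1:4, 1L)
    e <- interval_edge(g, uv[1L], uv[2L], delta_gap = d1)
    expect_identical(e, interval_edge(g, uv[2L], uv[1L], delta_gap = d1))
    if (e) expect_true(interval_edge(g, uv[1L], uv[2L], delta_gap = d1 + 1L))
  }
  # linear genome, delta = 1: the interval graph is a path with L - 1 edges
  lin <- layered_graph(list(G1 = sprintf("a%d", 1:7), G2 = "b1"),
                       pairs = rbind(c("a1", "b1")))
  cmb <- combn(sprintf("a%d", 1:7), 2L)
  n_edges <- sum(vapply(seq_len(ncol(cmb)), function(k)
    interval_edge(lin, cmb[1L, k], cmb[2L, k], delta_gap = 1), logical(1)))
  expect_identical(n_edges, 6L)
})

test_that("layered graph validates its inputs", {
  f1 <- otfq_fixture("F1")
  expect_identical(f1$graph$n, 3L)
  expect_identical(nrow(f1$graph$pairs), 11L)

  # empty relation is valid
  g0 <- layered_graph(list(G1 = c("a", "b"), G2 = c("c", "d")), NULL)
  expect_identical(nrow(g0$pairs), 0L)

  # symmetric duplicates collapse to a single pair
  g1 <- layered_graph(list(G1 = "a", G2 = "b"),
                      rbind(c("a", "b"), c("b", "a")))
  expect_identical(nrow(g1$pairs), 1L)

  expect_error(layered_graph(list(G1 = "a", G2 = "b"),
                             rbind(c("a", "zz"))),
               "zz", class = "synton_input_error")
  expect_error(layered_graph(data.frame(genome = c("G1", "G1", "G2"),
                                        gene = c("a", "b", "c"),
                                        rank = c(1, 1, 1)),
                             NULL),
               "duplicate rank", class = "synton_input_error")
  expect_error(layered_graph(list(G1 = c("a", "b"), G2 = "c"),
                             rbind(c("a", "b"))),
               "intra-genome", class = "synton_input_error")
  expect_error(layered_graph(list(G1 = "a"), NULL),
               class = "synton_input_error")
})

test_that("sparse ranks are accepted and dense ranks assigned from row order", {
  tab <- data.frame(genome = c("G1", "G1", "G2", "G2"),
                    gene = c("a", "b", "c", "d"),
                    rank = c(1L, 5L, 1L, 2L))
  g <- layered_graph(tab, NULL)
  expect_false(interval_edge(g, "a", "b", delta_gap = 1))
  expect_true(interval_edge(g, "a", "b", delta_gap = 4))

  tab2 <- data.frame(genome = c("G2", "G2", "G1"), gene = c("x", "y", "z"))
  g2 <- layered_graph(tab2, NULL)
  expect_identical(unname(g2$rank_of[c("x", "y", "z")]), c(1L, 2L, 1L))
})

test_that("BLAST pair filter applies the three thresholds on the smaller protein", {
  hit <- function(q, s, p, id, aln, ql, sl)
    data.frame(query_id = q, subject_id = s, p_value = p,
               percent_identity = id, alignment_length = aln,
               query_length = ql, subject_length = sl)
  hits <- rbind(
    hit("a", "b", 1e-12, 55.0, 90, 100, 120),  # kept: coverage 90/100 = 0.9
    hit("a", "c", 1e-12, 39.9, 100, 100, 100), # identity below 40
    hit("b", "c", 1e-09, 80.0, 100, 100, 100), # p-value above 1e-10
    hit("c", "d", 1e-12, 80.0, 70, 100, 90),   # coverage 70/90 < 0.8
    hit("d", "e", 1e-10, 40.0, 80, 100, 100))  # kept: all three at boundary
  pm <- filter_blast_pairs(hits)
  expect_identical(nrow(pm), 2L)
  expect_setequal(paste(pm[, 1L], pm[, 2L]), c("a b", "d e"))

  # invariant under swapping query and subject in every hit
  swapped <- hits[, c(2, 1, 3, 4, 5, 7, 6)]
  names(swapped) <- names(hits)
  expect_identical(filter_blast_pairs(swapped), pm)

  expect_identical(nrow(filter_blast_pairs(hits[0, ])), 0L)
  expect_error(filter_blast_pairs(hits, min_coverage = 0),
               class = "synton_input_error")
})

test_that("gene/pair/BLAST tables round-trip through the TSV readers", {
  fx <- otfq_fixture("F2")
  td <- withr::local_tempdir()
  write_gene_table(fx$graph, file.path(td, "genes.tsv"))
  write_pair_table(fx$graph$pairs, file.path(td, "pairs.tsv"))
  g2 <- layered_graph(read_gene_table(file.path(td, "genes.tsv")),
                      read_pair_table(file.path(td, "pairs.tsv")),
                      delta_gap = 1)
  expect_identical(g2$genes, fx$graph$genes)
  expect_identical(g2$pairs, fx$graph$pairs)

  blast <- data.frame(q = c("a1", "a1"), s = c("a2", "a3"),
                      id = c(60, 35), len = c(95, 95),
                      mm = 0, go = 0, qs = 1, qe = 95, ss = 1, se = 95,
                      e = c(1e-20, 1e-20), bits = 200)
  utils::write.table(blast, file.path(td, "hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(gene = c("a1", "a2", "a3"), length = 100),
                     file.path(td, "len.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hits <- read_blast_table(file.path(td, "hits.tsv"),
                           file.path(td, "len.tsv"))
  expect_identical(hits$query_length, c(100L, 100L))
  pm <- filter_blast_pairs(hits)
  expect_identical(unname(pm[, 1:2]), c("a1", "a2"))
})
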