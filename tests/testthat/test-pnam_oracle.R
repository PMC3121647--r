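f1 <- otfq_fixture("F1")
f2 <- otfq_fixture("F2")

test_that("colour edges follow the per-genome interval rule on slot genes", {
  g <- f1$graph
  # shared identical gene: distance 0 counts as adjacency
  expect_true(colour_edge(c("b1", "a2", "a3"), c("b1", "b2", "b3"), 1, g))
  # a2 and b2 are rank neighbours on the red genome
  expect_true(colour_edge(c("a1", "a2", "a3"), c("b1", "b2", "b3"), 2, g))
  # a1 and b1 are separated by the gap gene d1 on the blue genome
  expect_false(colour_edge(c("a1", "a2", "a3"), c("b1", "b2", "b3"), 1, g))
  # a don't-care slot never carries an edge
  expect_false(colour_edge(c("a1", "a2", "*"), c("a1", "*", "a3"), 3,
                           f2$graph))
})

test_that("the explicit PNAM materialises the expected colour edges", {
  sp1 <- enumerate_spines(f1$graph, aggregator("clique"), 3)
  pn1 <- build_pnam(sp1, f1$graph)
  key <- function(s) paste(s, collapse = "|")
  keys <- vapply(pn1$spines, key, character(1))
  has_edge <- function(pn, i, a, b) {
    ia <- match(key(a), keys); ib <- match(key(b), keys)
    el <- pn$edges[[i]]
    any((el[, 1L] == ia & el[, 2L] == ib) |
          (el[, 1L] == ib & el[, 2L] == ia))
  }
  # b1/c1 at ranks 3 and 4: blue edge between the b- and c-spines
  expect_true(has_edge(pn1, 1, c("b1", "b2", "b3"), c("c1", "c2", "c3")))
  expect_false(has_edge(pn1, 1, c("a1", "a2", "a3"), c("b1", "b2", "b3")))

  sp2 <- enumerate_spines(f2$graph, aggregator("clique"), 2)
  pn2 <- build_pnam(sp2, f2$graph)
  # colour 3: exactly the three spines covered at layer 3, sharing a3,
  # pairwise connected -> 3 edges
  expect_identical(nrow(pn2$edges[[3L]]), 3L)
  covered3 <- vapply(pn2$spines, function(s) s[3L] != "*", logical(1))
  expect_identical(sum(covered3), 3L)

  pn_single <- build_pnam(list(c("a1", "a2", "a3")), f2$graph)
  expect_identical(sum(vapply(pn_single$edges, nrow, integer(1))), 0L)
})

test_that("the oracle partition reproduces the worked examples", {
  p1 <- oracle_of(f1$graph, aggregator("clique"), 3)
  expect_length(p1, 2L)
  expect_identical(partition_sig(p1), partition_sig(f1$expected_partition))

  p2 <- oracle_of(f2$graph, aggregator("clique"), 2)
  expect_length(p2, 4L)
  expect_identical(partition_sig(p2), partition_sig(f2$expected_partition))
  covers <- lapply(p2, `[[`, "cover")
  expect_setequal(vapply(covers, paste, character(1), collapse = ","),
                  c("1,2,3", "1,3", "2,3", "1,2"))
  sizes <- vapply(p2, function(s) length(s$spines), integer(1))
  expect_identical(sort(sizes), c(1L, 1L, 1L, 2L))

  pn_single <- build_pnam(list(c("a1", "a2", "a3")), f2$graph)
  expect_length(oracle_partition(pn_single, 2), 1L)
})

test_that("is_synton checks cover uniformity, connectivity and maximality", {
  sp2 <- enumerate_spines(f2$graph, aggregator("clique"), 2)
  pn2 <- build_pnam(sp2, f2$graph)
  expect_true(is_synton(list(c("a1", "a2", "*"), c("b1", "b2", "*")),
                        pn2, 2))
  # not maximal: the b-spine can be added
  expect_false(is_synton(list(c("a1", "a2", "*")), pn2, 2))
  # mixed covers are rejected
  expect_false(is_synton(list(c("a1", "a2", "a3"), c("a1", "a2", "*")),
                         pn2, 2))
  expect_true(is_synton(list(c("a1", "a2", "a3")), pn2, 2))
})

test_that("every oracle part is a synton and the parts tile the PNAM", {
  for (seed in 21:28) {
    inst <- random_instance(seed, n_range = 2:3, len_range = 5:10)
    graph <- instance_graph(inst)
    agg <- sample_aggregator(seed)
    sp <- enumerate_spines(graph, agg, inst$q)
    if (length(sp) == 0L) next
    pn <- build_pnam(sp, graph)
    part <- oracle_partition(pn, inst$q)
    all_keys <- unlist(lapply(part, function(s)
      vapply(s$spines, paste, character(1), collapse = "|")))
    expect_identical(sort(all_keys),
                     sort(vapply(sp, paste, character(1), collapse = "|")))
    expect_false(anyDuplicated(all_keys) > 0L)
    for (s in part) expect_true(is_synton(s$spines, pn, inst$q))
  }
})

test_that("refinement is order-independent", {
  for (seed in 29:48) {
    inst <- random_instance(seed, n_range = 2:3, len_range = 5:12)
    graph <- instance_graph(inst)
    agg <- sample_aggregator(seed)
    sp <- enumerate_spines(graph, agg, inst$q)
    if (length(sp) < 2L) next
    pn <- build_pnam(sp, graph)
    covers <- lapply(pn$spines, spine_layers)
    sig0 <- partition_sig(oracle_partition(pn, inst$q))
    # refine each cover group with a random colour and part order
    set.seed(seed * 1000L)
    groups <- split(seq_along(pn$spines),
                    vapply(covers, paste, character(1), collapse = ","))
    syn <- list()
    for (idx in groups[sample.int(length(groups))]) {
      I <- covers[[idx[1L]]]
      I <- I[sample.int(length(I))]
      parts <- synton:::refine_parts(idx[sample.int(length(idx))], I,
                                     function(part, i)
        synton:::pnam_colour_components(pn, part, i))
      for (part in parts)
        syn[[length(syn) + 1L]] <- list(spines = pn$spines[part],
                                        cover = covers[[idx[1L]]])
    }
    expect_identical(partition_sig(syn), sig0)
  }
})

test_that("raising the gap radius only coarsens the partition within cover groups", {
  for (seed in 49:60) {
    inst <- random_instance(seed, n_range = 2:3, len_range = 6:14,
                            delta_choices = 1:2)
    agg <- sample_aggregator(seed)
    graphs <- lapply(c(inst$delta, inst$delta + 1L), function(d)
      layered_graph(inst$genomes, inst$pairs, delta_gap = d,
                    circular = inst$circular))
    sp <- enumerate_spines(graphs[[1L]], agg, inst$q)
    if (length(sp) == 0L) next
    parts <- lapply(graphs, function(g)
      oracle_partition(build_pnam(sp, g), inst$q))
    sets <- lapply(parts, function(p) lapply(p, function(s)
      sort(vapply(s$spines, paste, character(1), collapse = "|"))))
    for (small in sets[[1L]]) {
      expect_true(any(vapply(sets[[2L]], function(big)
        all(small %in% big), logical(1))))
    }
  }
})
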