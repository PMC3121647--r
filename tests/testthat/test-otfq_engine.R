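f1 <- otfq_fixture("F1")
f2 <- otfq_fixture("F2")

test_that("initialisation: one class per first-genome component plus the don't-care class", {
  cl1 <- initialize_classes(f1$graph, engine_config(q = 3L))
  # blue genome is a single rank chain; q = n, so no don't-care class
  expect_length(cl1, 1L)
  expect_length(cl1[[1L]]$members, 4L)

  cl2 <- initialize_classes(f2$graph, engine_config(q = 2L))
  expect_length(cl2, 2L)
  expect_setequal(unlist(cl2[[1L]]$members), c("a1", "b1"))
  expect_identical(cl2[[2L]]$members, list("*"))

  sparse <- layered_graph(
    data.frame(genome = c("G1", "G1", "G2"), gene = c("x", "y", "z"),
               rank = c(1L, 5L, 1L)),
    rbind(c("x", "z")))
  cls <- initialize_classes(sparse, engine_config(q = 2L))
  expect_length(cls, 2L)  # ranks 1 and 5 are disconnected at delta_gap = 1
})

test_that("split keeps colour-connected members together and replicates don't-cares", {
  cfg <- engine_config(q = 2L)
  C <- list(layer = 2L,
            members = list(c("a1", "a2"), c("b1", "b2"), c("*", "a2")))
  expect_length(split_class(C, f2$graph, cfg), 1L)  # stable

  far <- layered_graph(
    data.frame(genome = c("G1", "G1", "G2"), gene = c("x", "y", "z"),
               rank = c(1L, 5L, 1L)),
    rbind(c("x", "z"), c("y", "z")))
  Cf <- list(layer = 1L, members = list("x", "y"))
  expect_length(split_class(Cf, far, engine_config(q = 2L)), 2L)

  expect_length(split_class(list(layer = 1L, members = list("x")), far,
                            engine_config(q = 2L)), 1L)

  # a member with a don't-care at the splitting colour goes to every branch
  g <- layered_graph(
    data.frame(genome = c(rep("G1", 4), "G2", "G2"),
               gene = c("u1", "u2", "v1", "v2", "w1", "w2"),
               rank = c(1L, 2L, 6L, 7L, 1L, 2L)),
    rbind(c("u1", "w1"), c("v1", "w1")))
  Cd <- list(layer = 1L, members = list("u1", "v1", "*"))
  parts <- split_class(Cd, g, engine_config(q = 2L))
  expect_length(parts, 2L)
  for (p in parts)
    expect_true(any(vapply(p$members, identical, logical(1), "*")))
})

test_that("expand adds terminals and budget-limited don't-cares", {
  cfg <- engine_config(q = 2L)
  C <- list(layer = 2L, members = list(c("a1", "a2")))
  NC <- expand_class(C, f2$graph, cfg)
  expect_setequal(vapply(NC$members, paste, character(1), collapse = "|"),
                  c("a1|a2|a3", "a1|a2|*"))

  # no gene of G3 is related to both b1 and b2: only the don't-care branch
  NCb <- expand_class(list(layer = 2L, members = list(c("b1", "b2"))),
                      f2$graph, cfg)
  expect_identical(vapply(NCb$members, paste, character(1), collapse = "|"),
                   "b1|b2|*")

  # budget exhausted and no terminal: the member dies
  NCd <- expand_class(list(layer = 2L, members = list(c("b1", "*"))),
                      f2$graph, cfg)
  expect_length(NCd$members, 0L)
})

test_that("the engine reproduces the worked examples and the size filter", {
  p1 <- otfq_partition(f1$graph, q = 3)
  expect_length(p1, 2L)
  expect_identical(partition_sig(p1), partition_sig(f1$expected_partition))

  p2 <- otfq_partition(f2$graph, q = 2)
  expect_length(p2, 4L)
  expect_identical(partition_sig(p2), partition_sig(f2$expected_partition))

  p2b <- otfq_partition(f2$graph, q = 2, min_size = 2)
  expect_length(p2b, 1L)
  expect_length(p2b[[1L]]$spines, 2L)
})

test_that("engine equals oracle on random instances in all aggregation modes", {
  for (seed in 101:160) {
    inst <- random_instance(seed)
    graph <- instance_graph(inst)
    agg <- sample_aggregator(seed)
    eng <- otfq_partition(graph, q = inst$q, aggregator = agg)
    ora <- oracle_of(graph, agg, inst$q)
    expect_identical(partition_sig(eng), partition_sig(ora),
                     label = sprintf("engine sig (seed %d, mode %s)",
                                     seed, agg$mode))
  }
})

test_that("the result does not depend on the genome input order", {
  for (seed in 161:172) {
    inst <- random_instance(seed, len_range = 6:15)
    agg <- sample_aggregator(seed)
    g0 <- instance_graph(inst)
    p0 <- partition_gene_sig(otfq_partition(g0, q = inst$q, aggregator = agg))
    set.seed(seed + 5000L)
    perm <- sample(inst$n)
    g1 <- layered_graph(inst$genomes[perm],
                        if (nrow(g0$pairs) > 0L) g0$pairs else NULL,
                        delta_gap = inst$delta,
                        circular = inst$circular[perm])
    p1 <- partition_gene_sig(otfq_partition(g1, q = inst$q, aggregator = agg))
    expect_identical(p1, p0)
  }
})

test_that("identical inputs give byte-identical canonical output", {
  inst <- random_instance(4242)
  graph <- instance_graph(inst)
  r1 <- otfq_partition(graph, q = inst$q)
  r2 <- otfq_partition(graph, q = inst$q)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
})

test_that("the live-spine cap raises a resource error", {
  inst <- random_instance(77, n_range = 4, len_range = 20:25,
                          density_range = c(0.25, 0.3))
  graph <- instance_graph(inst)
  expect_error(otfq_partition(graph, q = 2, spine_cap = 10),
               "quorum", class = "synton_resource_error")
})

test_that("invalid quorum or sizes are rejected", {
  expect_error(otfq_partition(f2$graph, q = 1), class = "synton_input_error")
  expect_error(otfq_partition(f2$graph, q = 4), class = "synton_input_error")
  expect_error(engine_config(min_size = 0), class = "synton_input_error")
})
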