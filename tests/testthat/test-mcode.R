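# MCODE-style vertex weighting, module growth, filtering and collapse.

two_k5_bridge <- function() {
  a <- combn(paste0("a", 1:5), 2)
  b <- combn(paste0("b", 1:5), 2)
  make_network(c(a[1, ], b[1, ], "a1"), c(a[2, ], b[2, ], "b1"))
}

test_that("vertex weights follow the k-core density rule", {
  w <- mcode_weights(complete_graph(5))
  expect_equal(unname(w), rep(4, 5))  # density 1 x core 4
  # star hub: only a 1-core; density of the whole closed neighborhood
  s4 <- star_graph(4)
  w_s <- mcode_weights(s4, degree_cutoff = 0)
  expect_equal(unname(w_s["hub"]), 1 * (2 * 4) / (5 * 4))
  # isolated node scores 0
  g <- make_network(c("a"), c("b"), nodes = "iso")
  expect_equal(unname(mcode_weights(g)["iso"]), 0)
  # default degree cutoff zeroes low-degree nodes (the leaves, not the hub)
  w_def <- mcode_weights(s4)
  expect_equal(unname(w_def["leaf1"]), 0)
  expect_equal(unname(w_def["hub"]), 0.4)
})

test_that("two bridged K5s yield exactly two K5 modules", {
  ms <- mcode_find(two_k5_bridge())
  expect_length(ms$modules, 2L)
  expect_setequal(ms$modules[[1]]$nodes, paste0("a", 1:5))
  expect_setequal(ms$modules[[2]]$nodes, paste0("b", 1:5))
  expect_equal(ms$modules[[1]]$score, 5)  # density 1 x size 5
})

test_that("an edgeless graph has no modules; disjoint cliques return the cliques", {
  empty <- make_network(character(0), character(0), nodes = letters[1:4])
  expect_length(mcode_find(empty)$modules, 0L)
  x <- combn(paste0("x", 1:4), 2)
  y <- combn(paste0("y", 1:5), 2)
  g <- make_network(c(x[1, ], y[1, ]), c(x[2, ], y[2, ]))
  ms <- mcode_find(g)
  got <- lapply(ms$modules, `[[`, "nodes")
  expect_length(got, 2L)
  expect_setequal(got[[which(lengths(got) == 4)]], paste0("x", 1:4))
  expect_setequal(got[[which(lengths(got) == 5)]], paste0("y", 1:5))
})

test_that("module detection is deterministic", {
  pn <- gen_planted_modules(4, 6, 3, seed = 9)
  ms1 <- mcode_find(pn$network)
  ms2 <- mcode_find(pn$network)
  expect_identical(lapply(ms1$modules, `[[`, "nodes"),
                   lapply(ms2$modules, `[[`, "nodes"))
})

test_that("planted clique communities are recovered exactly", {
  pn <- gen_planted_modules(3, 6, 2, seed = 7)
  ms <- mcode_find(pn$network)
  got <- lapply(ms$modules, `[[`, "nodes")
  expect_length(got, 3L)
  truth_keys <- sort(vapply(pn$modules_truth,
                            function(x) paste(sort(x), collapse = ","),
                            character(1)))
  got_keys <- sort(vapply(got, function(x) paste(x, collapse = ","),
                          character(1)))
  expect_identical(got_keys, truth_keys)
})

test_that("size filtering is strict and recorded", {
  ms <- structure(list(modules = list(
    list(nodes = paste0("a", 1:5), score = 5),
    list(nodes = paste0("b", 1:4), score = 4),
    list(nodes = paste0("c", 1:3), score = 3),
    list(nodes = paste0("d", 1:2), score = 2)),
    params = list(), min_size_applied = NULL), class = "module_set")
  f <- filter_modules(ms, 3)
  expect_length(f$modules, 2L)
  expect_equal(f$min_size_applied, 3L)
  expect_length(filter_modules(ms, 0)$modules, 4L)
})

test_that("collapse aggregates cross-group edges and conserves counts", {
  # module {a, b}, outside node c, edges a-c and b-c
  g <- make_network(c("a", "a", "b"), c("b", "c", "c"))
  ms <- structure(list(modules = list(list(nodes = c("a", "b"), score = 1)),
                       params = list(), min_size_applied = NULL),
                  class = "module_set")
  cg <- collapse_modules(g, ms)
  expect_setequal(igraph::V(cg)$name, c("M01", "c"))
  expect_equal(igraph::E(cg)$weight, 2L)
  expect_equal(igraph::V(cg)$node_weight[igraph::V(cg)$name == "M01"], 2L)

  # two modules with 3 cross edges
  g2 <- make_network(c("a1", "a1", "a2", "a1", "a2", "a1"),
                     c("a2", "a3", "a3", "b1", "b2", "b2"))
  g2 <- igraph::add_edges(g2, c("b1", "b2"))
  ms2 <- structure(list(modules = list(
    list(nodes = c("a1", "a2", "a3"), score = 3),
    list(nodes = c("b1", "b2"), score = 1)),
    params = list(), min_size_applied = NULL), class = "module_set")
  cg2 <- collapse_modules(g2, ms2)
  expect_equal(sum(igraph::E(cg2)$weight), 3L)

  # intra-module edges only: collapsed graph edgeless
  g3 <- complete_graph(4)
  ms3 <- structure(list(modules = list(
    list(nodes = igraph::V(g3)$name, score = 4)),
    params = list(), min_size_applied = NULL), class = "module_set")
  expect_equal(igraph::ecount(collapse_modules(g3, ms3)), 0L)
})

test_that("collapse conserves total edge count (cross + intra)", {
  pn <- gen_planted_modules(3, 6, 2, seed = 11)
  ms <- mcode_find(pn$network)
  cg <- collapse_modules(pn$network, ms)
  intra <- sum(vapply(ms$modules, function(m)
    igraph::ecount(igraph::induced_subgraph(pn$network, m$nodes)),
    numeric(1)))
  expect_equal(sum(igraph::E(cg)$weight) + intra,
               igraph::ecount(pn$network))
})

test_that("restrict_to keeps outside nodes as singletons", {
  g <- two_k5_bridge()
  ms <- mcode_find(g)
  cg <- collapse_modules(g, ms, restrict_to = paste0("a", 1:5))
  # only the a-clique collapses; b nodes stay singleton
  expect_true("M01" %in% igraph::V(cg)$name ||
                "M02" %in% igraph::V(cg)$name)
  expect_true(all(paste0("b", 1:5) %in% igraph::V(cg)$name))
})
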