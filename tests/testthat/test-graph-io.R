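# Edge-list loading, the network invariants, and the basic topology metrics.

write_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("score thresholding keeps exactly the qualifying edges", {
  path <- write_lines(c("A\tB\t0.9", "A\tC\t0.3", "B\tC\t0.5"))
  net <- read_scored_edges(path, score_min = 0.4)
  expect_equal(igraph::ecount(net), 2L)
  expect_setequal(igraph::V(net)$name, c("A", "B", "C"))
  expect_false(igraph::are_adjacent(net, "A", "C"))
})

test_that("STRING integer scores are rescaled and duplicates merged on max", {
  path <- write_lines(c("A\tB\t900", "A\tB\t700"))
  net <- read_scored_edges(path, score_min = 0.4)
  expect_equal(igraph::ecount(net), 1L)
  expect_equal(igraph::E(net)$score, 0.9)
})

test_that("self-loops are dropped but their node is retained", {
  path <- write_lines(c("A\tA\t0.9", "B\tC\t0.8"))
  net <- read_scored_edges(path)
  expect_setequal(igraph::V(net)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(net), 1L)
})

test_that("header lines are skipped and score-free files load fully", {
  path <- write_lines(c("node1\tnode2\tcombined_score", "A\tB\t0.9"))
  expect_equal(igraph::ecount(read_scored_edges(path)), 1L)
  path2 <- write_lines(c("A\tB", "B\tC"))
  expect_equal(igraph::ecount(read_scored_edges(path2)), 2L)
})

test_that("malformed lines and bad score_min raise informative errors", {
  path <- write_lines(c("A\tB\t0.9", "orphan"))
  expect_error(read_scored_edges(path), "line 2")
  path2 <- write_lines(c("A\tB\t0.9", "B\tC\tnot_a_number"))
  expect_error(read_scored_edges(path2), "line 2")
  path3 <- write_lines("A\tB\t0.9")
  expect_error(read_scored_edges(path3, score_min = 1.4), "score_min")
})

test_that("writing then reloading an edge list round-trips the network", {
  path <- write_lines(c("A\tB\t0.9", "B\tC\t0.6", "C\tD\t0.41"))
  net <- read_scored_edges(path)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_scored_edges(net, out)
  net2 <- read_scored_edges(out)
  expect_setequal(igraph::V(net2)$name, igraph::V(net)$name)
  el <- function(g) {
    e <- igraph::as_edgelist(g)
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_identical(el(net2), el(net))
  expect_equal(sort(igraph::E(net2)$score), sort(igraph::E(net)$score))
})

test_that("clustering matches the closed forms on cliques and stars", {
  expect_equal(unname(node_clustering(complete_graph(3))), rep(1, 3))
  cc <- node_clustering(star_graph(4))
  expect_equal(unname(cc["hub"]), 0)
  g <- make_network(c("a", "a", "b", "a"), c("b", "c", "c", "d"))
  cc <- node_clustering(g)
  expect_equal(unname(cc["a"]), 1 / 3)
  expect_equal(mean(cc), mean(c(1 / 3, 1, 1, 0)))
})

test_that("path length and efficiency match hand enumeration", {
  expect_equal(average_path_length(path_graph(3)), 4 / 3)
  expect_equal(average_path_length(complete_graph(4)), 1)
  expect_equal(global_efficiency(complete_graph(3)), 1)
  expect_equal(global_efficiency(path_graph(3)), (1 + 1 + 0.5) / 3)
  disjoint <- make_network(c("a", "c"), c("b", "d"))
  expect_equal(global_efficiency(disjoint), 1 / 3)
  expect_warning(apl <- average_path_length(make_network(character(0),
                                                         character(0),
                                                         nodes = c("a", "b"))),
                 "undefined")
  expect_true(is.na(apl))
})

test_that("path metrics equal the all-pairs brute-force oracle on random graphs", {
  for (s in 1:12) {
    g <- random_test_graph(n = 5L + (s %% 6L), p = 0.35, seed = 200 + s)
    A <- oracle_adjacency(g)
    oa <- oracle_apl(A)
    if (is.na(oa)) {
      expect_warning(expect_true(is.na(average_path_length(g))))
    } else {
      expect_equal(average_path_length(g), oa)
    }
    expect_equal(global_efficiency(g), oracle_efficiency(A))
    expect_equal(node_clustering(g), oracle_clustering(A))
  }
})

test_that("efficiency is 1 iff complete; clustering 1 on clique unions", {
  expect_equal(global_efficiency(complete_graph(5)), 1)
  g <- make_network(c("a", "b"), c("b", "c"))
  expect_lt(global_efficiency(g), 1)
  two_cliques <- make_network(
    c(combn(paste0("x", 1:3), 2)[1, ], combn(paste0("y", 1:4), 2)[1, ]),
    c(combn(paste0("x", 1:3), 2)[2, ], combn(paste0("y", 1:4), 2)[2, ]))
  expect_equal(mean(node_clustering(two_cliques)), 1)
})

test_that("power-law fitting recovers generative exponents and rejects degenerate input", {
  pa <- gen_scale_free(2000, 3, seed = 4)
  fit <- fit_degree_powerlaw(igraph::degree(pa))
  expect_gt(fit$exponent, 2.3)
  expect_lt(fit$exponent, 3.6)
  expect_error(fit_degree_powerlaw(rep(5L, 50L)), "degenerate")
  expect_error(fit_degree_powerlaw(c(1L, 2L, 3L)), "degenerate")
  # exact discrete power-law sample, alpha = 2.5
  x <- withr::with_seed(10, floor(5 * (1 - runif(5000))^(-1 / 1.5)))
  fit2 <- fit_degree_powerlaw(x)
  expect_lt(abs(fit2$exponent - 2.5), 0.2)
  reg <- fit_degree_powerlaw(x, method = "regression")
  expect_identical(reg$method, "regression")
  expect_gt(reg$exponent, 1)
})

test_that("global_metrics assembles the summary fields", {
  g <- gen_scale_free(200, 3, seed = 2)
  gm <- global_metrics(g)
  expect_equal(gm$n_nodes, 200L)
  expect_equal(gm$n_edges, igraph::ecount(g))
  expect_gte(gm$avg_path_length, 1)
  expect_true(gm$avg_clustering >= 0 && gm$avg_clustering <= 1)
  expect_true(gm$global_efficiency >= 0 && gm$global_efficiency <= 1)
  expect_true(is.finite(gm$powerlaw_exponent))
})
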