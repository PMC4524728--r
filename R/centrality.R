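# Centrality battery: degree, closeness, betweenness, brokering, z-scores,
# multi-sigma central core and top-broker ranking.

#' Shortest-path betweenness
#'
#' Exact unnormalized betweenness (Brandes accumulation over all shortest
#' paths), counting each unordered node pair once.
#'
#' @param net An undirected `igraph` network.
#' @return Named numeric vector of pair counts.
#' @export
node_betweenness <- function(net) {
  assert_network(net)
  igraph::betweenness(net, directed = FALSE, normalized = FALSE,
                      weights = NA)
}

#' Closeness centrality (Wasserman-Faust)
#'
#' Within-component closeness scaled for disconnected networks:
#' `((n_c - 1) / (N - 1)) * ((n_c - 1) / sum(d))` where `n_c` is the size of
#' the node's component and the sum runs over its reachable nodes. Isolated
#' nodes score 0.
#'
#' @param net An undirected `igraph` network.
#' @return Named numeric vector in `[0, 1]`.
#' @export
node_closeness <- function(net) {
  assert_network(net)
  N <- igraph::vcount(net)
  out <- stats::setNames(numeric(N), igraph::V(net)$name)
  if (N < 2L) return(out)
  D <- igraph::distances(net, weights = NA)
  for (i in seq_len(N)) {
    d <- D[i, -i]
    reach <- d[is.finite(d)]
    n_c <- length(reach) + 1L
    if (n_c >= 2L)
      out[i] <- ((n_c - 1) / (N - 1)) * ((n_c - 1) / sum(reach))
  }
  out
}

#' Brokering coefficient
#'
#' `b_i = (k_i / (N - 1)) * (1 - C_i)`: rewards nodes combining high degree
#' with low local clustering, i.e. nodes that bridge otherwise unconnected
#' neighborhoods. The formula is the normalized-degree times
#' one-minus-clustering reading of the "broker" concept; nodes inside a
#' clique score 0 and a zero-clustering node scores its normalized degree.
#'
#' @param net An undirected `igraph` network with at least 2 nodes.
#' @return Named numeric vector in `[0, 1]`.
#' @export
brokering <- function(net) {
  assert_network(net)
  N <- igraph::vcount(net)
  if (N < 2L)
    stop("brokering needs at least 2 nodes", call. = FALSE)
  (igraph::degree(net) / (N - 1)) * (1 - node_clustering(net))
}

#' Per-node centrality table
#'
#' Degree, Wasserman-Faust closeness, unnormalized betweenness and brokering
#' for every node, with z-scores for the three centrality measures.
#' Standardization is computed over connected (degree > 0) nodes; isolated
#' nodes receive `NA` z-scores.
#'
#' @param net An undirected `igraph` network.
#' @return A `centrality_table` data frame: `node`, `degree`, `closeness`,
#'   `betweenness`, `brokering`, `z_degree`, `z_closeness`, `z_betweenness`.
#' @export
centrality_table <- function(net) {
  assert_network(net)
  deg <- igraph::degree(net)
  tab <- data.frame(
    node = igraph::V(net)$name,
    degree = unname(deg),
    closeness = unname(node_closeness(net)),
    betweenness = unname(node_betweenness(net)),
    brokering = if (igraph::vcount(net) >= 2L) unname(brokering(net))
                else rep(NA_real_, igraph::vcount(net)),
    stringsAsFactors = FALSE)
  connected <- tab$degree > 0L
  zscore <- function(x) {
    z <- rep(NA_real_, length(x))
    if (sum(connected) >= 2L) {
      s <- sd(x[connected])
      if (is.finite(s) && s > 0)
        z[connected] <- (x[connected] - mean(x[connected])) / s
    }
    z
  }
  tab$z_degree <- zscore(tab$degree)
  tab$z_closeness <- zscore(tab$closeness)
  tab$z_betweenness <- zscore(tab$betweenness)
  class(tab) <- c("centrality_table", "data.frame")
  tab
}

#' Multi-sigma central core
#'
#' Nodes whose z-scores exceed `sd_mult` on all three centrality measures
#' simultaneously (degree, closeness, betweenness). The conventional cutoff
#' is 3 standard deviations; 2 is also seen for more permissive cores.
#'
#' @param table A [centrality_table()].
#' @param sd_mult Standard-deviation multiplier (default 3).
#' @return Character vector of node names; empty (with a warning) when any
#'   z-column is degenerate.
#' @export
central_core <- function(table, sd_mult = 3) {
  if (!inherits(table, "centrality_table"))
    stop("`table` must be a centrality_table", call. = FALSE)
  z <- table[, c("z_degree", "z_closeness", "z_betweenness")]
  if (all(is.na(z$z_degree)) || all(is.na(z$z_closeness)) ||
      all(is.na(z$z_betweenness))) {
    warning("degenerate centrality column; central core undefined")
    return(character(0L))
  }
  ok <- !is.na(z$z_degree) & !is.na(z$z_closeness) & !is.na(z$z_betweenness) &
    z$z_degree > sd_mult & z$z_closeness > sd_mult & z$z_betweenness > sd_mult
  table$node[ok]
}

#' Top network brokers
#'
#' Nodes ranked by brokering coefficient (descending, ties broken
#' lexicographically by node name), after removing any exclusions.
#'
#' @param table A [centrality_table()].
#' @param n Number of brokers to return.
#' @param exclude Node names to drop before ranking (e.g. rich-club members).
#' @return Character vector of at most `n` node names.
#' @export
top_brokers <- function(table, n = 20L, exclude = character(0L)) {
  if (!inherits(table, "centrality_table"))
    stop("`table` must be a centrality_table", call. = FALSE)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  keep <- !(table$node %in% exclude) & !is.na(table$brokering)
  tab <- table[keep, , drop = FALSE]
  ord <- order(-tab$brokering, tab$node)
  head(tab$node[ord], n)
}
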