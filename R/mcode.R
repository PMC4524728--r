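# MCODE-style module detection: k-core vertex weighting, seeded growth,
# size filtering, and collapse into weighted supernode networks.

#' MCODE vertex weights
#'
#' For each node, the induced subgraph on its closed neighborhood is reduced
#' to its highest k-core; the weight is that core's density times its core
#' number (`k`). Nodes with degree below `degree_cutoff` are not scored
#' (weight 0), as are isolated nodes.
#'
#' @param net An undirected `igraph` network.
#' @param degree_cutoff Minimum degree for a node to receive a weight
#'   (default 2).
#' @return Named numeric vector of weights.
#' @export
mcode_weights <- function(net, degree_cutoff = 2L) {
  assert_network(net)
  nms <- igraph::V(net)$name
  deg <- igraph::degree(net)
  w <- stats::setNames(numeric(length(nms)), nms)
  adj <- igraph::as_adj_list(net)
  for (i in seq_along(nms)) {
    if (deg[i] < degree_cutoff) next
    nb <- c(i, as.integer(adj[[i]]))
    sub <- igraph::induced_subgraph(net, nb)
    cor <- igraph::coreness(sub)
    kmax <- max(cor)
    if (kmax == 0L) next
    core_nodes <- which(cor >= kmax)
    nc <- length(core_nodes)
    if (nc < 2L) next
    e_core <- igraph::ecount(igraph::induced_subgraph(sub, core_nodes))
    w[i] <- kmax * (2 * e_core / (nc * (nc - 1)))
  }
  w
}

# does edge (u, v) sit inside a triangle? (u, v are names; adj a named list
# of neighbor-name vectors)
triangle_supported <- function(u, v, adj) {
  length(intersect(adj[[u]], adj[[v]])) > 0L
}

#' MCODE-style module detection
#'
#' Seeds are taken in decreasing vertex-weight order (ties broken
#' lexicographically by node name). Each complex grows from its seed by
#' breadth-first inclusion of neighbors whose weight is at least
#' `(1 - node_score_cutoff)` times the seed weight, to a depth of at most
#' `max_depth`; a node joins at most one complex. Growth only traverses
#' triangle-supported edges (edges whose endpoints share a neighbor), so a
#' single bridge edge cannot fuse two otherwise unrelated dense regions.
#' Complexes whose induced subgraph lacks a `k_core`-core are discarded, and
#' each surviving module is scored density times size.
#'
#' @param net An undirected `igraph` network.
#' @param degree_cutoff,node_score_cutoff,k_core,max_depth The canonical
#'   MCODE parameters (defaults 2, 0.2, 2, 100).
#' @return A `module_set` object: list with `modules` (each a list with
#'   `nodes` and `score`), `params`, and `min_size_applied` (`NULL` until
#'   [filter_modules()] is used). Modules are in discovery order.
#' @export
mcode_find <- function(net, degree_cutoff = 2L, node_score_cutoff = 0.2,
                       k_core = 2L, max_depth = 100L) {
  assert_network(net)
  w <- mcode_weights(net, degree_cutoff)
  nms <- names(w)
  adj <- lapply(igraph::as_adj_list(net), function(x) nms[as.integer(x)])
  names(adj) <- nms
  visited <- stats::setNames(rep(FALSE, length(nms)), nms)
  modules <- list()
  for (s in nms[order(-w, nms)]) {
    if (visited[s]) next
    if (w[s] <= 0) { visited[s] <- TRUE; next }
    thr <- (1 - node_score_cutoff) * w[s]
    comp <- s
    depth <- stats::setNames(0L, s)
    queue <- s
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      if (depth[u] >= max_depth) next
      for (v in adj[[u]]) {
        if (visited[v] || v %in% comp) next
        if (w[v] < thr) next
        if (!triangle_supported(u, v, adj)) next
        comp <- c(comp, v)
        depth[v] <- depth[u] + 1L
        queue <- c(queue, v)
      }
    }
    visited[comp] <- TRUE
    if (length(comp) < 2L) next
    sub <- igraph::induced_subgraph(net, comp)
    if (max(igraph::coreness(sub)) < k_core) next
    size <- length(comp)
    dens <- 2 * igraph::ecount(sub) / (size * (size - 1))
    modules[[length(modules) + 1L]] <-
      list(nodes = sort(comp), score = dens * size)
  }
  structure(
    list(modules = modules,
         params = list(degree_cutoff = degree_cutoff,
                       node_score_cutoff = node_score_cutoff,
                       k_core = k_core, max_depth = max_depth),
         min_size_applied = NULL),
    class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- vapply(x$modules, function(m) length(m$nodes), integer(1L))
  cat(sprintf("Module set: %d modules (sizes %s)\n", length(x$modules),
              if (length(sizes)) paste(sort(sizes, decreasing = TRUE),
                                       collapse = ", ") else "-"))
  if (!is.null(x$min_size_applied))
    cat(sprintf("  filtered to size > %d\n", x$min_size_applied))
  invisible(x)
}

#' Filter modules by size
#'
#' Keeps modules with strictly more than `min_size` nodes (the "more than
#' three nodes" convention at the default) and records the cutoff.
#'
#' @param ms A [mcode_find()] result.
#' @param min_size Strict lower bound on module size (default 3).
#' @return The filtered `module_set` with `min_size_applied` set.
#' @export
filter_modules <- function(ms, min_size = 3L) {
  if (!inherits(ms, "module_set"))
    stop("`ms` must be a module_set", call. = FALSE)
  if (min_size < 0L) stop("`min_size` must be >= 0", call. = FALSE)
  ms$modules <- Filter(function(m) length(m$nodes) > min_size, ms$modules)
  ms$min_size_applied <- as.integer(min_size)
  ms
}

# node -> group assignment; overlaps resolved by higher module score, then
# lexicographic module id. Returns named character vector over all nodes.
module_assignment <- function(nodes, ms, restrict_to = NULL) {
  group <- stats::setNames(nodes, nodes)
  if (!length(ms$modules)) return(group)
  ids <- sprintf("M%02d", seq_along(ms$modules))
  scores <- vapply(ms$modules, `[[`, numeric(1L), "score")
  for (i in order(-scores, ids)) {
    mem <- ms$modules[[i]]$nodes
    if (!is.null(restrict_to)) mem <- intersect(mem, restrict_to)
    mem <- intersect(mem, nodes)
    unassigned <- mem[group[mem] == mem]  # still mapping to themselves
    group[unassigned] <- ids[i]
  }
  group
}

#' Collapse modules into a weighted supernode network
#'
#' Each module becomes one supernode; nodes outside every module (or outside
#' `restrict_to`, when given) remain singleton supernodes. Superedge weight
#' counts the source edges running between two groups; intra-group edges are
#' dropped. Overlapping module assignments are resolved toward the
#' higher-scoring module.
#'
#' @param net An undirected `igraph` network.
#' @param ms A [mcode_find()] (optionally filtered) `module_set`.
#' @param restrict_to Optional node names; only these are eligible for
#'   collapse into their module (used to collapse rich-club nodes only).
#' @return An undirected `igraph` network with vertex attributes
#'   `node_weight` (member count) and `is_module`, and edge attribute
#'   `weight`.
#' @export
collapse_modules <- function(net, ms, restrict_to = NULL) {
  assert_network(net)
  if (!inherits(ms, "module_set"))
    stop("`ms` must be a module_set", call. = FALSE)
  nodes <- igraph::V(net)$name
  group <- module_assignment(nodes, ms, restrict_to)
  counts <- table(group)
  supernodes <- sort(unique(group))
  g_is_module <- grepl("^M[0-9]+$", supernodes) &
    !(supernodes %in% nodes)
  el <- igraph::as_edgelist(net)
  g1 <- group[el[, 1L]]; g2 <- group[el[, 2L]]
  cross <- g1 != g2
  res_edges <- NULL
  if (any(cross)) {
    a <- pmin(g1[cross], g2[cross]); b <- pmax(g1[cross], g2[cross])
    key <- paste(a, b, sep = "\r")
    wt <- table(key)
    parts <- strsplit(names(wt), "\r", fixed = TRUE)
    res_edges <- data.frame(
      from = vapply(parts, `[[`, character(1L), 1L),
      to = vapply(parts, `[[`, character(1L), 2L),
      weight = as.integer(wt), stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    if (is.null(res_edges)) data.frame(from = character(), to = character(),
                                       weight = integer())
    else res_edges,
    directed = FALSE,
    vertices = data.frame(name = supernodes, stringsAsFactors = FALSE))
  igraph::V(g)$node_weight <- as.integer(counts[igraph::V(g)$name])
  igraph::V(g)$is_module <- g_is_module[match(igraph::V(g)$name, supernodes)]
  g
}
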