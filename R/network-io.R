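# Graph data model, scored edge-list I/O and basic topology metrics.

#' Build an undirected simple network from an edge table
#'
#' Constructs the package's working network representation: an undirected
#' simple [igraph][igraph::igraph-package] graph with character vertex names.
#' Self-loops are dropped (their endpoint is retained as a node) and duplicate
#' pairs are merged keeping the maximum score.
#'
#' @param from,to Character vectors of endpoint identifiers (same length).
#' @param score Optional numeric vector of edge confidences in `[0, 1]`.
#' @param nodes Optional character vector of additional (possibly isolated)
#'   node identifiers to include.
#' @return An undirected simple `igraph` object; edge attribute `score` is set
#'   when `score` is supplied.
#' @export
make_network <- function(from, to, score = NULL, nodes = NULL) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to))
    stop("`from` and `to` must have the same length", call. = FALSE)
  if (!is.null(score) && length(score) != length(from))
    stop("`score` must match the number of edges", call. = FALSE)
  all_nodes <- unique(c(from, to, as.character(nodes)))
  loop <- from == to
  from <- from[!loop]; to <- to[!loop]
  if (!is.null(score)) score <- score[!loop]
  # merge duplicate unordered pairs, keeping the maximum score
  if (length(from)) {
    key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
    if (anyDuplicated(key)) {
      if (!is.null(score)) {
        score <- as.numeric(tapply(score, key, max)[unique(key)])
      }
      first <- !duplicated(key)
      from <- from[first]; to <- to[first]
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = all_nodes, stringsAsFactors = FALSE)
  )
  if (!is.null(score) && igraph::ecount(g) > 0)
    igraph::E(g)$score <- score
  g
}

assert_network <- function(net, arg = "net") {
  if (!igraph::is_igraph(net))
    stop(sprintf("`%s` must be an igraph network", arg), call. = FALSE)
  if (igraph::is_directed(net))
    stop(sprintf("`%s` must be undirected", arg), call. = FALSE)
  if (is.null(igraph::V(net)$name))
    stop(sprintf("`%s` must have named vertices", arg), call. = FALSE)
  invisible(net)
}

#' Load a scored edge list
#'
#' Reads a STRING-export-style TSV (`node1 <TAB> node2 [<TAB> combined
#' score]`) into a simple undirected network, keeping the edges whose score is
#' at least `score_min`. A header line is skipped automatically. When any
#' score exceeds 1 the whole column is taken to be in STRING's integer dialect
#' and rescaled by 1/1000 before thresholding. Self-loops are dropped (the
#' node is retained) and duplicate pairs are merged keeping the maximum score.
#'
#' @param path Path to the edge-list file (tab- or whitespace-separated).
#' @param score_min Minimum combined score in `[0, 1]`; default 0.4, the
#'   conventional medium-confidence STRING cutoff.
#' @return An undirected simple `igraph` network (edge attribute `score` when
#'   the file has a score column). All node identifiers seen in the file are
#'   retained, including endpoints of dropped edges.
#' @export
read_scored_edges <- function(path, score_min = 0.4) {
  if (!is.numeric(score_min) || length(score_min) != 1L || is.na(score_min) ||
      score_min < 0 || score_min > 1)
    stop("`score_min` must be a single number in [0, 1]", call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- trimws(lines[keep])
  if (!length(lines)) return(make_network(character(), character()))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  is_num <- function(x) !is.na(suppressWarnings(as.numeric(x)))
  header_names <- c("node1", "node2", "protein1", "protein2", "source",
                    "target", "from", "to", "gene1", "gene2")
  f1 <- fields[[1L]]
  header <- (nf[1L] >= 3L && !is_num(f1[3L])) ||
    all(tolower(f1[1:2]) %in% header_names)
  if (header) {
    fields <- fields[-1L]; lineno <- lineno[-1L]; nf <- nf[-1L]
  }
  if (!length(fields)) return(make_network(character(), character()))
  bad <- which(nf < 2L)
  if (length(bad))
    stop(sprintf("malformed edge list '%s': line %d has fewer than 2 fields",
                 path, lineno[bad[1L]]), call. = FALSE)
  n1 <- vapply(fields, `[[`, character(1L), 1L)
  n2 <- vapply(fields, `[[`, character(1L), 2L)
  score <- NULL
  if (any(nf >= 3L)) {
    bad <- which(nf < 3L)
    if (length(bad))
      stop(sprintf("malformed edge list '%s': line %d is missing a score",
                   path, lineno[bad[1L]]), call. = FALSE)
    raw <- vapply(fields, `[[`, character(1L), 3L)
    score <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(score))
    if (length(bad))
      stop(sprintf("malformed edge list '%s': non-numeric score on line %d",
                   path, lineno[bad[1L]]), call. = FALSE)
    if (any(score > 1)) score <- score / 1000  # STRING integer dialect
  }
  all_nodes <- unique(c(n1, n2))
  if (!is.null(score)) {
    # merge duplicates on max score before thresholding
    g <- make_network(n1, n2, score = score, nodes = all_nodes)
    drop <- igraph::E(g)[igraph::E(g)$score < score_min]
    g <- igraph::delete_edges(g, drop)
    g
  } else {
    make_network(n1, n2, nodes = all_nodes)
  }
}

#' Write a network as a scored edge list
#'
#' Inverse of [read_scored_edges()]: writes one `node1<TAB>node2[<TAB>score]`
#' line per edge (no header). Isolated nodes are not representable in an edge
#' list; use [export_graphml()] to preserve them.
#'
#' @param net An undirected `igraph` network.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scored_edges <- function(net, path) {
  assert_network(net)
  el <- igraph::as_edgelist(net)
  df <- data.frame(node1 = el[, 1L], node2 = el[, 2L],
                   stringsAsFactors = FALSE)
  if (!is.null(igraph::edge_attr(net, "score")))
    df$score <- igraph::E(net)$score
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a network to GraphML
#'
#' @param net An `igraph` network (vertex/edge attributes are preserved).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path) {
  assert_network(net)
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

largest_component <- function(net) {
  comp <- igraph::components(net)
  igraph::induced_subgraph(net, which(comp$membership ==
                                        which.max(comp$csize)))
}

#' Per-node clustering coefficients
#'
#' Local clustering `C_i` = observed triangles at `i` divided by
#' `k_i (k_i - 1) / 2`; nodes of degree < 2 score 0.
#'
#' @param net An undirected `igraph` network.
#' @return Named numeric vector of `C_i` in `[0, 1]`.
#' @export
node_clustering <- function(net) {
  assert_network(net)
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  names(cc) <- igraph::V(net)$name
  cc
}

#' Average shortest-path length
#'
#' Mean geodesic distance over connected unordered node pairs. Disconnected
#' pairs are excluded by default; `scope = "largest_component"` restricts the
#' computation to the largest connected component instead (both conventions
#' appear in the interactome literature).
#'
#' @param net An undirected `igraph` network with at least 2 nodes.
#' @param scope `"connected_pairs"` (default) or `"largest_component"`.
#' @return Mean path length (`>= 1` for any network with an edge), or `NA`
#'   with a warning when no pair of nodes is connected.
#' @export
average_path_length <- function(net,
                                scope = c("connected_pairs",
                                          "largest_component")) {
  assert_network(net)
  scope <- match.arg(scope)
  if (igraph::vcount(net) < 2L)
    stop("average path length needs at least 2 nodes", call. = FALSE)
  g <- if (scope == "largest_component") largest_component(net) else net
  if (igraph::ecount(g) == 0L || igraph::vcount(g) < 2L) {
    warning("no connected node pair; average path length undefined")
    return(NA_real_)
  }
  igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
}

#' Global network efficiency
#'
#' `E = (1 / (N (N - 1))) * sum_{i != j} 1 / d(i, j)` with `1 / d = 0` for
#' disconnected pairs, so the measure is defined on fragmented networks.
#'
#' @param net An undirected `igraph` network with at least 2 nodes.
#' @return Efficiency in `[0, 1]`; 1 exactly for a complete graph.
#' @export
global_efficiency <- function(net) {
  assert_network(net)
  if (igraph::vcount(net) < 2L)
    stop("global efficiency needs at least 2 nodes", call. = FALSE)
  igraph::global_efficiency(net, directed = FALSE)
}

#' Fit a power law to a degree sequence
#'
#' Discrete maximum-likelihood fit with Kolmogorov-Smirnov-minimizing lower
#' cutoff (the `plfit` method), or a log-log regression on the degree
#' frequency spectrum as a cruder fallback.
#'
#' @param degrees Integer vector of node degrees; at least 10 positive values
#'   spanning at least 3 distinct degrees are required.
#' @param method `"mle"` (default) or `"regression"`.
#' @return List with `exponent`, `xmin` and `method`.
#' @export
fit_degree_powerlaw <- function(degrees, method = c("mle", "regression")) {
  method <- match.arg(method)
  d <- degrees[!is.na(degrees) & degrees > 0]
  if (length(d) < 10L || length(unique(d)) < 3L)
    stop("degenerate degree sequence: need >= 10 positive degrees with >= 3 distinct values",
         call. = FALSE)
  if (method == "mle") {
    fit <- igraph::fit_power_law(d, implementation = "plfit")
    list(exponent = fit$alpha, xmin = fit$xmin, method = "mle")
  } else {
    tab <- table(d)
    k <- as.numeric(names(tab))
    f <- as.numeric(tab) / length(d)
    co <- stats::coef(stats::lm(log(f) ~ log(k)))
    list(exponent = -unname(co[2L]), xmin = min(k), method = "regression")
  }
}

#' Global topology summary
#'
#' Node/edge counts, average path length, mean clustering coefficient, global
#' efficiency and the degree power-law fit for a network.
#'
#' @param net An undirected `igraph` network.
#' @param fit_powerlaw Fit the degree distribution? Skipped (with `NA`
#'   results) when the degree sequence is degenerate.
#' @param apl_scope Passed to [average_path_length()].
#' @return List with `n_nodes`, `n_edges`, `avg_path_length`, `avg_clustering`,
#'   `global_efficiency`, `powerlaw_exponent`, `powerlaw_xmin`.
#' @export
global_metrics <- function(net, fit_powerlaw = TRUE,
                           apl_scope = "connected_pairs") {
  assert_network(net)
  n <- igraph::vcount(net)
  pl <- list(exponent = NA_real_, xmin = NA_real_)
  if (fit_powerlaw)
    pl <- tryCatch(fit_degree_powerlaw(igraph::degree(net)),
                   error = function(e) pl)
  list(
    n_nodes = n,
    n_edges = igraph::ecount(net),
    avg_path_length = if (n >= 2L)
      suppressWarnings(average_path_length(net, scope = apl_scope))
      else NA_real_,
    avg_clustering = if (n > 0L) mean(node_clustering(net)) else NA_real_,
    global_efficiency = if (n >= 2L) global_efficiency(net) else NA_real_,
    powerlaw_exponent = pl$exponent,
    powerlaw_xmin = pl$xmin
  )
}
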