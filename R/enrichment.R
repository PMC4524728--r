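# Local over-representation analysis (hypergeometric / EASE) against
# user-supplied GMT annotation collections, and term-interaction networks.

#' Read a GMT annotation collection
#'
#' Standard gene-set format: one tab-separated line per term
#' (`term <TAB> description <TAB> member ...`).
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (term -> members).
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Over-representation analysis of a node set
#'
#' For each term, the one-sided hypergeometric tail `P(X >= k)` for drawing
#' `k` term members in a set of size `n` from a background of size `N`
#' containing `K` term members. Mode `"ease"` is DAVID's conservative
#' variant, computed with one hit removed (`k - 1`). P-values are
#' Benjamini-Hochberg adjusted across terms and reported together with the
#' display transform `enrichment_score = log10(1 / p)`.
#'
#' @param set Character vector of query nodes (intersected with
#'   `background`).
#' @param collection Named list of character vectors (term -> members), e.g.
#'   from [read_gmt()].
#' @param background Character vector defining the test universe (typically
#'   all network nodes).
#' @param mode `"ease"` (default, the DAVID convention) or `"fisher"`.
#' @return Data frame sorted by p ascending with columns `term`, `hits`,
#'   `set_size`, `term_size`, `background_size`, `p`, `p_adjusted`,
#'   `enrichment_score`.
#' @export
enrich <- function(set, collection, background, mode = c("ease", "fisher")) {
  mode <- match.arg(mode)
  background <- unique(as.character(background))
  if (!length(background))
    stop("`background` must be non-empty", call. = FALSE)
  if (!length(collection) || is.null(names(collection)))
    stop("`collection` must be a named list of term member vectors",
         call. = FALSE)
  set <- intersect(unique(as.character(set)), background)
  N <- length(background)
  n <- length(set)
  rows <- lapply(names(collection), function(term) {
    members <- intersect(unique(as.character(collection[[term]])), background)
    K <- length(members)
    k <- length(intersect(set, members))
    p <- if (k == 0L) 1 else {
      q <- if (mode == "ease") k - 1L else k
      # P(X >= q); q = 0 gives 1
      phyper(q - 1L, K, N - K, n, lower.tail = FALSE)
    }
    data.frame(term = term, hits = k, set_size = n, term_size = K,
               background_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p, method = "BH")
  out$enrichment_score <- log10(1 / out$p)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pathway / term interaction network
#'
#' Builds a weighted supernode network over annotation terms: one supernode
#' per term, weighted by its member count within the network, and superedges
#' weighted by the number of network edges running between the two term
#' sets. An edge whose endpoints both belong to both terms of a pair
#' contributes once to that pair's weight.
#'
#' @param net An undirected `igraph` network.
#' @param collection Named list of term member vectors.
#' @param terms Terms to include (must exist in `collection`).
#' @return An undirected `igraph` over `terms` with vertex attribute
#'   `node_weight` and edge attribute `weight` (pairs with zero interactions
#'   carry no edge).
#' @export
pathway_interaction_network <- function(net, collection, terms) {
  assert_network(net)
  terms <- unique(as.character(terms))
  missing_terms <- setdiff(terms, names(collection))
  if (length(missing_terms))
    stop(sprintf("term(s) absent from collection: %s",
                 paste(head(missing_terms, 3L), collapse = ", ")),
         call. = FALSE)
  nodes <- igraph::V(net)$name
  sets <- lapply(collection[terms], function(m)
    intersect(unique(as.character(m)), nodes))
  el <- igraph::as_edgelist(net)
  edges <- NULL
  if (length(terms) >= 2L && nrow(el)) {
    member <- vapply(sets, function(s)
      cbind(el[, 1L] %in% s, el[, 2L] %in% s),
      matrix(logical(1L), nrow(el), 2L))
    # member[edge, endpoint, term]
    pairs <- combn(seq_along(terms), 2L)
    res <- apply(pairs, 2L, function(pr) {
      a <- pr[1L]; b <- pr[2L]
      sum((member[, 1L, a] & member[, 2L, b]) |
          (member[, 1L, b] & member[, 2L, a]))
    })
    keep <- res > 0L
    if (any(keep))
      edges <- data.frame(from = terms[pairs[1L, keep]],
                          to = terms[pairs[2L, keep]],
                          weight = res[keep], stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(), to = character(),
                                   weight = integer())
    else edges,
    directed = FALSE,
    vertices = data.frame(name = terms, stringsAsFactors = FALSE))
  igraph::V(g)$node_weight <- lengths(sets)[match(igraph::V(g)$name, terms)]
  g
}
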