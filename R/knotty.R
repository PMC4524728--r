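# Knotty centrality: connective-core score, greedy and exhaustive search.

#' Knotty centrality of a node subset
#'
#' `KC(S) = [2 |E(S)| / (|S| (|S| - 1))] * [sum_{i in S} b_i / sum_{i in V}
#' b_i]` — internal edge density times the subset's share of total (raw)
#' betweenness. A subgraph scoring high on both terms is a topologically
#' central connective core. Normalization of betweenness cancels in the
#' share, so raw pair counts are used.
#'
#' @param net An undirected `igraph` network.
#' @param subset Character vector of node names (must exist in `net`).
#' @return Score in `[0, 1]`; 0 when `|subset| < 2` or total betweenness is
#'   zero.
#' @export
knotty_centrality <- function(net, subset) {
  assert_network(net)
  subset <- unique(as.character(subset))
  unknown <- setdiff(subset, igraph::V(net)$name)
  if (length(unknown))
    stop(sprintf("unknown node(s) in subset: %s",
                 paste(head(unknown, 3L), collapse = ", ")), call. = FALSE)
  if (length(subset) < 2L) return(0)
  btw <- node_betweenness(net)
  tot <- sum(btw)
  if (tot == 0) return(0)
  s <- length(subset)
  e_in <- igraph::ecount(igraph::induced_subgraph(net, subset))
  (2 * e_in / (s * (s - 1))) * (sum(btw[subset]) / tot)
}

# hill-climb from a seed member set; vectorized steepest-ascent over single
# add/remove moves. A is a dense adjacency matrix, btw raw betweenness.
kc_hill_climb <- function(A, btw, tot_btw, seed_idx) {
  n <- nrow(A)
  in_set <- rep(FALSE, n)
  in_set[seed_idx] <- TRUE
  kc_of <- function(e_in, b_sum, s)
    if (s < 2L) 0 else (2 * e_in / (s * (s - 1))) * (b_sum / tot_btw)
  s <- sum(in_set)
  e_in <- sum(A[in_set, in_set]) / 2
  b_sum <- sum(btw[in_set])
  score <- kc_of(e_in, b_sum, s)
  repeat {
    deg_to_set <- as.vector(A %*% in_set)
    cand_add <- which(!in_set)
    cand_rem <- which(in_set)
    best_gain <- 0; best_v <- NA_integer_; best_dir <- NA_character_
    if (length(cand_add)) {
      sc <- kc_of(e_in + deg_to_set[cand_add], b_sum + btw[cand_add], s + 1L)
      i <- which.max(sc)
      if (sc[i] - score > best_gain + 1e-12) {
        best_gain <- sc[i] - score; best_v <- cand_add[i]; best_dir <- "add"
      }
    }
    if (s > 2L) {
      sc <- kc_of(e_in - deg_to_set[cand_rem], b_sum - btw[cand_rem], s - 1L)
      i <- which.max(sc)
      if (sc[i] - score > best_gain + 1e-12) {
        best_gain <- sc[i] - score; best_v <- cand_rem[i]; best_dir <- "remove"
      }
    }
    if (is.na(best_v)) break
    if (best_dir == "add") {
      in_set[best_v] <- TRUE
      e_in <- e_in + deg_to_set[best_v]; b_sum <- b_sum + btw[best_v]
      s <- s + 1L
    } else {
      in_set[best_v] <- FALSE
      e_in <- e_in - deg_to_set[best_v]; b_sum <- b_sum - btw[best_v]
      s <- s - 1L
    }
    score <- score + best_gain
  }
  # plateau expansion: absorb nodes that leave the score unchanged, so ties
  # resolve toward the largest core (e.g. a full clique rather than two of
  # its members); additions only, hence terminating
  repeat {
    deg_to_set <- as.vector(A %*% in_set)
    cand_add <- which(!in_set)
    if (!length(cand_add)) break
    sc <- kc_of(e_in + deg_to_set[cand_add], b_sum + btw[cand_add], s + 1L)
    i <- which.max(sc)
    if (sc[i] < score - 1e-12) break
    v <- cand_add[i]
    in_set[v] <- TRUE
    e_in <- e_in + deg_to_set[v]; b_sum <- b_sum + btw[v]
    s <- s + 1L
    score <- sc[i]
  }
  list(members = which(in_set), score = score)
}

#' Find the knotty centre of a network
#'
#' Searches for the node subset maximizing [knotty_centrality()]. The search
#' runs on the largest connected component. The heuristic is a deterministic
#' steepest-ascent hill-climb over single add-or-remove moves, restarted from
#' every pair among the five highest-betweenness nodes, keeping the best
#' result. The exhaustive method enumerates every subset (feasible only for
#' small networks) and serves as an exact reference.
#'
#' @param net An undirected `igraph` network with at least 3 nodes and 2
#'   edges.
#' @param method `"heuristic"` (default) or `"exhaustive"`.
#' @param seed Integer recorded in the result; the search itself is
#'   deterministic.
#' @param exhaustive_max Refuse exhaustive search above this many nodes
#'   (default 12).
#' @return A `knotty_centre` object (`members`, `kc_score`, `method`,
#'   `seed`), or `NULL` when every node has zero betweenness (no connective
#'   core exists, e.g. disjoint edges).
#' @export
find_knotty_centre <- function(net, method = c("heuristic", "exhaustive"),
                               seed = 1L, exhaustive_max = 12L) {
  assert_network(net)
  method <- match.arg(method)
  if (igraph::vcount(net) < 3L || igraph::ecount(net) < 2L)
    stop("knotty-centre search needs >= 3 nodes and >= 2 edges",
         call. = FALSE)
  g <- largest_component(net)
  btw <- node_betweenness(g)
  if (all(btw == 0)) return(NULL)
  nms <- igraph::V(g)$name
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  tot <- sum(btw)
  if (method == "exhaustive") {
    n <- length(nms)
    if (n > exhaustive_max)
      stop(sprintf("exhaustive search limited to %d nodes (network has %d)",
                   exhaustive_max, n), call. = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    best_score <- -Inf; best_mask <- NULL; best_size <- 0L
    for (mask in seq_len(2^n - 1L)) {
      sel <- as.logical(bitwAnd(mask, 2^(0:(n - 1L))))
      s <- sum(sel)
      if (s < 2L) next
      e_in <- sum(sel[el[, 1L]] & sel[el[, 2L]])
      sc <- (2 * e_in / (s * (s - 1))) * (sum(btw[sel]) / tot)
      # ties resolve toward the larger subset (the most inclusive core)
      if (sc > best_score + 1e-12 ||
          (sc > best_score - 1e-12 && s > best_size)) {
        best_score <- sc; best_mask <- sel; best_size <- s
      }
    }
    members <- sort(nms[best_mask])
    return(structure(list(members = members, kc_score = best_score,
                          method = "exhaustive", seed = as.integer(seed)),
                     class = "knotty_centre"))
  }
  ord <- order(-btw, nms)
  top <- ord[seq_len(min(5L, length(ord)))]
  seeds <- if (length(top) >= 2L) combn(top, 2L, simplify = FALSE)
           else list(top)
  best <- NULL
  for (sd_idx in seeds) {
    res <- kc_hill_climb(A, btw, tot, sd_idx)
    if (is.null(best) || res$score > best$score + 1e-12 ||
        (res$score > best$score - 1e-12 &&
         length(res$members) > length(best$members))) best <- res
  }
  structure(list(members = sort(nms[best$members]), kc_score = best$score,
                 method = "heuristic", seed = as.integer(seed)),
            class = "knotty_centre")
}

#' @export
print.knotty_centre <- function(x, ...) {
  cat(sprintf("Knotty centre (%s): %d members, KC = %.4f\n",
              x$method, length(x$members), x$kc_score))
  invisible(x)
}

#' Mutual overlap of two node sets
#'
#' @param a,b Character vectors (node sets).
#' @return Numeric `c(frac_a, frac_b)`: the intersection as a fraction of
#'   each set; 0 components for empty sets.
#' @export
overlap_fraction <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  common <- length(intersect(a, b))
  c(frac_a = if (length(a)) common / length(a) else 0,
    frac_b = if (length(b)) common / length(b) else 0)
}
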