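# Degree-preserving randomization ensembles and the small-world index.

#' Degree-preserving rewiring
#'
#' Randomizes a network by attempted double-edge swaps that reject self-loops
#' and multi-edges, leaving the degree sequence exactly intact. Deterministic
#' for a given seed. Connectedness is not enforced.
#'
#' @param net An undirected `igraph` network.
#' @param swaps_per_edge Number of attempted swaps per edge (default 10).
#' @param seed Integer RNG seed.
#' @return A rewired `igraph` network with the same vertices and degree
#'   sequence (edge scores, being meaningless after rewiring, are dropped).
#' @export
rewire_preserving_degrees <- function(net, swaps_per_edge = 10, seed = 1L) {
  assert_network(net)
  g <- strip_edge_attrs(net)
  if (igraph::ecount(g) < 2L) return(g)
  withr::with_seed(seed,
    igraph::rewire(g, igraph::keeping_degseq(
      loops = FALSE, niter = ceiling(swaps_per_edge * igraph::ecount(g)))))
}

strip_edge_attrs <- function(net) {
  for (a in igraph::edge_attr_names(net))
    net <- igraph::delete_edge_attr(net, a)
  net
}

#' Build a degree-preserving null ensemble
#'
#' Generates `n` independent rewirings of `net` (member `i` uses seed
#' `seed + i - 1`), the comparison population for rich-club normalization and
#' the small-world index.
#'
#' @param net An undirected `igraph` network.
#' @param n Ensemble size; the conventional choice for rich-club
#'   normalization is 1000.
#' @param seed Integer base seed; regeneration with the same seed reproduces
#'   the ensemble exactly.
#' @param swaps_per_edge Attempted swaps per edge for each member.
#' @return A `null_ensemble` object: list with `members` (list of igraph),
#'   `degree_sequence`, `seed`, `swaps_per_edge`.
#' @export
make_null_ensemble <- function(net, n = 1000L, seed = 1L,
                               swaps_per_edge = 10) {
  assert_network(net)
  n <- as.integer(n)
  if (is.na(n) || n < 1L)
    stop("`n` must be a positive integer", call. = FALSE)
  members <- lapply(seq_len(n) - 1L, function(i)
    rewire_preserving_degrees(net, swaps_per_edge = swaps_per_edge,
                              seed = seed + i))
  structure(
    list(members = members,
         degree_sequence = sort(igraph::degree(net)),
         seed = as.integer(seed),
         swaps_per_edge = swaps_per_edge),
    class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("Degree-preserving null ensemble: %d members, %d nodes, seed %d\n",
              length(x$members), length(x$degree_sequence), x$seed))
  invisible(x)
}

assert_ensemble <- function(ensemble) {
  if (!inherits(ensemble, "null_ensemble") || !length(ensemble$members))
    stop("`ensemble` must be a non-empty null_ensemble", call. = FALSE)
  invisible(ensemble)
}

#' Small-world index
#'
#' Humphries-Gurney sigma: `(C / <C_rand>) / (L / <L_rand>)` where `C` is the
#' mean local clustering coefficient, `L` the average path length over
#' connected pairs, and the angle brackets are means over a null ensemble of
#' the network. `sigma > 1` indicates small-world organization.
#'
#' @param net An undirected `igraph` network.
#' @param ensemble A [make_null_ensemble()] result built from `net`.
#' @return The index, or `NA` with a warning when the null mean clustering is
#'   zero.
#' @export
small_world_index <- function(net, ensemble) {
  assert_network(net)
  assert_ensemble(ensemble)
  C <- mean(node_clustering(net))
  L <- average_path_length(net)
  C_rand <- mean(vapply(ensemble$members,
                        function(g) mean(node_clustering(g)), numeric(1L)))
  L_rand <- mean(vapply(ensemble$members, function(g)
    suppressWarnings(average_path_length(g)), numeric(1L)))
  if (!is.finite(C_rand) || C_rand == 0) {
    warning("null ensemble has zero mean clustering; small-world index undefined")
    return(NA_real_)
  }
  (C / C_rand) / (L / L_rand)
}
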