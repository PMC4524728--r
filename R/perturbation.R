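# Targeted-removal perturbation: impact of deleting a chosen triad versus
# random triads drawn from a comparison pool.

#' Remove nodes from a network
#'
#' @param net An undirected `igraph` network.
#' @param nodes Character vector of node names to delete (must exist).
#' @return The induced subgraph on the remaining nodes.
#' @export
remove_nodes <- function(net, nodes) {
  assert_network(net)
  nodes <- unique(as.character(nodes))
  unknown <- setdiff(nodes, igraph::V(net)$name)
  if (length(unknown))
    stop(sprintf("unknown node(s): %s",
                 paste(head(unknown, 3L), collapse = ", ")), call. = FALSE)
  if (!length(nodes)) return(net)
  igraph::delete_vertices(net, nodes)
}

perturbation_metrics <- c("global_efficiency", "avg_path_length",
                          "avg_clustering")

eval_metric <- function(net, metric) {
  if (igraph::vcount(net) < 2L) return(NA_real_)
  switch(metric,
    global_efficiency = global_efficiency(net),
    avg_path_length = suppressWarnings(average_path_length(net)),
    avg_clustering = mean(node_clustering(net)),
    stop(sprintf("unknown metric '%s'", metric), call. = FALSE))
}

#' Metric change under node removal
#'
#' Absolute change `|m(net) - m(net \ nodes)|` for each requested global
#' metric. A metric that is undefined after removal is recorded as `NA`.
#'
#' @param net An undirected `igraph` network.
#' @param nodes Node names to remove.
#' @param metrics Subset of `"global_efficiency"`, `"avg_path_length"`,
#'   `"avg_clustering"`.
#' @return Named numeric vector of absolute changes.
#' @export
metric_change <- function(net, nodes, metrics = perturbation_metrics) {
  assert_network(net)
  metrics <- match.arg(metrics, perturbation_metrics, several.ok = TRUE)
  reduced <- remove_nodes(net, nodes)
  vapply(metrics, function(m)
    abs(eval_metric(net, m) - eval_metric(reduced, m)), numeric(1L))
}

#' Targeted triad-removal experiment
#'
#' Compares the impact of removing a chosen 3-node set against `n_random`
#' distinct random triads drawn from a comparison pool (typically the
#' rich-club members, with the targeted triad excluded). For each metric the
#' result reports the ratio of the targeted change to the mean random change
#' and a one-sided one-sample t-test of the random-change distribution
#' against the targeted change (alternative: the targeted change exceeds).
#'
#' @param net An undirected `igraph` network.
#' @param triad Exactly 3 node names.
#' @param pool Node names to draw random triads from; the triad members are
#'   removed from it, and at least 3 must remain.
#' @param n_random Number of distinct random triads (default 100; capped with
#'   a warning when the pool admits fewer).
#' @param seed Integer RNG seed fixing every random draw.
#' @param metrics Metrics to monitor (see [metric_change()]).
#' @return A `perturbation_result`: list with `metric_names`,
#'   `targeted_change`, `random_changes` (matrix, one row per triad),
#'   `ratio`, `p_value`, `n_random`, `seed`.
#' @export
triad_experiment <- function(net, triad, pool, n_random = 100L, seed = 1L,
                             metrics = perturbation_metrics) {
  assert_network(net)
  triad <- unique(as.character(triad))
  if (length(triad) != 3L)
    stop("`triad` must contain exactly 3 distinct nodes", call. = FALSE)
  metrics <- match.arg(metrics, perturbation_metrics, several.ok = TRUE)
  pool <- setdiff(unique(as.character(pool)), triad)
  unknown <- setdiff(c(triad, pool), igraph::V(net)$name)
  if (length(unknown))
    stop(sprintf("unknown node(s): %s",
                 paste(head(unknown, 3L), collapse = ", ")), call. = FALSE)
  if (length(pool) < 3L)
    stop("`pool` must contain at least 3 nodes besides the triad",
         call. = FALSE)
  n_random <- as.integer(n_random)
  if (n_random < 1L) stop("`n_random` must be >= 1", call. = FALSE)
  max_triads <- choose(length(pool), 3L)
  if (n_random > max_triads) {
    warning(sprintf("pool admits only %d distinct triads; capping n_random",
                    max_triads))
    n_random <- as.integer(max_triads)
  }
  triads <- withr::with_seed(seed, {
    seen <- character(0L)
    out <- vector("list", n_random)
    i <- 0L
    while (i < n_random) {
      tr <- sort(sample(pool, 3L))
      key <- paste(tr, collapse = "\r")
      if (key %in% seen) next
      i <- i + 1L
      seen <- c(seen, key)
      out[[i]] <- tr
    }
    out
  })
  targeted <- metric_change(net, triad, metrics)
  random_changes <- matrix(
    vapply(triads, function(tr) metric_change(net, tr, metrics),
           numeric(length(metrics))),
    ncol = length(metrics), byrow = TRUE)
  colnames(random_changes) <- metrics
  rand_mean <- colMeans(random_changes)
  ratio <- ifelse(!is.na(rand_mean) & rand_mean != 0,
                  targeted / rand_mean, NA_real_)
  p <- vapply(metrics, function(m) {
    x <- random_changes[, m]
    x <- x[!is.na(x)]
    if (length(x) < 2L || is.na(targeted[m])) return(NA_real_)
    if (sd(x) == 0) return(if (targeted[m] > x[1L]) 0 else 1)
    t.test(x, mu = targeted[m], alternative = "less")$p.value
  }, numeric(1L))
  structure(
    list(metric_names = metrics, targeted_change = targeted,
         random_changes = random_changes, ratio = ratio, p_value = p,
         n_random = n_random, seed = as.integer(seed)),
    class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("Triad-removal experiment (%d random triads, seed %d)\n",
              x$n_random, x$seed))
  for (m in x$metric_names)
    cat(sprintf("  %-18s targeted %.5f  ratio %.3f  p %.4g\n",
                m, x$targeted_change[m], x$ratio[m], x$p_value[m]))
  invisible(x)
}
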