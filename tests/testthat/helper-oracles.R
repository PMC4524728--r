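# Independent brute-force oracles for small graphs. These deliberately avoid
# igraph: distances by Floyd-Warshall, betweenness by explicit shortest-path
# enumeration, phi/kc by direct set arithmetic on an adjacency matrix.

oracle_adjacency <- function(net) {
  nms <- igraph::V(net)$name
  n <- length(nms)
  A <- matrix(0L, n, n, dimnames = list(nms, nms))
  el <- igraph::as_edgelist(net)
  if (nrow(el)) {
    for (i in seq_len(nrow(el))) {
      A[el[i, 1L], el[i, 2L]] <- 1L
      A[el[i, 2L], el[i, 1L]] <- 1L
    }
  }
  A
}

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  diag(D) <- 0
  D[A == 1L] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_apl <- function(A) {
  D <- oracle_distances(A)
  d <- D[upper.tri(D)]
  d <- d[is.finite(d)]
  if (!length(d)) NA_real_ else mean(d)
}

oracle_efficiency <- function(A) {
  D <- oracle_distances(A)
  n <- nrow(A)
  inv <- 1 / D[upper.tri(D)]
  inv[!is.finite(inv)] <- 0
  2 * sum(inv) / (n * (n - 1))
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  out <- stats::setNames(numeric(n), rownames(A))
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1L)
    k <- length(nb)
    if (k < 2L) next
    tri <- sum(A[nb, nb]) / 2
    out[i] <- tri / (k * (k - 1) / 2)
  }
  out
}

# all shortest i->j paths, enumerated by walking the distance matrix
oracle_all_shortest_paths <- function(A, D, i, j) {
  if (!is.finite(D[i, j])) return(list())
  if (i == j) return(list(i))
  paths <- list()
  for (v in which(A[i, ] == 1L)) {
    if (D[v, j] == D[i, j] - 1) {
      for (p in oracle_all_shortest_paths(A, D, v, j))
        paths[[length(paths) + 1L]] <- c(i, p)
    }
  }
  paths
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  b <- stats::setNames(numeric(n), rownames(A))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      paths <- oracle_all_shortest_paths(A, D, i, j)
      if (!length(paths)) next
      for (p in paths) {
        interior <- setdiff(p, c(i, j))
        if (length(interior))
          b[interior] <- b[interior] + 1 / length(paths)
      }
    }
  }
  b
}

oracle_phi <- function(A, k) {
  deg <- rowSums(A)
  S <- which(deg > k)
  if (length(S) < 2L) return(NA_real_)
  e <- sum(A[S, S]) / 2
  2 * e / (length(S) * (length(S) - 1))
}

oracle_kc <- function(A, subset) {
  b <- oracle_betweenness(A)
  tot <- sum(b)
  if (tot == 0 || length(subset) < 2L) return(0)
  s <- length(subset)
  e_in <- sum(A[subset, subset]) / 2
  (2 * e_in / (s * (s - 1))) * (sum(b[subset]) / tot)
}

# exact knotty-centre optimum by subset enumeration (oracle-side)
oracle_kc_optimum <- function(A) {
  n <- nrow(A)
  b <- oracle_betweenness(A)
  tot <- sum(b)
  if (tot == 0) return(NULL)
  best <- -Inf; best_set <- NULL
  for (mask in seq_len(2^n - 1L)) {
    sel <- which(as.logical(bitwAnd(mask, 2^(0:(n - 1L)))))
    s <- length(sel)
    if (s < 2L) next
    e_in <- sum(A[sel, sel]) / 2
    sc <- (2 * e_in / (s * (s - 1))) * (sum(b[sel]) / tot)
    if (sc > best + 1e-12) {
      best <- sc; best_set <- sel
    }
  }
  list(score = best, members = rownames(A)[best_set])
}

# exact hypergeometric upper tail P(X >= k) by factorial summation
oracle_hyper_tail <- function(k, K, N, n) {
  if (k <= 0) return(1)
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# deterministic Erdos-Renyi test graph with named nodes
random_test_graph <- function(n, p, seed) {
  g <- withr::with_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

complete_graph <- function(n, prefix = "k") {
  pr <- combn(sprintf("%s%d", prefix, seq_len(n)), 2L)
  netarch::make_network(pr[1L, ], pr[2L, ])
}

star_graph <- function(leaves = 4L) {
  netarch::make_network(rep("hub", leaves), sprintf("leaf%d", seq_len(leaves)))
}

path_graph <- function(n) {
  nm <- sprintf("p%d", seq_len(n))
  netarch::make_network(nm[-n], nm[-1L])
}

cycle_graph <- function(n) {
  nm <- sprintf("c%d", seq_len(n))
  netarch::make_network(nm, nm[c(2:n, 1L)])
}

# two K4s joined by a 3-node path: a1..a4 - p1 - p2 - p3 - b1..b4
barbell_graph <- function() {
  a <- combn(sprintf("a%d", 1:4), 2L)
  b <- combn(sprintf("b%d", 1:4), 2L)
  netarch::make_network(c(a[1L, ], b[1L, ], "a1", "p1", "p2", "p3"),
                        c(a[2L, ], b[2L, ], "p1", "p2", "p3", "b1"))
}

oracle_closeness <- function(A) {
  D <- oracle_distances(A)
  n <- nrow(A)
  out <- stats::setNames(numeric(n), rownames(A))
  if (n < 2L) return(out)
  for (i in seq_len(n)) {
    d <- D[i, -i]
    reach <- d[is.finite(d)]
    n_c <- length(reach) + 1L
    if (n_c >= 2L)
      out[i] <- ((n_c - 1) / (n - 1)) * ((n_c - 1) / sum(reach))
  }
  out
}
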