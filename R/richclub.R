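# Rich-club coefficient, null-normalization, regime calling and significance.

# counts of values strictly greater than each k in `ks` (values are positive
# integers; O(max(values)) rather than O(length(ks) * length(values)))
count_above <- function(values, ks) {
  if (!length(values)) return(integer(length(ks)))
  tab <- tabulate(values, nbins = max(values))
  tot <- rev(cumsum(rev(tab)))          # tot[j] = #values >= j
  vapply(ks, function(k)
    if (k + 1L <= length(tot)) tot[k + 1L] else 0L, integer(1L))
}

# phi(k) for a vector of ks; NA where fewer than 2 nodes exceed k
phi_vector <- function(net, ks) {
  deg <- igraph::degree(net)
  n_above <- count_above(deg, ks)
  if (igraph::ecount(net)) {
    e <- igraph::as_edgelist(net, names = FALSE)
    min_deg <- pmin(deg[e[, 1L]], deg[e[, 2L]])
    e_above <- count_above(min_deg, ks)
  } else {
    e_above <- integer(length(ks))
  }
  phi <- ifelse(n_above >= 2L,
                2 * e_above / (n_above * (n_above - 1)), NA_real_)
  list(phi = phi, n_above = n_above, e_above = e_above)
}

#' Rich-club coefficient at a single degree cutoff
#'
#' With `S` the set of nodes of degree strictly greater than `k`,
#' `phi(k) = 2 |E(S)| / (|S| (|S| - 1))`: the fraction of possible
#' interactions realized among the nodes richer than `k`.
#'
#' @param net An undirected `igraph` network.
#' @param k Non-negative degree cutoff.
#' @return `phi(k)` in `[0, 1]`, or `NA` when fewer than two nodes have
#'   degree above `k` (undefined, by convention an explicit value rather than
#'   an error).
#' @export
rich_club_phi <- function(net, k) {
  assert_network(net)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0)
    stop("`k` must be a single non-negative degree", call. = FALSE)
  phi_vector(net, as.integer(k))$phi
}

#' Normalized rich-club profile
#'
#' Computes `phi(k)` for every `k` from 0 to the maximum degree minus one,
#' the null mean and standard deviation of `phi(k)` over a degree-preserving
#' ensemble, and the normalized coefficient
#' `rho(k) = phi(k) / phi_random(k)`. `rho(k) > 1` over a degree range
#' signals rich-club organization: the hubs are more densely interconnected
#' than degree-matched chance.
#'
#' @param net An undirected `igraph` network.
#' @param ensemble A [make_null_ensemble()] built from `net` (the members'
#'   degree sequences must match).
#' @return A `rich_club_profile` object: data-frame-like list with `k`,
#'   `phi`, `phi_rand_mean`, `phi_rand_sd`, `rho`, `n_above`, `e_above`, plus
#'   the per-member null `phi` matrix in `null_phi` (members x k) used for
#'   significance testing.
#' @export
rich_club_profile <- function(net, ensemble) {
  assert_network(net)
  assert_ensemble(ensemble)
  deg <- igraph::degree(net)
  if (!identical(sort(unname(deg)), unname(ensemble$degree_sequence)))
    stop("`ensemble` was not built from `net` (degree sequences differ)",
         call. = FALSE)
  max_deg <- max(deg, 0L)
  if (max_deg < 1L)
    stop("network has no edges; rich-club profile undefined", call. = FALSE)
  ks <- 0:(max_deg - 1L)
  obs <- phi_vector(net, ks)
  null_phi <- t(vapply(ensemble$members,
                       function(g) phi_vector(g, ks)$phi,
                       numeric(length(ks))))
  phi_rand_mean <- colMeans(null_phi)
  phi_rand_sd <- apply(null_phi, 2L, sd)
  rho <- ifelse(!is.na(obs$phi) & !is.na(phi_rand_mean) & phi_rand_mean > 0,
                obs$phi / phi_rand_mean, NA_real_)
  structure(
    list(k = ks, phi = obs$phi, phi_rand_mean = phi_rand_mean,
         phi_rand_sd = phi_rand_sd, rho = rho,
         n_above = obs$n_above, e_above = obs$e_above,
         null_phi = null_phi, n_null = length(ensemble$members)),
    class = "rich_club_profile")
}

#' @export
print.rich_club_profile <- function(x, ...) {
  defined <- sum(!is.na(x$rho))
  cat(sprintf("Rich-club profile: k = %d..%d (%d defined), %d nulls\n",
              min(x$k), max(x$k), defined, x$n_null))
  if (defined)
    cat(sprintf("  max rho = %.3f at k = %d\n",
                max(x$rho, na.rm = TRUE), x$k[which.max(x$rho)]))
  invisible(x)
}

#' @export
as.data.frame.rich_club_profile <- function(x, ...) {
  data.frame(k = x$k, phi = x$phi, phi_rand_mean = x$phi_rand_mean,
             phi_rand_sd = x$phi_rand_sd, rho = x$rho,
             n_above = x$n_above, e_above = x$e_above)
}

#' Detect the rich-club regime
#'
#' The regime is the longest contiguous run of degrees with
#' `rho(k) > rho_min` (ties resolved toward the lowest `k`); `NULL` when no
#' degree qualifies. Undefined `rho` values break a run.
#'
#' @param profile A [rich_club_profile()].
#' @param rho_min Threshold on the normalized coefficient (default 1).
#' @return Integer `c(k_lo, k_hi)` (inclusive) or `NULL`.
#' @export
detect_regime <- function(profile, rho_min = 1) {
  if (!inherits(profile, "rich_club_profile"))
    stop("`profile` must be a rich_club_profile", call. = FALSE)
  ok <- !is.na(profile$rho) & profile$rho > rho_min
  if (!any(ok)) return(NULL)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  true_runs <- which(r$values)
  best <- true_runs[which.max(r$lengths[true_runs])]  # ties -> first = lowest k
  c(k_lo = profile$k[starts[best]], k_hi = profile$k[ends[best]])
}

# one-sided one-sample t-test p-value: H1 "observed exceeds the null mean"
phi_exceedance_p <- function(null_values, observed) {
  null_values <- null_values[!is.na(null_values)]
  if (length(null_values) < 2L) return(NA_real_)
  if (sd(null_values) == 0) {
    warning("zero null variance; p set by direct comparison")
    return(if (observed > null_values[1L]) 0 else 1)
  }
  t.test(null_values, mu = observed, alternative = "less")$p.value
}

#' Significance of the rich-club regime
#'
#' For every degree in the regime, a one-sided one-sample t-test asks whether
#' the observed `phi(k)` exceeds the null distribution of `phi(k)` across the
#' ensemble members. The pooled p-value is the arithmetic mean of the per-k
#' p-values across the regime (the "average p-value across the rich-club
#' range" convention).
#'
#' @param profile A [rich_club_profile()].
#' @param regime Integer `c(k_lo, k_hi)`; defaults to
#'   [detect_regime()] on `profile`.
#' @param rho_min Passed to [detect_regime()] when `regime` is missing.
#' @return List with `p_per_k` (named by degree), `p_pooled`, and the
#'   `regime` used. When no regime exists, `p_per_k` is empty and `p_pooled`
#'   is `NA`.
#' @export
regime_significance <- function(profile, regime = NULL, rho_min = 1) {
  if (!inherits(profile, "rich_club_profile"))
    stop("`profile` must be a rich_club_profile", call. = FALSE)
  if (is.null(regime)) regime <- detect_regime(profile, rho_min)
  if (is.null(regime))
    return(list(p_per_k = numeric(0L), p_pooled = NA_real_, regime = NULL))
  ks <- regime[1L]:regime[2L]
  idx <- match(ks, profile$k)
  if (anyNA(idx))
    stop("`regime` lies outside the profile's degree range", call. = FALSE)
  p <- vapply(seq_along(ks), function(i)
    phi_exceedance_p(profile$null_phi[, idx[i]], profile$phi[idx[i]]),
    numeric(1L))
  names(p) <- ks
  list(p_per_k = p, p_pooled = mean(p, na.rm = TRUE), regime = regime)
}

#' Rich-club membership
#'
#' Members are the nodes whose degree exceeds the lower bound of the detected
#' regime.
#'
#' @param net An undirected `igraph` network.
#' @param regime Integer `c(k_lo, k_hi)` from [detect_regime()], or `NULL`.
#' @return Character vector of member node names (empty when `regime` is
#'   `NULL`).
#' @export
club_members <- function(net, regime) {
  assert_network(net)
  if (is.null(regime)) return(character(0L))
  deg <- igraph::degree(net)
  names(deg)[deg > regime[1L]]
}
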