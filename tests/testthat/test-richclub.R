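# Rich-club coefficient, normalization, regime calling and significance.

test_that("phi matches closed forms and hand enumeration", {
  expect_equal(rich_club_phi(complete_graph(5), 2), 1)
  expect_true(is.na(rich_club_phi(star_graph(4), 1)))
  g <- make_network(c("a", "a", "a", "b", "c", "d"),
                    c("b", "c", "d", "d", "d", "e"))
  expect_equal(rich_club_phi(g, 1), 10 / 12)
  expect_error(rich_club_phi(g, -1), "non-negative")
})

test_that("phi equals brute-force recomputation on random graphs", {
  for (s in 1:15) {
    g <- random_test_graph(n = 6L + (s %% 7L), p = 0.4, seed = 300 + s)
    A <- oracle_adjacency(g)
    for (k in 0:max(rowSums(A))) {
      expect_equal(rich_club_phi(g, k), oracle_phi(A, k),
                   info = sprintf("seed %d k %d", s, k))
    }
  }
})

test_that("profile rho is ~1 against a self-null and exactly 1 on cliques", {
  base <- gen_scale_free(300, 3, seed = 11)
  net <- rewire_preserving_degrees(base, seed = 99)
  ens <- make_null_ensemble(net, n = 100, seed = 5)
  prof <- rich_club_profile(net, ens)
  well <- prof$n_above >= 20 & !is.na(prof$rho)
  expect_true(any(well))
  expect_lt(abs(mean(prof$rho[well]) - 1), 0.1)

  k6 <- complete_graph(6)
  ens_k <- make_null_ensemble(k6, n = 5, seed = 1)
  prof_k <- rich_club_profile(k6, ens_k)
  expect_true(all(abs(prof_k$rho[!is.na(prof_k$rho)] - 1) < 1e-12))
})

test_that("profile rejects a mismatched ensemble and empty graphs", {
  g <- random_test_graph(20, 0.3, seed = 2)
  other <- random_test_graph(21, 0.3, seed = 3)
  ens <- make_null_ensemble(other, n = 3, seed = 1)
  expect_error(rich_club_profile(g, ens), "degree sequences differ")
  empty <- make_network(character(0), character(0), nodes = c("a", "b"))
  ens2 <- structure(list(members = list(empty),
                         degree_sequence = c(a = 0, b = 0), seed = 1L,
                         swaps_per_edge = 10),
                    class = "null_ensemble")
  expect_error(rich_club_profile(empty, ens2), "no edges")
})

test_that("regime detection returns the longest contiguous run, lowest-k on ties", {
  fake <- structure(list(k = 1:5, rho = c(0.9, 1.2, 1.3, 1.1, 0.8)),
                    class = "rich_club_profile")
  expect_equal(unname(detect_regime(fake)), c(2L, 4L))
  fake$rho <- c(1.1, 0.9, 1.05, NA, 1.2)
  expect_equal(unname(detect_regime(fake)), c(1L, 1L))
  fake$rho <- rep(0.7, 5)
  expect_null(detect_regime(fake))
})

test_that("per-k significance equals the closed-form one-sample t tail", {
  nulls <- c(0.10, 0.12, 0.11, 0.13)
  obs <- 0.30
  t_stat <- (mean(nulls) - obs) / (sd(nulls) / sqrt(4))
  p_expected <- pt(t_stat, df = 3)
  fake <- structure(
    list(k = 1L, phi = obs, null_phi = matrix(nulls, ncol = 1),
         rho = 2), class = "rich_club_profile")
  sig <- regime_significance(fake, regime = c(1L, 1L))
  expect_equal(unname(sig$p_per_k), p_expected)
  expect_equal(sig$p_pooled, p_expected)
  # centered null: p ~ 0.5
  fake$phi <- mean(nulls)
  sig2 <- regime_significance(fake, regime = c(1L, 1L))
  expect_lt(abs(sig2$p_pooled - 0.5), 0.01)
  # zero-variance null: direct comparison with a warning
  fake$null_phi <- matrix(rep(0.1, 4), ncol = 1)
  fake$phi <- 0.3
  expect_warning(sig3 <- regime_significance(fake, regime = c(1L, 1L)),
                 "zero null variance")
  expect_equal(unname(sig3$p_per_k), 0)
})

test_that("no regime yields an NA pooled p and empty membership", {
  fake <- structure(list(k = 1:3, rho = c(0.5, 0.6, 0.7)),
                    class = "rich_club_profile")
  sig <- regime_significance(fake)
  expect_null(sig$regime)
  expect_true(is.na(sig$p_pooled))
  expect_identical(club_members(star_graph(4), NULL), character(0))
})

test_that("club membership is degree > k_lo", {
  s4 <- star_graph(4)
  expect_identical(club_members(s4, c(1L, 1L)), "hub")
})

test_that("the planted rich club is detected and recovered", {
  pn <- gen_planted_club(n = 300, club_size = 30, p_in = 0.8, p_out = 0.02,
                         seed = 42)
  ens <- make_null_ensemble(pn$network, n = 100, seed = 1)
  prof <- rich_club_profile(pn$network, ens)
  regime <- detect_regime(prof)
  expect_false(is.null(regime))
  expect_gt(max(prof$rho[!is.na(prof$rho)]), 1)
  sig <- regime_significance(prof, regime)
  expect_lt(sig$p_pooled, 0.05)
  members <- club_members(pn$network, regime)
  expect_gte(mean(pn$club %in% members), 0.9)
})

test_that("club members are more frequently reported when frequency tracks degree", {
  pn <- gen_planted_club(seed = 7)
  deg <- igraph::degree(pn$network)
  mp <- gen_meta_proteome(n = length(deg), mean_freq = 10.5, seed = 3,
                          degrees = deg)
  freq <- stats::setNames(mp$frequency, mp$accession)
  in_club <- names(freq) %in% pn$club
  expect_gt(mean(freq[in_club]), mean(freq[!in_club]))
})
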