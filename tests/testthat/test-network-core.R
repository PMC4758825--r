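test_that("simple ratio index matches hand counts on the 4-group fixture", {
  s <- obs_stream(list(c("A", "B"), c("A", "B"), "A", "B"),
                  roster = c("A", "B", "C"))
  net <- build_sri_network(s)
  expect_identical(net$roster, c("A", "B", "C"))
  expect_equal(net$weights["A", "B"], 0.5)    # 2 / (2 + 0 + 1 + 1)
  expect_equal(net$weights["A", "C"], 0)      # 0 / 3, zero-denominator guard
  expect_equal(diag(net$weights), setNames(rep(0, 3), net$roster))

  always <- obs_stream(rep(list(c("A", "B")), 6))
  expect_equal(build_sri_network(always)$weights["A", "B"], 1)

  expect_error(build_sri_network(obs_stream(list(), roster = "A")), "empty")
})

test_that("period-mode SRI distinguishes co-presence from association", {
  ids <- c("A", "B", "C")
  m0 <- matrix(0L, 3, 3, dimnames = list(ids, ids))
  both <- m0; both["A", "B"] <- both["B", "A"] <- 1L
  # A-C and B-C associate, so all three are "observed", but A-B are apart
  apart <- m0; apart["A", "C"] <- apart["C", "A"] <- 1L
  apart["B", "C"] <- apart["C", "B"] <- 1L
  s <- obs_stream(list(both, both, apart), roster = ids, mode = "period")
  net <- build_sri_network(s)
  # x = 2, y_AB = 1 (both active in period 3 but not together)
  expect_equal(net$weights["A", "B"], 2 / 3)
  # C active only in period 3, together with A there: x = 1, y_A = 2
  expect_equal(net$weights["A", "C"], 1 / 3)
})

test_that("SRI is permutation-equivariant and invariant to duplicating units", {
  set.seed(11)
  for (i in 1:5) {
    s <- random_group_stream(n_ids = 9, n_groups = 25)
    w <- build_sri_network(s)$weights
    perm <- sample(s$roster)
    s_perm <- obs_stream(s$units, roster = perm)
    expect_equal(build_sri_network(s_perm)$weights[s$roster, s$roster], w)
    s_dup <- obs_stream(c(s$units, s$units), roster = s$roster)
    expect_equal(build_sri_network(s_dup)$weights, w)
  }
})

test_that("weighted modularity matches hand values and independent oracles", {
  w <- matrix(0, 6, 6, dimnames = rep(list(letters[1:6]), 2))
  w[1:3, 1:3] <- 1; w[4:6, 4:6] <- 1; diag(w) <- 0
  net <- assoc_network(w)
  expect_equal(modularity_q(net, c(1, 1, 1, 2, 2, 2)), 0.5)
  expect_equal(modularity_q(net, rep(1, 6)), 0)

  set.seed(21)
  for (i in 1:20) {
    wm <- random_weight_matrix(8)
    net <- assoc_network(wm)
    labels <- sample.int(3, 8, replace = TRUE)
    q <- modularity_q(net, labels)
    expect_equal(q, oracle_modularity(wm, labels), tolerance = 1e-12)
    g <- igraph::graph_from_adjacency_matrix(wm, mode = "undirected", weighted = TRUE)
    expect_equal(q, igraph::modularity(g, labels, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("Q is invariant under relabelling and 0 on weightless networks", {
  set.seed(31)
  wm <- random_weight_matrix(7)
  net <- assoc_network(wm)
  labels <- sample.int(3, 7, replace = TRUE)
  relab <- c(3, 1, 2)[labels]   # permute community names
  expect_equal(modularity_q(net, labels), modularity_q(net, relab))

  zero <- assoc_network(matrix(0, 3, 3, dimnames = rep(list(c("x", "y", "z")), 2)))
  expect_warning(q <- modularity_q(zero, 1:3), "zero total weight")
  expect_identical(q, 0)
})

test_that("community detection recovers planted structure and handles isolates", {
  # two unit-weight triangles: the exhaustive maximum-Q partition is the cliques
  w <- matrix(0, 6, 6, dimnames = rep(list(letters[1:6]), 2))
  w[1:3, 1:3] <- 1; w[4:6, 4:6] <- 1; diag(w) <- 0
  part <- detect_communities(assoc_network(w))
  best <- oracle_best_partition(w)
  expect_equal(part$c, 2L)
  expect_equal(part$Q, best$Q, tolerance = 1e-12)
  expect_identical(unname(part$labels[1:3]), rep(part$labels[[1]], 3))
  expect_identical(unname(part$labels[4:6]), rep(part$labels[[4]], 3))

  # complete graph with equal weights: one community is optimal
  k5 <- matrix(0.4, 5, 5, dimnames = rep(list(paste0("k", 1:5)), 2))
  diag(k5) <- 0
  expect_equal(detect_communities(assoc_network(k5))$c, 1L)

  # an isolate forms its own singleton community
  w7 <- rbind(cbind(w, 0), 0)
  dimnames(w7) <- rep(list(c(letters[1:6], "iso")), 2)
  part7 <- detect_communities(assoc_network(w7))
  expect_equal(part7$c, 3L)
  expect_equal(sum(part7$labels == part7$labels[["iso"]]), 1L)
})

test_that("detected partitions are self-consistent and deterministic", {
  set.seed(41)
  for (i in 1:10) {
    net <- assoc_network(random_weight_matrix(8))
    p1 <- detect_communities(net)
    p2 <- detect_communities(net)
    expect_identical(p1$labels, p2$labels)
    expect_equal(p1$Q, modularity_q(net, p1$labels), tolerance = 1e-12)
    expect_true(p1$Q >= -0.5 && p1$Q <= 1)
  }
  single <- assoc_network(matrix(0, 1, 1, dimnames = list("solo", "solo")))
  p <- detect_communities(single)
  expect_equal(p$c, 1L)
  expect_identical(p$Q, 0)
})
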