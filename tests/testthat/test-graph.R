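test_that("complete edge count follows n(n-1)/2", {
  expect_equal(complete_edge_count(28), 378)
  expect_equal(complete_edge_count(1), 0)
  expect_equal(complete_edge_count(5), 10)
  expect_error(complete_edge_count(0), "positive")
})

test_that("strength sums incident weights", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.3
  W[1, 3] <- W[3, 1] <- 0.4
  expect_equal(strength(W), c(0.7, 0.3, 0.4))
  W6 <- random_W(6, seed = 11)
  expect_equal(strength(W6),
               vapply(1:6, function(i) sum(W6[i, ]), numeric(1)))
  expect_error(strength(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("distance map is D = 1 - W with unreachable markers", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.7
  D <- distance_matrix(W)
  expect_equal(D[1, 2], 0.3)
  expect_equal(D[1, 3], Inf)
  expect_equal(unname(diag(D)), rep(0, 3))
  W[1, 3] <- W[3, 1] <- 1
  expect_error(distance_matrix(W), "< 1")
})

test_that("shortest paths prefer light multi-hop routes", {
  ## path A-B-C
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.7
  W[2, 3] <- W[3, 2] <- 0.7
  sp <- shortest_paths_matrix(distance_matrix(W))
  expect_equal(sp[1, 3], 0.6)
  ## triangle: indirect 0.3 + 0.3 beats direct 0.9
  W2 <- matrix(0, 3, 3)
  W2[1, 2] <- W2[2, 1] <- 0.7
  W2[2, 3] <- W2[3, 2] <- 0.7
  W2[1, 3] <- W2[3, 1] <- 0.1
  sp2 <- shortest_paths_matrix(distance_matrix(W2))
  expect_equal(sp2[1, 3], 0.6)
  ## disconnected pair flagged unreachable
  W3 <- diag(0, 4)
  W3[1, 2] <- W3[2, 1] <- 0.5
  expect_equal(shortest_paths_matrix(distance_matrix(W3))[1, 3], Inf)
})

test_that("paths, betweenness, efficiency match exhaustive oracles", {
  for (s in 1:20) {
    n <- sample(4:7, 1)
    W <- random_W(n, density = runif(1, 0.3, 0.9), seed = 400 + s)
    D <- distance_matrix(W)
    expect_equal(unname(shortest_paths_matrix(D)), bf_shortest_paths(D),
                 tolerance = 1e-10)
    expect_equal(betweenness_w(D), bf_betweenness(D), tolerance = 1e-8)
    expect_equal(global_efficiency(D), bf_global_efficiency(D),
                 tolerance = 1e-10)
  }
  ## middle of a 3-node path carries the only geodesic
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- 0.5
  expect_equal(betweenness_w(distance_matrix(W)), c(0, 1, 0))
  ## complete equal-weight graph has no intermediaries
  W4 <- matrix(0.5, 4, 4); diag(W4) <- 0
  expect_equal(betweenness_w(distance_matrix(W4)), rep(0, 4))
  ## two nodes, W = 0.5: efficiency = 1/0.5
  W2 <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_equal(global_efficiency(distance_matrix(W2)), 2)
  expect_equal(global_efficiency(distance_matrix(diag(0, 3))), 0)
})

test_that("Louvain finds planted cliques and verifies its own Q", {
  ## two 4-cliques, unit weights, no inter-clique edges
  W <- matrix(0, 8, 8)
  for (i in 1:4) for (j in 1:4) if (i != j) {
    W[i, j] <- 1
    W[i + 4, j + 4] <- 1
  }
  part <- louvain_partition(W, seed = 1, restarts = 20)
  expect_equal(length(unique(part$assignment)), 2)
  expect_equal(part$assignment[1:4], rep(part$assignment[1], 4))
  expect_equal(part$assignment[5:8], rep(part$assignment[5], 4))
  expect_equal(part$q_value, 0.5)
  ## q_value always equals direct re-evaluation
  expect_equal(part$q_value, modularity_q(W, part$assignment), tolerance = 1e-12)
  ## planted recovery is stable across seeds
  for (s in 2:6)
    expect_equal(louvain_partition(W, seed = s, restarts = 20)$q_value, 0.5)
  ## single-edge graph: endpoints share a module
  W1 <- matrix(0, 3, 3); W1[1, 2] <- W1[2, 1] <- 0.5
  p1 <- louvain_partition(W1, seed = 1, restarts = 5)
  expect_equal(p1$assignment[1], p1$assignment[2])
  expect_error(louvain_partition(diag(0, 4)), "no edges")
})

test_that("Louvain with restarts attains the exhaustive-search optimum (n <= 8)", {
  for (s in 1:10) {
    n <- sample(5:8, 1)
    W <- random_W(n, density = runif(1, 0.4, 0.9), seed = 500 + s)
    part <- louvain_partition(W, seed = s, restarts = 60)
    best <- bf_best_modularity(W)
    expect_gte(part$q_value, best - 1e-9)
    expect_equal(part$q_value, bf_modularity(W, part$assignment),
                 tolerance = 1e-12)
  }
})

test_that("modularity formula agrees with the independent direct version", {
  set.seed(6)
  for (k in 1:20) {
    W <- random_W(6, seed = 600 + k)
    memb <- sample(3, 6, replace = TRUE)
    expect_equal(modularity_q(W, memb), bf_modularity(W, memb),
                 tolerance = 1e-12)
    g <- sample(c(0.5, 1, 1.6), 1)
    expect_equal(modularity_q(W, memb, g), bf_modularity(W, memb, g),
                 tolerance = 1e-12)
  }
})

test_that("assortativity matches direct edge-list correlation", {
  ## star: hub links to leaves only -> disassortative
  W <- matrix(0, 5, 5)
  W[1, 2:5] <- W[2:5, 1] <- c(0.4, 0.5, 0.6, 0.7)
  expect_lt(assortativity_w(W), 0)
  ## random graph vs direct computation
  for (s in 1:10) {
    W6 <- random_W(6, seed = 700 + s)
    st <- rowSums(W6)
    ut <- which(upper.tri(W6) & W6 > 0, arr.ind = TRUE)
    ref <- cor(c(st[ut[, 1]], st[ut[, 2]]), c(st[ut[, 2]], st[ut[, 1]]))
    expect_equal(assortativity_w(W6), ref, tolerance = 1e-12)
  }
  ## equal strengths: undefined, flagged
  Wr <- matrix(0, 4, 4)
  Wr[1, 2] <- Wr[2, 1] <- Wr[3, 4] <- Wr[4, 3] <- 0.5
  a <- assortativity_w(Wr)
  expect_true(is.na(a))
  expect_true(attr(a, "undefined"))
})

test_that("weighted clustering and small-world behave on reference shapes", {
  ## triangle-free graph: C = 0
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- W[3, 4] <- W[4, 3] <- 0.5
  expect_equal(clustering_w(W), rep(0, 4))
  ## ring lattice with strong local weights is more clustered than random
  n <- 16
  Wl <- matrix(0, n, n)
  for (i in seq_len(n)) for (d in 1:2) {
    j <- ((i + d - 1) %% n) + 1
    Wl[i, j] <- Wl[j, i] <- ifelse(d == 1, 0.8, 0.6)
  }
  sw <- small_world_indices(Wl, n_random = 10, seed = 3)
  expect_gt(sw$C / sw$C_rand, 1)
  ## an unstructured random graph sits near sigma = 1
  set.seed(8)
  Wr <- random_W(20, density = 0.3, seed = 8)
  swr <- small_world_indices(Wr, n_random = 15, seed = 4)
  expect_equal(swr$sigma, 1, tolerance = 0.35)
})

test_that("graph metrics are permutation equivariant", {
  W <- random_W(7, seed = 900)
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  Wp <- W[perm, perm]
  expect_equal(strength(Wp), strength(W)[perm])
  expect_equal(betweenness_w(distance_matrix(Wp)),
               betweenness_w(distance_matrix(W))[perm], tolerance = 1e-10)
  expect_equal(global_efficiency(distance_matrix(Wp)),
               global_efficiency(distance_matrix(W)), tolerance = 1e-12)
  expect_equal(clustering_w(Wp), clustering_w(W)[perm], tolerance = 1e-12)
})
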