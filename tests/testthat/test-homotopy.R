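test_that("strongest-link selection follows per-node argmax with documented ties", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.8
  W[1, 3] <- W[3, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- 0.6
  partners <- strongest_link_per_node(W)
  expect_equal(as.integer(partners), c(2L, 1L, 2L))
  ## single edge: that edge is selected
  W1 <- matrix(0, 3, 3); W1[2, 3] <- W1[3, 2] <- 0.4
  expect_warning(p1 <- strongest_link_per_node(W1), "isolated")
  expect_true(is.na(p1[1]))
  expect_equal(as.integer(p1[2:3]), c(3L, 2L))
  ## exact tie: lowest index wins, tie flagged
  Wt <- matrix(0, 3, 3)
  Wt[1, 2] <- Wt[2, 1] <- 0.5
  Wt[1, 3] <- Wt[3, 1] <- 0.5
  pt <- strongest_link_per_node(Wt)
  expect_equal(as.integer(pt[1]), 2L)
  expect_true(attr(pt, "ties")[1])
})

test_that("anchoring counts paired nodes whose strongest link is homotopic", {
  nd <- default_nodeset()
  n <- 28
  h <- homolog_of(nd)
  ## planted maximum on every homotopic edge
  set.seed(10)
  W <- matrix(runif(n * n, 0, 0.3), n, n)
  W[lower.tri(W)] <- 0; W <- W + t(W); diag(W) <- 0
  W[nd$pair_map] <- 0.9; W[nd$pair_map[, 2:1]] <- 0.9
  a <- anchoring_count(strongest_link_per_node(W), nd)
  expect_equal(a$anchored, 24)
  expect_equal(a$total_paired, 24)
  expect_equal(a$unique_homotopic_links, 12)
  ## remove homotopic dominance entirely
  W2 <- W
  W2[nd$pair_map] <- 0; W2[nd$pair_map[, 2:1]] <- 0
  a2 <- anchoring_count(strongest_link_per_node(W2), nd)
  expect_equal(a2$anchored, 0)
  ## anchoring invariant under strictly monotone weight transforms
  expect_equal(anchoring_count(strongest_link_per_node(tanh(W)), nd)$anchored,
               a$anchored)
  expect_equal(anchoring_count(strongest_link_per_node(W^3), nd)$anchored,
               a$anchored)
})

test_that("module pairing and symmetry ratios count co-located homologs", {
  nd <- default_nodeset()
  ## every pair split across modules
  split <- integer(28)
  split[nd$pair_map[, 1]] <- 1; split[nd$pair_map[, 2]] <- 2
  split[is.na(homolog_of(nd))] <- 1
  expect_equal(module_pairing(split, nd)$pairs_colocated, 0)
  expect_equal(unname(symmetry_ratios(split, nd)$totals), c(0, 28))
  ## single module: all 12 pairs co-located, totals 24/28
  one <- rep(1L, 28)
  expect_equal(module_pairing(one, nd)$pairs_colocated, 12)
  expect_equal(unname(symmetry_ratios(one, nd)$totals), c(24, 28))
  ## partition co-locating 8 of 12 pairs: totals 16/28
  part8 <- split
  part8[as.vector(nd$pair_map[1:8, ])] <- 3
  sr <- symmetry_ratios(part8, nd)
  expect_equal(module_pairing(part8, nd)$pairs_colocated, 8)
  expect_equal(unname(sr$totals), c(16, 28))
  ## K = 2 x pairs_colocated for random partitions
  set.seed(11)
  for (k in 1:25) {
    a <- sample(4, 28, replace = TRUE)
    expect_equal(unname(symmetry_ratios(a, nd)$totals["K"]),
                 2 * module_pairing(a, nd)$pairs_colocated)
  }
  ## direct brute-force comparison on a small node set
  nd6 <- small_nodeset(2, 2)
  for (k in 1:10) {
    a <- sample(3, 6, replace = TRUE)
    pm <- nd6$pair_map
    expect_equal(module_pairing(a, nd6)$pairs_colocated,
                 sum(a[pm[, 1]] == a[pm[, 2]]))
  }
})

test_that("exact anchoring null matches full rank-order enumeration (n = 4)", {
  nd4 <- small_nodeset(2)
  ex <- null_anchoring(nd4, observed = 2, mode = "exact")
  set.seed(12)
  ref_pmf <- bf_anchoring_pmf_enum(nd4)
  expect_equal(ex$pmf, ref_pmf, tolerance = 1e-12)
  ## expected per-node anchoring probability is 1/(n-1) = 1/3
  expect_equal(sum(0:4 * ex$pmf) / 4, 1 / 3, tolerance = 1e-12)
  ## p-values from the pmf
  expect_equal(null_anchoring(nd4, 0, mode = "exact")$p, 1)
  expect_equal(null_anchoring(nd4, 4, mode = "exact")$p, ref_pmf[5],
               tolerance = 1e-12)
})

test_that("exact anchoring null matches Monte-Carlo at n = 6 and 8", {
  set.seed(13)
  for (cfg in list(small_nodeset(3), small_nodeset(2, 2),
                   small_nodeset(4), small_nodeset(3, 2))) {
    ex <- null_anchoring(cfg, observed = 1, mode = "exact")
    B <- 20000
    draws <- vapply(seq_len(B), function(k) bf_anchoring_draw(cfg),
                    numeric(1))
    for (v in 0:(length(ex$pmf) - 1)) {
      phat <- mean(draws == v)
      se <- sqrt(max(ex$pmf[v + 1] * (1 - ex$pmf[v + 1]), 1e-9) / B)
      expect_lt(abs(phat - ex$pmf[v + 1]), 4 * se + 1e-6)
    }
  }
  expect_error(null_anchoring(small_nodeset(6), 1, mode = "exact"),
               "at most 10")
})

test_that("permutation anchoring null is valid and detects planted homotopy", {
  nd <- default_nodeset()
  ## planted saturation: minimal attainable p at 999 permutations
  res <- null_anchoring(nd, observed = 24, n_perm = 999, seed = 14)
  expect_lte(res$p, 0.001)
  expect_equal(null_anchoring(nd, 0, n_perm = 199, seed = 1)$p, 1)
  ## super-uniform p under data drawn from the null itself
  set.seed(15)
  ps <- vapply(1:200, function(k) {
    obs <- bf_anchoring_draw(nd)
    null_anchoring(nd, obs, n_perm = 199, seed = 2000 + k)$p
  }, numeric(1))
  expect_lte(mean(ps <= 0.05), 0.07)
  expect_gt(mean(ps), 0.4)
})

test_that("co-location null matches combinatorics and flags degeneracy", {
  nd4 <- small_nodeset(2)
  ex <- null_colocation(c(2, 2), nd4, observed = 1, mode = "exact")
  ## enumeration over all 4! label assignments
  ref <- bf_colocation_pmf_enum(c(2, 2), nd4)
  expect_equal(ex$pmf, ref, tolerance = 1e-12)
  ## P(a given pair co-located) = 1/3: E[count]/2 = 1/3
  expect_equal(sum(0:2 * ex$pmf) / 2, 1 / 3, tolerance = 1e-12)
  ## single all-node module: null always equals observed, p = 1
  nd <- default_nodeset()
  expect_equal(null_colocation(28, nd, observed = 12, n_perm = 199,
                               seed = 3)$p, 1)
  ## planted symmetric partition: p below 0.01
  sizes <- c(7, 7, 7, 7)
  pr <- null_colocation(sizes, nd, observed = 12, n_perm = 999, seed = 4)
  expect_lte(pr$p, 0.01)
  expect_error(null_colocation(c(5, 5), nd, 3), "sum")
  ## exact mode vs Monte-Carlo on 6 nodes
  nd6 <- small_nodeset(3)
  ex6 <- null_colocation(c(3, 3), nd6, observed = 0, mode = "exact")
  ref6 <- bf_colocation_pmf_enum(c(3, 3), nd6)
  expect_equal(ex6$pmf, ref6, tolerance = 1e-12)
})

test_that("homotopy report assembles consistent counts", {
  nd <- default_nodeset()
  set.seed(16)
  n <- 28
  W <- matrix(runif(n * n, 0, 0.3), n, n)
  W[lower.tri(W)] <- 0; W <- W + t(W); diag(W) <- 0
  W[nd$pair_map] <- 0.9; W[nd$pair_map[, 2:1]] <- 0.9
  part <- louvain_partition(W, seed = 1, restarts = 20)
  rep <- homotopy_report(W, part, nd, n_perm = 199, seed = 5)
  expect_s3_class(rep, "homotopy_report")
  expect_equal(rep$anchoring$anchored, 24)
  expect_equal(unname(rep$symmetry$totals["K"]),
               2 * rep$pairing$pairs_colocated)
  expect_lte(rep$p_anchoring, 0.005)
  expect_output(print(rep), "anchoring: 24 of 24")
})
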