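# Independent brute-force oracles and small fixtures. Everything here is
# deliberately naive (enumeration, direct formulas) and shares no code with
# the implementation under test.

# random connected-ish symmetric weight matrix with entries in (0, 0.95)
random_W <- function(n, density = 0.6, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- runif(length(ut)) < density
  ## spanning path keeps most fixtures connected
  for (i in seq_len(n - 1)) W[i, i + 1] <- runif(1, 0.05, 0.95)
  W[ut[on]] <- runif(sum(on), 0.05, 0.95)
  W[lower.tri(W)] <- 0
  W <- W + t(W)
  diag(W) <- 0
  W
}

# Benjamini-Hochberg step-up by the textbook rule
bf_bh <- function(p, q) {
  m <- length(p)
  if (!m) return(logical(0))
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(m) * q / m)
  k <- if (length(ok)) max(ok) else 0
  rej <- rep(FALSE, m)
  if (k > 0) rej[ord[seq_len(k)]] <- TRUE
  rej
}

# all simple paths i -> j by DFS; returns list of vertex sequences
.all_paths <- function(D, i, j) {
  n <- nrow(D)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == j) {
      out[[length(out) + 1]] <<- path
      return()
    }
    for (w in seq_len(n))
      if (is.finite(D[v, w]) && v != w && !(w %in% path))
        walk(c(path, w))
  }
  walk(i)
  out
}

path_cost <- function(D, path)
  sum(D[cbind(path[-length(path)], path[-1])])

# exhaustive shortest-path lengths
bf_shortest_paths <- function(D) {
  n <- nrow(D)
  out <- matrix(Inf, n, n)
  diag(out) <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ps <- .all_paths(D, i, j)
    if (length(ps))
      out[i, j] <- out[j, i] <- min(vapply(ps, path_cost, numeric(1),
                                           D = D))
  }
  out
}

# exhaustive betweenness with fractional shortest-path shares,
# normalised by (n-1)(n-2)/2
bf_betweenness <- function(D, tol = 1e-10) {
  n <- nrow(D)
  b <- numeric(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ps <- .all_paths(D, i, j)
    if (!length(ps)) next
    costs <- vapply(ps, path_cost, numeric(1), D = D)
    sp <- ps[costs <= min(costs) + tol]
    for (v in seq_len(n)) {
      if (v == i || v == j) next
      through <- sum(vapply(sp, function(p) v %in% p, logical(1)))
      b[v] <- b[v] + through / length(sp)
    }
  }
  b / ((n - 1) * (n - 2) / 2)
}

bf_global_efficiency <- function(D) {
  sp <- bf_shortest_paths(D)
  n <- nrow(D)
  inv <- 1 / sp
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

# direct modularity formula, written independently of modularity_q
bf_modularity <- function(W, memb, gamma = 1) {
  two_m <- sum(W)
  q <- 0
  for (c in unique(memb)) {
    idx <- memb == c
    e_c <- sum(W[idx, idx]) / 2
    a_c <- sum(W[idx, ])
    q <- q + e_c / (two_m / 2) - gamma * (a_c / two_m)^2
  }
  q
}

# all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(a, mx) {
    k <- length(a) + 1
    if (k > n) {
      out[[length(out) + 1]] <<- a
      return()
    }
    for (v in seq_len(mx + 1)) grow(c(a, v), max(mx, v))
  }
  grow(integer(0), 0)
  out
}

bf_best_modularity <- function(W, gamma = 1) {
  best <- -Inf
  for (memb in all_partitions(nrow(W))) {
    q <- bf_modularity(W, memb, gamma)
    if (q > best) best <- q
  }
  best
}

# all permutations of a vector
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (k in seq_along(v))
    for (rest in all_perms(v[-k])) out[[length(out) + 1]] <- c(v[k], rest)
  out
}

# small node sets with homotopic pairs for null-distribution oracles
small_nodeset <- function(n_pairs, n_unpaired = 0) {
  n <- 2 * n_pairs + n_unpaired
  labels <- paste0("r", seq_len(n))
  centers <- cbind(rep(c(-10, 10), length.out = n) * seq_len(n),
                   seq_len(n) * 20, 0)
  hemi <- c(rep(c("L", "R"), n_pairs), rep("L", n_unpaired))
  pm <- if (n_pairs) cbind(seq(1, 2 * n_pairs, 2), seq(2, 2 * n_pairs, 2))
        else matrix(integer(0), ncol = 2)
  nodeset(labels, centers, hemi, pm)
}

# anchoring count of one i.i.d.-weights draw on K_n (oracle version)
bf_anchoring_draw <- function(nodes) {
  n <- length(nodes$labels)
  h <- homolog_of(nodes)
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- runif(n * (n - 1) / 2)
  W <- W + t(W)
  partner <- apply(W, 1, which.max)
  paired <- which(!is.na(h))
  sum(partner[paired] == h[paired])
}

# exact anchoring pmf by full enumeration of edge-rank orderings (n = 4)
bf_anchoring_pmf_enum <- function(nodes) {
  n <- length(nodes$labels)
  stopifnot(n <= 4)
  h <- homolog_of(nodes)
  paired <- which(!is.na(h))
  eidx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cnt <- integer(length(paired) + 1)
  for (pp in all_perms(seq_len(nrow(eidx)))) {
    W <- matrix(0, n, n)
    W[eidx] <- pp
    W <- W + t(W)
    partner <- apply(W, 1, which.max)
    a <- sum(partner[paired] == h[paired])
    cnt[a + 1] <- cnt[a + 1] + 1
  }
  cnt / sum(cnt)
}

# exact co-location pmf by enumerating all label permutations
bf_colocation_pmf_enum <- function(module_sizes, nodes) {
  n <- length(nodes$labels)
  base <- rep(seq_along(module_sizes), module_sizes)
  pm <- nodes$pair_map
  cnt <- integer(nrow(pm) + 1)
  for (pp in all_perms(seq_len(n))) {
    a <- base[order(pp)]
    k <- sum(a[pm[, 1]] == a[pm[, 2]])
    cnt[k + 1] <- cnt[k + 1] + 1
  }
  cnt / sum(cnt)
}
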