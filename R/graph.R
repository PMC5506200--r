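.check_W <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (max(abs(W - t(W))) > 1e-10)
    stop("weight matrix must be symmetric", call. = FALSE)
  if (any(W < 0)) stop("weights must be non-negative", call. = FALSE)
  if (any(diag(W) != 0)) stop("diagonal must be zero", call. = FALSE)
  invisible(W)
}

.graph_from_D <- function(D) {
  n <- nrow(D)
  ut <- which(upper.tri(D) & is.finite(D), arr.ind = TRUE)
  igraph::graph_from_data_frame(
    data.frame(from = ut[, 1], to = ut[, 2], weight = D[ut]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
}

#' Edge count of the complete graph
#' @param n node count (>= 1).
#' @return n(n-1)/2.
#' @export
complete_edge_count <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("n must be a positive integer", call. = FALSE)
  as.integer(n * (n - 1) / 2)
}

#' Node strength (sum of incident edge weights)
#' @param W symmetric non-negative weight matrix, zero diagonal.
#' @return per-node strength vector.
#' @export
strength <- function(W) {
  .check_W(W)
  rowSums(W)
}

#' Weight-to-distance conversion D = 1 - W
#'
#' Edges (W > 0) get cost 1 - W; absent edges are marked unreachable (Inf);
#' the diagonal is 0. Requires weights strictly below 1 so costs stay
#' positive.
#'
#' @param W symmetric weight matrix with entries in [0, 1).
#' @return distance matrix D.
#' @export
distance_matrix <- function(W) {
  .check_W(W)
  if (any(W >= 1)) stop("weights must be < 1 for D = 1 - W", call. = FALSE)
  D <- ifelse(W > 0, 1 - W, Inf)
  diag(D) <- 0
  dimnames(D) <- dimnames(W)
  D
}

#' All-pairs shortest path lengths over edge costs D
#'
#' Dijkstra on the weighted graph whose edge costs are the finite
#' off-diagonal entries of D. Unreachable pairs are Inf.
#'
#' @param D distance matrix from \code{\link{distance_matrix}}.
#' @return pairwise geodesic length matrix.
#' @export
shortest_paths_matrix <- function(D) {
  g <- .graph_from_D(D)
  out <- igraph::distances(g, algorithm = "dijkstra")
  ord <- order(as.integer(rownames(out)))
  out <- out[ord, ord]
  dimnames(out) <- dimnames(D)
  out
}

#' Weighted betweenness centrality
#'
#' Brandes betweenness over edge costs D with fractional shortest-path
#' shares, normalised by the number of node pairs excluding the node,
#' (n-1)(n-2)/2.
#'
#' @param D distance matrix from \code{\link{distance_matrix}}.
#' @return per-node normalised betweenness in [0, 1].
#' @export
betweenness_w <- function(D) {
  n <- nrow(D)
  g <- .graph_from_D(D)
  b <- igraph::betweenness(g, directed = FALSE)
  b <- b[order(as.integer(names(b)))]
  unname(b) / ((n - 1) * (n - 2) / 2)
}

#' Global efficiency
#'
#' Mean over ordered node pairs of 1/d(i, j); unreachable pairs contribute
#' zero.
#'
#' @param D distance matrix from \code{\link{distance_matrix}}.
#' @return scalar efficiency.
#' @export
global_efficiency <- function(D) {
  n <- nrow(D)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  sp <- shortest_paths_matrix(D)
  inv <- 1 / sp
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted modularity of a partition
#'
#' Newman-Girvan weighted modularity with resolution \eqn{\gamma}:
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \left( W_{ij} -
#'   \gamma \frac{k_i k_j}{2m} \right) \delta(c_i, c_j)}
#' with \eqn{k} the node strengths and \eqn{2m} the total weight.
#'
#' @param W symmetric weight matrix.
#' @param membership integer module id per node.
#' @param gamma resolution parameter (default 1).
#' @return scalar Q.
#' @export
modularity_q <- function(W, membership, gamma = 1) {
  .check_W(W)
  k <- rowSums(W)
  two_m <- sum(W)
  if (two_m <= 0) stop("network has no edges", call. = FALSE)
  same <- outer(membership, membership, "==")
  sum((W - gamma * outer(k, k) / two_m)[same]) / two_m
}

# deterministic refinement: single-node moves and whole-module merges with
# incremental modularity gains; tie-break toward the lowest module id
.refine_partition <- function(W, membership, gamma) {
  n <- nrow(W)
  k <- rowSums(W)
  two_m <- sum(W)
  m <- two_m / 2
  repeat {
    improved <- FALSE
    ## single-node moves
    repeat {
      moved <- FALSE
      for (i in seq_len(n)) {
        a <- membership[i]
        ## weight from i into each module
        w_to <- tapply(W[i, ], membership, sum)
        mods <- as.integer(names(w_to))
        a_str <- tapply(k, membership, sum)[as.character(mods)]
        gain <- (w_to - w_to[as.character(a)]) / m -
          gamma * k[i] * (a_str - a_str[as.character(a)] + k[i]) / (2 * m^2)
        best <- which.max(gain)
        if (gain[best] > 1e-12) {
          membership[i] <- mods[best]
          moved <- TRUE
          improved <- TRUE
        }
      }
      if (!moved) break
    }
    ## whole-module merges
    mods <- sort(unique(membership))
    if (length(mods) > 1) {
      a_str <- vapply(mods, function(mm) sum(k[membership == mm]), numeric(1))
      e_between <- matrix(0, length(mods), length(mods))
      for (p in seq_along(mods)) for (q in seq_along(mods)) {
        if (p < q)
          e_between[p, q] <- sum(W[membership == mods[p],
                                   membership == mods[q]])
      }
      gains <- e_between / m -
        gamma * outer(a_str, a_str) / (2 * m^2)
      gains[lower.tri(gains, diag = TRUE)] <- -Inf
      if (max(gains) > 1e-12) {
        idx <- which(gains == max(gains), arr.ind = TRUE)[1, ]
        membership[membership == mods[idx[2]]] <- mods[idx[1]]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  membership
}

#' Louvain community detection with restarts
#'
#' Runs Louvain on the weighted graph under random node permutations
#' (\code{restarts} times), refines each result with a deterministic
#' single-node-move pass, and keeps the partition with the highest weighted
#' modularity. The returned \code{q_value} is recomputed from the assignment
#' with \code{\link{modularity_q}}, never taken on trust from the search.
#'
#' @param W symmetric weight matrix with at least one edge.
#' @param gamma resolution parameter (default 1).
#' @param seed RNG seed for the restarts.
#' @param restarts number of random restarts (default 100).
#' @return An object of class \code{partition}: list with \code{assignment}
#'   (module ids, contiguous from 1, relabelled in order of first
#'   appearance) and \code{q_value}.
#' @export
louvain_partition <- function(W, gamma = 1, seed = 1, restarts = 100) {
  .check_W(W)
  if (sum(W) <= 0) stop("network has no edges", call. = FALSE)
  n <- nrow(W)
  set.seed(as.integer(seed))
  best <- NULL; best_q <- -Inf
  for (r in seq_len(restarts)) {
    if (r %% 2 == 1) {
      ## Louvain on a randomly permuted copy of the graph
      perm <- if (r == 1) seq_len(n) else sample(n)
      Wp <- W[perm, perm]
      ut <- which(upper.tri(Wp) & Wp > 0, arr.ind = TRUE)
      g <- igraph::graph_from_data_frame(
        data.frame(from = ut[, 1], to = ut[, 2], weight = Wp[ut]),
        directed = FALSE, vertices = data.frame(name = seq_len(n)))
      cl <- igraph::cluster_louvain(g, resolution = gamma)
      memb <- igraph::membership(cl)
      memb <- memb[order(as.integer(names(memb)))]
      assignment <- integer(n)
      assignment[perm] <- as.integer(memb)
    } else {
      ## random K-way start; escapes merge-resistant local optima (a chain
      ## of pairwise merges can be downhill even when the merged partition
      ## is better)
      K <- sample(1:min(n, 8), 1)
      assignment <- sample(K, n, replace = TRUE)
    }
    assignment <- .refine_partition(W, assignment, gamma)
    qv <- modularity_q(W, assignment, gamma)
    if (qv > best_q + 1e-12) {
      best_q <- qv
      best <- assignment
    }
  }
  best <- as.integer(factor(best, levels = unique(best)))
  structure(list(assignment = best, q_value = best_q), class = "partition")
}

#' Weighted strength assortativity
#'
#' Pearson correlation, over edges (both orientations), between the
#' strengths of the two endpoints.
#'
#' @param W symmetric weight matrix with >= 2 edges.
#' @return coefficient in [-1, 1], or NA with attribute
#'   \code{undefined = TRUE} when endpoint strengths have zero variance.
#' @export
assortativity_w <- function(W) {
  .check_W(W)
  ut <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  if (nrow(ut) < 2) stop("need at least 2 edges", call. = FALSE)
  s <- rowSums(W)
  a <- c(s[ut[, 1]], s[ut[, 2]])
  b <- c(s[ut[, 2]], s[ut[, 1]])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  stats::cor(a, b)
}

#' Weighted clustering coefficient (geometric-mean triangle rule)
#'
#' Onnela et al. definition: with weights scaled by the network maximum,
#' \eqn{C_i = \frac{1}{k_i (k_i - 1)} \sum_{j \ne h}
#'   (\hat w_{ij} \hat w_{ih} \hat w_{jh})^{1/3}}
#' for nodes with degree >= 2, else 0.
#'
#' @param W symmetric weight matrix.
#' @return per-node clustering coefficients.
#' @export
clustering_w <- function(W) {
  .check_W(W)
  if (max(W) == 0) return(rep(0, nrow(W)))
  Wh <- (W / max(W))^(1 / 3)
  cyc <- diag(Wh %*% Wh %*% Wh)
  k <- rowSums(W > 0)
  ifelse(k >= 2, cyc / (k * (k - 1)), 0)
}

#' Characteristic path length
#'
#' Mean geodesic length over reachable ordered pairs. Unreachable pairs are
#' excluded; if any exist the result carries attribute
#' \code{disconnected = TRUE}.
#'
#' @param D distance matrix.
#' @return scalar L.
#' @export
char_path_length <- function(D) {
  sp <- shortest_paths_matrix(D)
  off <- sp[row(sp) != col(sp)]
  reach <- is.finite(off)
  L <- mean(off[reach])
  if (!all(reach)) attr(L, "disconnected") <- TRUE
  L
}

#' Small-world indices against degree-preserving random references
#'
#' C = mean weighted clustering, L = characteristic path length on
#' D = 1 - W. References preserve the degree sequence by edge rewiring
#' (10 iterations per edge) and reshuffle the observed weights over the
#' surviving edges. sigma = (C/C_rand) / (L/L_rand).
#'
#' @param W symmetric weight matrix.
#' @param n_random number of random reference networks (>= 10).
#' @param seed RNG seed.
#' @return list with C, L, C_rand, L_rand, sigma, and a disconnected flag.
#' @export
small_world_indices <- function(W, n_random = 20, seed = 1) {
  .check_W(W)
  stopifnot(n_random >= 10)
  set.seed(as.integer(seed))
  n <- nrow(W)
  C <- mean(clustering_w(W))
  L <- char_path_length(distance_matrix(W))
  disconnected <- isTRUE(attr(L, "disconnected"))
  wts <- W[upper.tri(W) & W > 0]
  ut <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ut[, 1], to = ut[, 2]), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  Cr <- Lr <- numeric(n_random)
  for (k in seq_len(n_random)) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * length(wts)))
    el <- igraph::as_edgelist(gr)
    Wr <- matrix(0, n, n)
    idx <- cbind(as.integer(el[, 1]), as.integer(el[, 2]))
    wperm <- sample(wts)
    Wr[idx] <- wperm
    Wr[idx[, 2:1]] <- wperm
    Cr[k] <- mean(clustering_w(Wr))
    Lr[k] <- as.numeric(char_path_length(distance_matrix(Wr)))
  }
  C_rand <- mean(Cr); L_rand <- mean(Lr)
  list(C = C, L = as.numeric(L), C_rand = C_rand, L_rand = L_rand,
       sigma = (C / C_rand) / (as.numeric(L) / L_rand),
       disconnected = disconnected)
}
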