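#' Strongest incident link per node
#'
#' For every node, the partner with the maximal incident edge weight (one
#' selection per node, so a single link may be selected by both endpoints).
#' Ties are broken toward the lowest partner index and flagged; isolated
#' nodes (all-zero row) get NA with a warning.
#'
#' @param W symmetric non-negative weight matrix, zero diagonal.
#' @return integer vector of partner indices with attribute \code{ties}
#'   (logical per node).
#' @export
strongest_link_per_node <- function(W) {
  .check_W(W)
  n <- nrow(W)
  partner <- rep(NA_integer_, n)
  ties <- rep(FALSE, n)
  for (i in seq_len(n)) {
    row <- W[i, ]
    if (all(row == 0)) next
    mx <- max(row)
    cand <- which(row == mx)
    partner[i] <- cand[1]
    ties[i] <- length(cand) > 1
  }
  if (anyNA(partner))
    warning("isolated node(s) excluded from strongest-link selection: ",
            paste(which(is.na(partner)), collapse = ", "))
  attr(partner, "ties") <- ties
  partner
}

#' Homotopic anchoring count
#'
#' Among homotopically paired nodes, counts those whose strongest link
#' connects to their contralateral homolog. Isolated paired nodes (NA
#' partner) are dropped from the denominator. Also reports the
#' deduplicated count of distinct homotopic links that are some node's
#' strongest, and the number of paired nodes touched by such links whether
#' or not they selected them.
#'
#' @param partners output of \code{\link{strongest_link_per_node}}.
#' @param nodes a \code{nodeset}.
#' @return list: \code{anchored}, \code{total_paired} (2 x number of pairs,
#'   minus isolated), \code{anchored_idx}, \code{unique_homotopic_links},
#'   \code{touched}.
#' @export
anchoring_count <- function(partners, nodes) {
  stopifnot(inherits(nodes, "nodeset"))
  h <- homolog_of(nodes)
  paired <- which(!is.na(h))
  valid <- paired[!is.na(partners[paired])]
  anchored_idx <- valid[partners[valid] == h[valid]]
  sel_pairs <- unique(t(apply(cbind(anchored_idx, h[anchored_idx]), 1, sort)))
  touched <- intersect(paired, unique(as.vector(sel_pairs)))
  list(anchored = length(anchored_idx),
       total_paired = length(valid),
       anchored_idx = anchored_idx,
       unique_homotopic_links = if (length(anchored_idx)) nrow(sel_pairs) else 0L,
       touched = length(touched))
}

#' Within-module homotopic pairing
#'
#' @param partition a \code{partition} (or integer assignment vector).
#' @param nodes a \code{nodeset}.
#' @return list: \code{pairs_colocated} (count of homotopic pairs with both
#'   members in the same module) and \code{pair_table}.
#' @export
module_pairing <- function(partition, nodes) {
  a <- if (inherits(partition, "partition")) partition$assignment else partition
  stopifnot(length(a) == length(nodes$labels))
  pm <- nodes$pair_map
  co <- a[pm[, 1]] == a[pm[, 2]]
  list(pairs_colocated = sum(co),
       pair_table = data.frame(i = pm[, 1], j = pm[, 2],
                               module_i = a[pm[, 1]], module_j = a[pm[, 2]],
                               colocated = co))
}

#' Per-module symmetry ratios
#'
#' For each module m, k_m = number of member nodes whose homotopic homolog
#' is also in m, and n_m = module size. Totals K = sum k_m (= 2 x
#' pairs_colocated) and N = sum n_m = node count.
#'
#' @param partition a \code{partition} (or assignment vector).
#' @param nodes a \code{nodeset}.
#' @return list: \code{per_module} data.frame (module, k, n, ratio) and
#'   \code{totals} (K, N).
#' @export
symmetry_ratios <- function(partition, nodes) {
  a <- if (inherits(partition, "partition")) partition$assignment else partition
  stopifnot(length(a) == length(nodes$labels))
  h <- homolog_of(nodes)
  sym <- rep(FALSE, length(a))
  idx <- which(!is.na(h))
  sym[idx] <- a[idx] == a[h[idx]]
  mods <- sort(unique(a))
  per <- data.frame(
    module = mods,
    k = vapply(mods, function(m) sum(sym[a == m]), integer(1)),
    n = vapply(mods, function(m) sum(a == m), integer(1)))
  per$ratio <- per$k / per$n
  list(per_module = per, totals = c(K = sum(per$k), N = sum(per$n)))
}

# anchored count per replicate under i.i.d. exchangeable weights on K_n
.anchoring_null_draw <- function(n, h, paired) {
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- stats::runif(n * (n - 1) / 2)
  W <- W + t(W)
  partner <- max.col(W, ties.method = "first")
  sum(partner[paired] == h[paired])
}

# exact P(all nodes in S anchor to their homolog) under i.i.d. weights.
# Inclusion of node i forces its homotopic edge above every other edge at i;
# the joint probability is an expectation over the top-edge values of a
# product of minima, evaluated by summing order-statistic integrals over all
# orderings of the top edges.
.anchor_joint_prob <- function(S, n, h) {
  if (!length(S)) return(1)
  edge_id <- function(i, j) paste(min(i, j), max(i, j))
  pairs <- unique(lapply(S, function(i) sort(c(i, h[i]))))
  t_n <- length(pairs)
  top_ids <- vapply(pairs, function(p) edge_id(p[1], p[2]), character(1))
  constraint <- list()   # non-top edge id -> indices of tops constraining it
  for (pi in seq_len(t_n)) {
    cov <- intersect(S, pairs[[pi]])
    for (i in cov) for (j in setdiff(seq_len(n), i)) {
      id <- edge_id(i, j)
      if (id %in% top_ids) next
      constraint[[id]] <- union(constraint[[id]], pi)
    }
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (k in seq_along(v))
      for (rest in perms(v[-k])) out <- c(out, list(c(v[k], rest)))
    out
  }
  total <- 0
  for (sigma in perms(seq_len(t_n))) {
    ## sigma[j] = which top has the j-th smallest value
    a <- numeric(t_n)
    for (tc in constraint) {
      pos <- min(match(tc, sigma))
      a[pos] <- a[pos] + 1
    }
    A <- cumsum(a)
    total <- total + prod(1 / (A + seq_len(t_n)))
  }
  total
}

# exact pmf of the anchoring count via binomial moments of joint events
.anchoring_exact_pmf <- function(nodes) {
  n <- length(nodes$labels)
  h <- homolog_of(nodes)
  paired <- which(!is.na(h))
  np <- length(paired)
  B <- numeric(np + 1)   # B[j+1] = sum over |S|=j of P(all of S anchored)
  B[1] <- 1
  for (j in seq_len(np)) {
    subs <- utils::combn(paired, j, simplify = FALSE)
    B[j + 1] <- sum(vapply(subs, .anchor_joint_prob, numeric(1),
                           n = n, h = h))
  }
  pmf <- numeric(np + 1)
  for (k in 0:np)
    pmf[k + 1] <- sum(vapply(k:np, function(j)
      (-1)^(j - k) * choose(j, k) * B[j + 1], numeric(1)))
  pmax(pmf, 0)
}

#' Chance null for the homotopic anchoring count
#'
#' Null model: edge weights of the complete graph on the node set are
#' i.i.d. exchangeable (only their ranks matter), so each node's strongest
#' partner carries no homotopic preference. \code{permute} mode redraws the
#' weights \code{n_perm} times and recomputes the anchoring count
#' (p = (1 + #\{null >= observed\}) / (1 + n_perm)); \code{exact} mode
#' evaluates the null distribution in closed form by inclusion-exclusion
#' over joint strongest-link events (feasible for n <= 10).
#'
#' @param nodes a \code{nodeset}.
#' @param observed observed anchoring count.
#' @param n_perm number of permutations (>= 100; permute mode).
#' @param seed RNG seed (permute mode).
#' @param mode \code{"permute"} or \code{"exact"}.
#' @return list: \code{p}, \code{mode}, and \code{null} (draws) or
#'   \code{pmf} (exact distribution over 0..n_paired).
#' @export
null_anchoring <- function(nodes, observed, n_perm = 999, seed = 1,
                           mode = c("permute", "exact")) {
  mode <- match.arg(mode)
  stopifnot(inherits(nodes, "nodeset"), observed >= 0)
  n <- length(nodes$labels)
  h <- homolog_of(nodes)
  paired <- which(!is.na(h))
  if (mode == "exact") {
    if (n > 10) stop("exact mode supports at most 10 nodes", call. = FALSE)
    pmf <- .anchoring_exact_pmf(nodes)
    p <- sum(pmf[(observed + 1):length(pmf)])
    if (observed == 0) p <- 1
    return(list(p = min(p, 1), pmf = pmf, mode = mode))
  }
  if (n_perm < 100) stop("need n_perm >= 100", call. = FALSE)
  set.seed(as.integer(seed))
  null <- vapply(seq_len(n_perm), function(k)
    .anchoring_null_draw(n, h, paired), numeric(1))
  list(p = (1 + sum(null >= observed)) / (1 + n_perm), null = null,
       mode = mode)
}

# all assignments of nodes into labeled modules of the given sizes
.enumerate_assignments <- function(nodes_left, sizes) {
  if (!length(nodes_left)) return(list(integer(0)))
  out <- list()
  first <- nodes_left[1]
  for (m in seq_along(sizes)) {
    if (sizes[m] == 0) next
    sizes2 <- sizes
    sizes2[m] <- sizes2[m] - 1
    for (rest in .enumerate_assignments(nodes_left[-1], sizes2)) {
      a <- integer(length(nodes_left))
      a[1] <- m
      a[-1] <- rest
      out <- c(out, list(a))
    }
  }
  out
}

#' Chance null for within-module homotopic pairing
#'
#' Null model: node labels are randomly permuted over a fixed module-size
#' partition, so module sizes are preserved while homotopic identity is
#' broken. \code{permute} mode resamples \code{n_perm} times; \code{exact}
#' mode enumerates all assignments (feasible for <= 10 nodes).
#'
#' @param module_sizes integer module sizes summing to the node count.
#' @param nodes a \code{nodeset}.
#' @param observed observed number of co-located pairs.
#' @param n_perm permutations (permute mode).
#' @param seed RNG seed (permute mode).
#' @param mode \code{"permute"} or \code{"exact"}.
#' @return list: \code{p}, \code{mode}, and \code{null} draws or exact
#'   \code{pmf} over 0..n_pairs.
#' @export
null_colocation <- function(module_sizes, nodes, observed, n_perm = 999,
                            seed = 1, mode = c("permute", "exact")) {
  mode <- match.arg(mode)
  n <- length(nodes$labels)
  if (sum(module_sizes) != n)
    stop("module sizes must sum to the node count", call. = FALSE)
  pm <- nodes$pair_map
  count_pairs <- function(a) sum(a[pm[, 1]] == a[pm[, 2]])
  if (mode == "exact") {
    if (n > 10) stop("exact mode supports at most 10 nodes", call. = FALSE)
    asg <- .enumerate_assignments(seq_len(n), module_sizes)
    counts <- vapply(asg, count_pairs, numeric(1))
    pmf <- tabulate(counts + 1, nbins = nrow(pm) + 1) / length(counts)
    p <- sum(pmf[(observed + 1):length(pmf)])
    if (observed == 0) p <- 1
    return(list(p = min(p, 1), pmf = pmf, mode = mode))
  }
  if (n_perm < 100) stop("need n_perm >= 100", call. = FALSE)
  set.seed(as.integer(seed))
  base <- rep(seq_along(module_sizes), module_sizes)
  null <- vapply(seq_len(n_perm), function(k) count_pairs(sample(base)),
                 numeric(1))
  list(p = (1 + sum(null >= observed)) / (1 + n_perm), null = null,
       mode = mode)
}

#' Full homotopy report for a group network
#'
#' Computes strongest-link anchoring, within-module pairing, symmetry
#' ratios, and their chance nulls.
#'
#' @param net a \code{group_network} (or bare weight matrix).
#' @param partition a \code{partition} of the same nodes.
#' @param nodes a \code{nodeset}.
#' @param n_perm permutations for both nulls.
#' @param seed RNG seed.
#' @return An object of class \code{homotopy_report}.
#' @export
homotopy_report <- function(net, partition, nodes, n_perm = 999, seed = 1) {
  W <- if (inherits(net, "group_network")) net$W else net
  partners <- strongest_link_per_node(W)
  anch <- anchoring_count(partners, nodes)
  pairing <- module_pairing(partition, nodes)
  ratios <- symmetry_ratios(partition, nodes)
  sizes <- as.integer(table(
    if (inherits(partition, "partition")) partition$assignment else partition))
  p_anchor <- null_anchoring(nodes, anch$anchored, n_perm = n_perm,
                             seed = seed)
  p_coloc <- null_colocation(sizes, nodes, pairing$pairs_colocated,
                             n_perm = n_perm, seed = seed + 1)
  structure(list(strongest_links = partners,
                 anchoring = anch,
                 pairing = pairing,
                 symmetry = ratios,
                 p_anchoring = p_anchor$p,
                 p_colocation = p_coloc$p,
                 n_perm = n_perm, seed = seed),
            class = "homotopy_report")
}

#' @export
print.homotopy_report <- function(x, ...) {
  cat("homotopy report\n")
  cat(sprintf("  anchoring: %d of %d paired regions (p = %.4g)\n",
              x$anchoring$anchored, x$anchoring$total_paired, x$p_anchoring))
  cat(sprintf("  pairs co-located in a module: %d of %d (p = %.4g)\n",
              x$pairing$pairs_colocated, nrow(x$pairing$pair_table),
              x$p_colocation))
  tot <- x$symmetry$totals
  cat(sprintf("  symmetry ratio total: %d/%d\n", tot["K"], tot["N"]))
  rat <- x$symmetry$per_module
  cat("  per module:", paste(sprintf("%d/%d", rat$k, rat$n), collapse = ", "),
      "\n")
  invisible(x)
}
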