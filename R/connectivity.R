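#' Weighted Pearson correlation
#'
#' Correlation with per-observation non-negative weights: means, variances
#' and the covariance are computed under weights normalised to sum 1. With
#' constant weights this reduces to the ordinary Pearson coefficient. Used
#' to restrict connectivity to scans where a condition's HRF-convolved
#' response is active.
#'
#' @param x,y numeric series of equal length.
#' @param w non-negative weights; at least 3 must be positive.
#' @return correlation in [-1, 1].
#' @export
weighted_correlation <- function(x, y, w) {
  stopifnot(length(x) == length(y), length(x) == length(w), all(w >= 0))
  if (sum(w > 0) < 3)
    stop("need at least 3 positively weighted scans", call. = FALSE)
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0)
    stop("degenerate series: zero weighted variance", call. = FALSE)
  sxy <- sum(w * (x - mx) * (y - my))
  max(-1, min(1, sxy / sqrt(vx * vy)))
}

#' Fisher's variance-stabilising transform
#'
#' \eqn{z = \tfrac12 \log((1+r)/(1-r)) = \mathrm{atanh}(r)}.
#'
#' @param r correlation(s), |r| < 1 (unless clipping enabled).
#' @param clip if TRUE, |r| >= 1 is clipped to 1 - 1e-7 in magnitude before
#'   transforming; otherwise out-of-domain input is an error.
#' @return z score(s).
#' @export
fisher_z <- function(r, clip = FALSE) {
  if (any(abs(r) >= 1)) {
    if (!clip) stop("|r| >= 1 is outside the Fisher transform domain",
                    call. = FALSE)
    r <- sign(r) * pmin(abs(r), 1 - 1e-7)
  }
  atanh(r)
}

#' Condition-weighted connectivity matrix for one subject
#'
#' All region pairs' weighted Pearson correlations, Fisher-transformed.
#'
#' @param ts region x scan matrix of denoised series.
#' @param weights per-scan non-negative condition weights (from
#'   \code{\link{condition_regressor}}'s \code{weights}).
#' @param condition identifier stored with the result.
#' @param subject_id identifier stored with the result.
#' @param clip clip |r| >= 1 before the Fisher transform (default TRUE:
#'   degenerate identical series otherwise make the matrix unusable).
#' @return An object of class \code{subject_connectivity}: list with
#'   \code{z} (symmetric region x region matrix, zero diagonal),
#'   \code{condition}, \code{subject_id}.
#' @export
subject_connectivity <- function(ts, weights, condition = "task",
                                 subject_id = "sub-01", clip = TRUE) {
  n <- nrow(ts)
  z <- matrix(0, n, n, dimnames = list(rownames(ts), rownames(ts)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- tryCatch(weighted_correlation(ts[i, ], ts[j, ], weights),
                  error = function(e)
                    stop("edge (", i, ",", j, "): ", conditionMessage(e),
                         call. = FALSE))
    z[i, j] <- z[j, i] <- fisher_z(r, clip = clip)
  }
  structure(list(z = z, condition = condition, subject_id = subject_id),
            class = "subject_connectivity")
}

#' Second-level random-effects edge test
#'
#' Per edge, a one-sample two-sided t test of the subjects' Fisher z values
#' against zero (df = n_subjects - 1). Edges with zero across-subject
#' variance get p = 1 when the mean is also zero, otherwise p = 0 with a
#' degenerate-edge flag (a warning is raised).
#'
#' @param subjects list of \code{subject_connectivity}, same condition and
#'   node count.
#' @return data.frame with one row per unordered pair: i, j, mean_z, t, p,
#'   plus attribute \code{n_subjects}.
#' @export
group_edge_test <- function(subjects) {
  stopifnot(length(subjects) >= 3)
  conds <- unique(vapply(subjects, function(s) s$condition, character(1)))
  if (length(conds) != 1)
    stop("subjects mix conditions: ", paste(conds, collapse = ", "),
         call. = FALSE)
  n <- nrow(subjects[[1]]$z)
  if (!all(vapply(subjects, function(s) nrow(s$z) == n, logical(1))))
    stop("subjects differ in node count", call. = FALSE)
  ns <- length(subjects)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  Z <- vapply(subjects, function(s) s$z[upper.tri(s$z)],
              numeric(nrow(ut)))
  Z <- matrix(Z, nrow = nrow(ut))
  m <- rowMeans(Z)
  s <- apply(Z, 1, stats::sd)
  t_stat <- ifelse(s > 0, m / (s / sqrt(ns)),
                   ifelse(m == 0, 0, sign(m) * Inf))
  p <- ifelse(s > 0, 2 * stats::pt(-abs(t_stat), df = ns - 1),
              ifelse(m == 0, 1, 0))
  if (any(s == 0 & m != 0))
    warning("edges with zero across-subject variance; p set to 0")
  res <- data.frame(i = ut[, 1], j = ut[, 2], mean_z = m, t = t_stat, p = p)
  attr(res, "n_subjects") <- ns
  attr(res, "condition") <- conds
  res
}

#' Benjamini-Hochberg rejection mask
#'
#' Step-up FDR control at level \code{q} over the supplied p values.
#'
#' @param p_values vector of p values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return logical mask, TRUE where rejected.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  if (!length(p_values)) return(logical(0))
  if (q <= 0) return(rep(FALSE, length(p_values)))
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Build the FDR-thresholded weighted group network
#'
#' Runs the group edge test, keeps edges that pass Benjamini-Hochberg FDR at
#' level \code{q} with positive group mean z, and assigns edge weights.
#' The default weight convention is \code{tanh(mean_z)} — the group-mean
#' correlation back-transformed into (0, 1), so distances D = 1 - W stay in
#' (0, 1] — with \code{mean_z} itself available as an alternative.
#' Significant negative-mean edges are excluded from W (matching networks
#' restricted to positive connections) but reported in the edge table.
#'
#' @param subjects list of \code{subject_connectivity}.
#' @param q FDR level (default 0.05).
#' @param weight \code{"tanh_mean_z"} or \code{"mean_z"}.
#' @return An object of class \code{group_network}: list with \code{W}
#'   (symmetric weight matrix, 0 off-edges), \code{edges} (full edge table
#'   with q values and significance flags), \code{n_subjects},
#'   \code{condition}, \code{weight}.
#' @export
build_group_network <- function(subjects, q = 0.05,
                                weight = c("tanh_mean_z", "mean_z")) {
  weight <- match.arg(weight)
  tab <- group_edge_test(subjects)
  tab$q_value <- stats::p.adjust(tab$p, method = "BH")
  tab$significant <- fdr_bh(tab$p, q)
  tab$kept <- tab$significant & tab$mean_z > 0
  n <- nrow(subjects[[1]]$z)
  W <- matrix(0, n, n, dimnames = dimnames(subjects[[1]]$z))
  wv <- if (weight == "tanh_mean_z") tanh(tab$mean_z) else tab$mean_z
  tab$W <- ifelse(tab$kept, wv, 0)
  W[cbind(tab$i, tab$j)] <- tab$W
  W[cbind(tab$j, tab$i)] <- tab$W
  structure(list(W = W, edges = tab,
                 n_subjects = attr(tab, "n_subjects"),
                 condition = attr(tab, "condition"), weight = weight,
                 q = q),
            class = "group_network")
}

#' @export
print.group_network <- function(x, ...) {
  cat("group_network:", nrow(x$W), "regions,", sum(x$edges$kept),
      "edges (FDR q =", x$q, ", condition", x$condition, ")\n")
  invisible(x)
}
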