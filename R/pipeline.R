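# FNV-1a hash of a string; short provenance fingerprint for output headers
.fnv1a <- function(s) {
  mul32 <- function(a, b) {     # a * b mod 2^32 without losing precision
    lo <- (a %% 65536) * b
    hi <- ((a %/% 65536) * b) %% 65536
    (lo + hi * 65536) %% 4294967296
  }
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    h <- mul32(h, 16777619)
  }
  sprintf("%08x", h)
}

.provenance <- function(config) {
  cfg <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE)
  sprintf("# homonet %s | config %s | seed %d",
          as.character(utils::packageVersion("homonet")),
          .fnv1a(as.character(cfg)), config$seed)
}

.write_tsv <- function(df, path, header_line) {
  con <- file(path, "w")
  writeLines(header_line, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. All stochastic steps
#' derive from \code{seed}.
#'
#' @param out_dir output directory.
#' @param condition condition analysed ("left" or "right").
#' @param n_subjects subjects to simulate (ignored when \code{ts_list}
#'   supplied to \code{\link{run_pipeline}}).
#' @param model a \code{coupling_model} for simulation.
#' @param low_hz,high_hz bandpass edges (Hz).
#' @param fdr_q FDR level for edge selection.
#' @param gamma Louvain resolution.
#' @param restarts Louvain restarts.
#' @param n_perm permutations for the homotopy nulls.
#' @param seed master seed.
#' @param weight edge-weight convention, \code{"tanh_mean_z"} or
#'   \code{"mean_z"}.
#' @return named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir = NULL, condition = "right",
                            n_subjects = 18, model = coupling_model(),
                            low_hz = 0.008, high_hz = 0.09, fdr_q = 0.05,
                            gamma = 1, restarts = 100, n_perm = 999,
                            seed = 7, weight = "tanh_mean_z") {
  stopifnot(fdr_q >= 0, fdr_q <= 1, gamma > 0, restarts >= 1,
            n_perm >= 100, n_subjects >= 3)
  structure(list(out_dir = out_dir, condition = condition,
                 n_subjects = n_subjects, model = model, low_hz = low_hz,
                 high_hz = high_hz, fdr_q = fdr_q, gamma = gamma,
                 restarts = restarts, n_perm = n_perm,
                 seed = as.integer(seed), weight = weight),
            class = "pipeline_config")
}

#' Run the full weighted-network homotopy pipeline
#'
#' Stages: simulate (or ingest) subject ROI time series; denoise (bandpass
#' + nuisance regression, confounds filtered to the same band); build the
#' condition-weighted connectivity per subject; second-level random-effects
#' edge test with FDR; weighted graph metrics and Louvain modularity;
#' homotopy statistics with chance nulls. When \code{out_dir} is set, edge
#' tables, the W matrix, the partition, metric and homotopy JSON reports and
#' BrainNet-style .node/.edge files are written, each with a provenance
#' header.
#'
#' @param config a \code{pipeline_config}.
#' @param nodes a \code{nodeset} (default \code{\link{default_nodeset}}).
#' @param paradigm a \code{task_paradigm} (default
#'   \code{\link{default_paradigm}}).
#' @param ts_list optional list of \code{subject_ts}; when supplied the
#'   simulation stage is skipped.
#' @return list with \code{network}, \code{partition}, \code{metrics},
#'   \code{homotopy}, \code{config}.
#' @export
run_pipeline <- function(config, nodes = default_nodeset(),
                         paradigm = default_paradigm(), ts_list = NULL) {
  stopifnot(inherits(config, "pipeline_config"), inherits(nodes, "nodeset"))
  if (is.null(ts_list))
    ts_list <- simulate_study(nodes, config$model, paradigm,
                              n_subjects = config$n_subjects,
                              seed = config$seed)
  reg <- condition_regressor(paradigm, config$condition)
  subjects <- lapply(ts_list, function(ts) {
    clean <- denoise_subject(ts, config$low_hz, config$high_hz)
    subject_connectivity(clean, reg$weights, condition = config$condition,
                         subject_id = ts$subject_id)
  })
  net <- build_group_network(subjects, q = config$fdr_q,
                             weight = config$weight)
  if (sum(net$W) == 0)
    stop("stage graph: no edges survived FDR; nothing to analyse",
         call. = FALSE)
  part <- louvain_partition(net$W, gamma = config$gamma, seed = config$seed,
                            restarts = config$restarts)
  D <- distance_matrix(net$W)
  metrics <- list(
    n_nodes = nrow(net$W),
    n_edges = sum(net$edges$kept),
    complete_edges = complete_edge_count(nrow(net$W)),
    strength = strength(net$W),
    global_efficiency = global_efficiency(D),
    betweenness = betweenness_w(D),
    clustering = clustering_w(net$W),
    assortativity = as.numeric(assortativity_w(net$W)),
    modularity_q = part$q_value,
    n_modules = length(unique(part$assignment)))
  hom <- homotopy_report(net, part, nodes, n_perm = config$n_perm,
                         seed = config$seed)
  res <- list(network = net, partition = part, metrics = metrics,
              homotopy = hom, config = config)
  if (!is.null(config$out_dir)) .write_pipeline_outputs(res, nodes)
  res
}

.write_pipeline_outputs <- function(res, nodes) {
  dir.create(res$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(res$config$out_dir, f)
  hdr <- .provenance(res$config[c("condition", "fdr_q", "gamma", "n_perm",
                                  "seed", "weight")])
  ed <- res$network$edges
  ed$label_i <- nodes$labels[ed$i]; ed$label_j <- nodes$labels[ed$j]
  .write_tsv(ed, out("edges.tsv"), hdr)
  Wdf <- as.data.frame(res$network$W)
  .write_tsv(cbind(region = nodes$labels, Wdf), out("W.tsv"), hdr)
  .write_tsv(data.frame(region = nodes$labels,
                        module = res$partition$assignment),
             out("partition.tsv"), hdr)
  jsonlite::write_json(res$metrics, out("metrics.json"), auto_unbox = TRUE,
                       digits = NA)
  h <- res$homotopy
  jsonlite::write_json(
    list(anchored = h$anchoring$anchored,
         total_paired = h$anchoring$total_paired,
         unique_homotopic_links = h$anchoring$unique_homotopic_links,
         pairs_colocated = h$pairing$pairs_colocated,
         symmetry_per_module = h$symmetry$per_module,
         symmetry_totals = as.list(h$symmetry$totals),
         p_anchoring = h$p_anchoring,
         p_colocation = h$p_colocation,
         n_perm = h$n_perm, seed = h$seed),
    out("homotopy.json"), auto_unbox = TRUE, digits = NA)
  export_brainnet(res$network$W, nodes, res$partition,
                  node_path = out("network.node"),
                  edge_path = out("network.edge"))
  writeLines(c(hdr, paste("stages: simulate/ingest denoise connect graph",
                          "homotopy")), out("run.log"))
  invisible(res)
}

#' Export a network for BrainNet-style viewers
#'
#' Writes a .node file (x y z color size label: color = module id, size =
#' node strength) and a .edge file (square weight matrix, tab separated).
#'
#' @param W weight matrix.
#' @param nodes a \code{nodeset}.
#' @param partition a \code{partition} (or assignment vector); optional.
#' @param node_path,edge_path output paths.
#' @return invisibly, the two paths.
#' @export
export_brainnet <- function(W, nodes, partition = NULL,
                            node_path, edge_path) {
  a <- if (is.null(partition)) rep(1L, nrow(W))
       else if (inherits(partition, "partition")) partition$assignment
       else partition
  nd <- data.frame(x = nodes$centers_mm[, 1], y = nodes$centers_mm[, 2],
                   z = nodes$centers_mm[, 3], color = a,
                   size = strength(W), label = nodes$labels)
  utils::write.table(nd, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(W, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(node_path, edge_path))
}

#' Write subject time series and confounds as TSV
#' @param ts a \code{subject_ts}.
#' @param dir output directory (created if needed).
#' @return invisibly, the data path.
#' @export
write_subject_ts <- function(ts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, ts$subject_id)
  utils::write.table(ts$data, paste0(base, "_ts.tsv"), sep = "\t",
                     quote = FALSE, col.names = FALSE)
  utils::write.table(ts$confounds, paste0(base, "_confounds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(tr_s = ts$tr_s, subject_id = ts$subject_id),
                       paste0(base, "_meta.json"), auto_unbox = TRUE)
  invisible(paste0(base, "_ts.tsv"))
}

#' Read subject time series written by \code{\link{write_subject_ts}}
#' @param dir directory.
#' @param subject_id subject identifier.
#' @return a \code{subject_ts}.
#' @export
read_subject_ts <- function(dir, subject_id) {
  base <- file.path(dir, subject_id)
  meta <- jsonlite::read_json(paste0(base, "_meta.json"))
  tab <- utils::read.delim(paste0(base, "_ts.tsv"), header = FALSE,
                           row.names = 1)
  structure(list(data = as.matrix(tab),
                 tr_s = meta$tr_s,
                 confounds = utils::read.delim(paste0(base,
                                                      "_confounds.tsv")),
                 subject_id = meta$subject_id),
            class = "subject_ts")
}
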