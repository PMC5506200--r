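#!/usr/bin/env Rscript
# Homotopy statistics of the group network: the strongest link per region,
# the count of paired regions anchored to their contralateral homolog,
# within-module homotopic pairing, per-module symmetry ratios, and
# permutation nulls (999 draws) for anchoring and co-location.

suppressPackageStartupMessages(library(homonet))
seed <- 7

nodes <- read_nodeset("results/sim/nodes.tsv")
W <- as.matrix(read.delim("results/network/W.tsv"))
dimnames(W) <- list(nodes$labels, nodes$labels)
part_tab <- read.delim("results/network/partition.tsv")
part <- part_tab$module

rep <- homotopy_report(W, part, nodes, n_perm = 999, seed = seed)
print(rep)

dir.create("results/homotopy", showWarnings = FALSE, recursive = TRUE)
jsonlite::write_json(
  list(anchored = rep$anchoring$anchored,
       total_paired = rep$anchoring$total_paired,
       unique_homotopic_links = rep$anchoring$unique_homotopic_links,
       pairs_colocated = rep$pairing$pairs_colocated,
       symmetry_per_module = rep$symmetry$per_module,
       symmetry_totals = as.list(rep$symmetry$totals),
       p_anchoring = rep$p_anchoring,
       p_colocation = rep$p_colocation),
  "results/homotopy/homotopy.json", auto_unbox = TRUE, digits = NA)
export_brainnet(W, nodes, part,
                node_path = "results/homotopy/network.node",
                edge_path = "results/homotopy/network.edge")
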