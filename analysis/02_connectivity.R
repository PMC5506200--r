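#!/usr/bin/env Rscript
# Condition-weighted connectivity from the simulated study: bandpass
# (0.008-0.09 Hz) + nuisance regression per subject, weighted Pearson
# correlation under the HRF-convolved right-foot regressor, Fisher z,
# second-level one-sample t tests across subjects, Benjamini-Hochberg FDR
# at q = 0.05, and the thresholded weighted group network W.

suppressPackageStartupMessages(library(homonet))
seed <- 7

nodes <- read_nodeset("results/sim/nodes.tsv")
paradigm <- read_paradigm("results/sim/events.tsv", tr_s = 2,
                          total_duration_s = 388)
ids <- sprintf("sub-%02d", 1:18)
study <- lapply(ids, function(id) read_subject_ts("results/sim", id))

w <- condition_regressor(paradigm, "right")$weights
subjects <- lapply(study, function(ts)
  subject_connectivity(denoise_subject(ts), w, condition = "right",
                       subject_id = ts$subject_id))
net <- build_group_network(subjects, q = 0.05)

dir.create("results/network", showWarnings = FALSE, recursive = TRUE)
ed <- net$edges
ed$label_i <- nodes$labels[ed$i]
ed$label_j <- nodes$labels[ed$j]
write.table(ed, "results/network/edges.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(net$W, "results/network/W.tsv", sep = "\t", quote = FALSE)

cat(sprintf("group network: %d of %d edges pass FDR (q = 0.05)\n",
            sum(ed$kept), complete_edge_count(length(nodes$labels))))
cat(sprintf("mean W on homotopic edges: %.3f, intrahemispheric: %.3f\n",
            mean(net$W[nodes$pair_map]),
            {
              hemi <- nodes$hemisphere
              same <- outer(hemi, hemi, "==") & upper.tri(net$W) &
                outer(hemi != "M", hemi != "M", "&")
              h <- homolog_of(nodes)
              same[cbind(nodes$pair_map[, 1], nodes$pair_map[, 2])] <- FALSE
              mean(net$W[same])
            }))
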