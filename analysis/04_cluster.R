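#!/usr/bin/env Rscript
# Step 4: Bayesian model-based clustering of the expression trajectories.
#
# Profiles changing more than 2-fold at some week enter a greedy
# agglomeration that merges trajectory clusters while the Bayes factor of
# the conjugate order-3 polynomial model favours merging; the number of
# clusters is emergent. Clusters whose center exceeds |1| log2 at some week
# are selected and classified as increased / variable / decreased.

suppressPackageStartupMessages(library(capclust))

pre <- file.path("results", "preprocess")
out <- file.path("results", "cluster")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- cluster_config()

for (g in c("sham", "immobilized")) {
  rtab <- read.delim(file.path(pre, paste0(g, "_log2_ratios.tsv")),
                     check.names = FALSE)
  ratios <- as.matrix(rtab[-1])
  rownames(ratios) <- rtab$probe_id
  included <- inclusion_filter(ratios, cfg)
  cat(sprintf("%s: %d of %d profiles exceed 2-fold at >= 1 week\n",
              g, nrow(included), nrow(ratios)))
  part <- classify_partition_trends(
    select_clusters(agglomerate(included, cfg)))
  summ <- partition_summary(part)
  print(summ, digits = 3)
  cat(sprintf("%s: %d clusters, %d selected, %d probes in selected clusters\n",
              g, nrow(summ), sum(summ$selected),
              sum(summ$size[summ$selected])))
  write_partition_tsv(part,
                      file.path(out, paste0(g, "_assignments.tsv")),
                      file.path(out, paste0(g, "_cluster_summary.tsv")))
  write.table(part$trace, file.path(out, paste0(g, "_merge_trace.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(selected_probes(part),
             file.path(out, paste0(g, "_selected_probes.txt")))
}
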