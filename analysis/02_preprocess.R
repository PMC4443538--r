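#!/usr/bin/env Rscript
# Step 2: filter and summarize each series independently.
#
# Two rules: drop probes called absent in every sample, then drop probes
# whose per-week replicate median never reaches the expression floor (100,
# the MAS5 target value). Survivors are collapsed to per-week medians and
# log2 ratios against week 1.

suppressPackageStartupMessages(library(capclust))

sim <- file.path("results", "sim")
out <- file.path("results", "preprocess")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (g in c("sham", "immobilized")) {
  ds <- read_expression_tsv(file.path(sim, paste0(g, ".tsv")))
  pp <- preprocess_dataset(ds)
  cat(sprintf("%s: %d -> absent filter -> %d -> floor filter -> %d probes\n",
              g, pp$n_initial, pp$n_initial - pp$n_all_absent, pp$n_retained))
  med <- median_by_timepoint(pp$dataset)
  ratios <- log2_ratio_profiles(med)
  write.table(data.frame(probe_id = rownames(med), med, check.names = FALSE),
              file.path(out, paste0(g, "_medians.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(probe_id = rownames(ratios), ratios,
                         check.names = FALSE),
              file.path(out, paste0(g, "_log2_ratios.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
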