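#!/usr/bin/env Rscript
# Step 3: fold-change binning and direction summaries.
#
# Week-over-week-1 ratios are turned into signed fold changes and binned
# (1.5- to 2-fold and >= 2-fold, each direction). The summary counts each
# probe once per direction and attributes the events to weeks.

suppressPackageStartupMessages(library(capclust))

pre <- file.path("results", "preprocess")
out <- file.path("results", "foldchange")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (g in c("sham", "immobilized")) {
  medtab <- read.delim(file.path(pre, paste0(g, "_medians.tsv")),
                       check.names = FALSE)
  med <- as.matrix(medtab[-1])
  rownames(med) <- medtab$probe_id
  fc <- compute_fold_changes(med, baseline_week = 1)
  ds <- summarize_directions(fc)
  cat(sprintf("\n== %s ==\n", g))
  print(ds)
  up24 <- attribution(ds, "up", c(2, 4))
  dn8 <- attribution(ds, "down", 8)
  cat(sprintf("increases at week 2 or 4: %d/%d = %.1f%%\n",
              up24$count, up24$total, up24$percent))
  cat(sprintf("decreases at week 8:      %d/%d = %.1f%%\n",
              dn8$count, dn8$total, dn8$percent))
  write.table(ds$per_week_counts,
              file.path(out, paste0(g, "_bin_counts.tsv")),
              sep = "\t", quote = FALSE, col.names = NA)
}
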