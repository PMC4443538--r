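#!/usr/bin/env Rscript
# Step 5: cross-group comparison, gene collapse and over-representation.
#
# The selected probe sets of the two series are intersected; probes unique
# to the immobilized series are collapsed to genes and tested for term
# over-representation (hypergeometric and EASE) against the genes surviving
# preprocessing, then cross-tabulated against the immobilized clusters.

suppressPackageStartupMessages(library(capclust))

sim <- file.path("results", "sim")
out <- file.path("results", "comparison")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sel <- lapply(c(sham = "sham", immobilized = "immobilized"), function(g)
  readLines(file.path("results", "cluster",
                      paste0(g, "_selected_probes.txt"))))
map <- read_probe_gene_map(file.path(sim, "probe_gene_map.tsv"))
cmp <- collapse_comparison(compare_groups(sel$sham, sel$immobilized), map)
print(cmp)

med_imm <- read.delim(file.path("results", "preprocess",
                                "immobilized_medians.tsv"),
                      check.names = FALSE)
background <- collapse_to_genes(med_imm$probe_id, map)
coll <- read_gmt(file.path(sim, "gene_sets.gmt"), "synthetic")
res <- hypergeometric_enrichment(cmp$immobilized_only_genes, background,
                                 coll)
assignments <- read.delim(file.path("results", "cluster",
                                    "immobilized_assignments.tsv"))
res <- crosstab_clusters(res, assignments, map)
cat("\nTop terms (term, k/K, p, EASE p, modal cluster):\n")
top <- head(res, 5)
for (i in seq_len(nrow(top)))
  cat(sprintf("  %-28s %3d/%-3d  p=%.2e  ease=%.2e  cluster %s (%d of %d, %d%%)\n",
              top$term[i], top$k[i], top$K[i], top$p[i], top$p_ease[i],
              top$modal_cluster[i], top$modal_count[i], top$k[i],
              top$modal_pct[i]))
write_enrichment_tsv(res, file.path(out, "enrichment.tsv"))
writeLines(c(
  sprintf("common probes\t%d", cmp$n_common),
  sprintf("immobilized-only probes\t%d", cmp$n_immobilized_only),
  sprintf("common genes\t%d", cmp$n_common_genes),
  sprintf("immobilized-only genes\t%d", cmp$n_immobilized_only_genes)),
  file.path(out, "comparison_counts.tsv"))
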