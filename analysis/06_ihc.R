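#!/usr/bin/env Rscript
# Step 6: immunohistochemistry field scoring.
#
# Per (rat, field) the two examiners' percent-positive counts are averaged;
# the most discordant field per rat is removed; the remaining three fields
# per rat are pooled within each week and the groups compared with the
# Kruskal-Wallis test.

suppressPackageStartupMessages(library(capclust))

out <- file.path("results", "ihc")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tab <- read_ihc_csv(file.path("results", "sim", "ihc_counts.csv"))
scores <- score_fields(tab)
cat(sprintf("%d fields scored, %d removed (worst inter-rater diff per rat)\n",
            nrow(scores), sum(scores$removed)))
res <- kruskal_wallis_by_week(scores)
print(res, digits = 3)
write.table(scores, file.path(out, "field_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res, file.path(out, "kruskal_by_week.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
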