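#!/usr/bin/env Rscript
# Step 1: build the synthetic study.
#
# No public accession exists for the original arrays, so the workflow runs on
# synthetic data with planted structure: two independent series (sham and
# immobilized), 5 weeks x 4 replicate arrays, MAS5-like intensities with
# detection calls, planted polynomial log2-ratio trajectory clusters, plus a
# two-examiner IHC count table with a group effect. We use a 4,000-probe chip
# here so the whole workflow runs in minutes at the desk; the planted
# fractions mirror the chip-scale filter proportions (18% all-absent, 34% of
# the remainder below the floor).

suppressPackageStartupMessages(library(capclust))

out <- file.path("results", "sim")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 2026L

n_probes <- 4000L
# immobilized: an increasing, a decreasing and a variable trajectory cluster
spec_imm <- list(
  list(coef = c(1.6, 1.0, 0, 0), size = 300),    # increased, > 2-fold
  list(coef = c(-1.8, -0.9, 0.3, 0), size = 300),# decreased
  list(coef = c(0.2, -1.6, 0, 0.9), size = 200), # variable
  list(coef = 0, size = n_probes - 800))         # unchanged bulk
# sham: shares the increasing trajectory on an overlapping probe block
spec_sham <- list(
  list(coef = c(1.6, 1.0, 0, 0), size = 300),
  list(coef = c(-1.4, 0.9, 0, 0), size = 150),
  list(coef = 0, size = n_probes - 450))

sims <- list(
  immobilized = generate_expression_dataset(
    sim_config(n_probes, spec_imm, replicate_noise_sd = 0.15,
               absent_fraction = 0.18, low_floor_fraction = 0.34,
               seed = seed), "immobilized"),
  sham = generate_expression_dataset(
    sim_config(n_probes, spec_sham, replicate_noise_sd = 0.15,
               absent_fraction = 0.18, low_floor_fraction = 0.34,
               seed = seed + 1L), "sham"))

for (g in names(sims)) {
  write_expression_tsv(sims[[g]]$dataset, file.path(out, paste0(g, ".tsv")))
  write.table(sims[[g]]$truth$assignments,
              file.path(out, paste0(g, "_truth.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d probes x %d samples written\n", g,
              nrow(sims[[g]]$dataset$intensity),
              ncol(sims[[g]]$dataset$intensity)))
}

# probe-gene map: two probes per gene, as is common on this class of chip
map <- data.frame(probe_id = probe_ids(sims$immobilized$dataset),
                  gene = sprintf("GENE%04d", rep(seq_len(n_probes / 2),
                                                 each = 2)))
write.table(map, file.path(out, "probe_gene_map.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# gene-set collection: terms enriched in the planted immobilized clusters
# (triglyceride/ECM/muscle stand-ins) plus background terms
set.seed(seed)
planted_genes <- unique(map$gene[match(
  sims$immobilized$truth$assignments$probe_id[
    sims$immobilized$truth$assignments$cluster %in% 1:2 &
      sims$immobilized$truth$assignments$status == "planted"],
  map$probe_id)])
all_genes <- unique(map$gene)
terms <- c(
  list(triglyceride_biosynthesis = sample(planted_genes, 40),
       extracellular_matrix = sample(planted_genes, 60),
       muscle_contraction = sample(planted_genes, 30)),
  lapply(setNames(seq_len(12), sprintf("background_term_%02d", 1:12)),
         function(i) sample(all_genes, 50)))
writeLines(vapply(names(terms), function(t)
  paste(c(t, "synthetic", terms[[t]]), collapse = "\t"), ""),
  file.path(out, "gene_sets.gmt"))
cat(sprintf("gene sets: %d terms written\n", length(terms)))

# IHC counts: sham stains higher than immobilized from week 2 on
effects <- data.frame(
  group = rep(c("sham", "immobilized"), each = 4),
  week = rep(c(2, 4, 8, 16), 2),
  mean = c(45, 42, 40, 38, 25, 20, 15, 12))
write_ihc_csv(generate_ihc_dataset(4, effects, examiner_sd = 5,
                                   field_sd = 6, seed = seed),
              file.path(out, "ihc_counts.csv"))
cat("IHC table: 4 rats x 8 cells x 4 fields x 2 examiners written\n")
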