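#' Pipeline configuration
#'
#' Paths of the inputs plus the per-stage configurations. Sham and
#' immobilized series are processed fully independently and meet only at the
#' cross-group comparison.
#'
#' @param sham_path,immobilized_path expression TSV paths (dialect of
#'   [write_expression_tsv()]).
#' @param probe_gene_map_path probe-to-gene TSV path.
#' @param gmt_paths named character vector of GMT collection paths (may be
#'   empty to skip enrichment).
#' @param ihc_path IHC CSV path (NULL to skip the IHC stage).
#' @param output_dir directory for stage outputs.
#' @param preprocess a [preprocess_config()].
#' @param cluster a [cluster_config()].
#' @param selection_threshold cluster-center selection threshold (|log2|).
#' @param trend_tolerance tolerance of [classify_trend()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sham_path, immobilized_path, probe_gene_map_path,
                            gmt_paths = character(), ihc_path = NULL,
                            output_dir = tempfile("capclust_run_"),
                            preprocess = preprocess_config(),
                            cluster = cluster_config(),
                            selection_threshold = 1,
                            trend_tolerance = 0.25) {
  stopifnot(selection_threshold > 0)
  structure(list(sham_path = sham_path, immobilized_path = immobilized_path,
                 probe_gene_map_path = probe_gene_map_path,
                 gmt_paths = gmt_paths, ihc_path = ihc_path,
                 output_dir = output_dir, preprocess = preprocess,
                 cluster = cluster,
                 selection_threshold = selection_threshold,
                 trend_tolerance = trend_tolerance),
            class = "pipeline_config")
}

run_group_stages <- function(dataset, config, out_dir, group) {
  pp <- preprocess_dataset(dataset, config$preprocess)
  med <- median_by_timepoint(pp$dataset)
  ratios <- log2_ratio_profiles(med, config$preprocess)
  fc <- compute_fold_changes(med, config$preprocess$baseline_week)
  dirsum <- summarize_directions(fc)
  included <- inclusion_filter(ratios, config$cluster)
  part <- agglomerate(included, config$cluster)
  part <- select_clusters(part, config$selection_threshold)
  part <- classify_partition_trends(part, config$selection_threshold,
                                    config$trend_tolerance)
  if (!is.null(out_dir)) {
    utils::write.table(
      data.frame(probe_id = rownames(med), med, check.names = FALSE),
      file.path(out_dir, paste0(group, "_medians.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(probe_id = rownames(ratios), ratios, check.names = FALSE),
      file.path(out_dir, paste0(group, "_log2_ratios.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(dirsum$per_week_counts,
                       file.path(out_dir, paste0(group, "_bin_counts.tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
    write_partition_tsv(part,
                        file.path(out_dir, paste0(group, "_clusters.tsv")),
                        file.path(out_dir, paste0(group, "_cluster_summary.tsv")))
  }
  list(counts = pp[c("n_initial", "n_all_absent", "n_below_floor",
                     "n_retained")],
       medians = med, ratios = ratios, fold_changes = fc,
       direction_summary = dirsum, n_clustered = nrow(included),
       partition = part,
       selected = selected_probes(part))
}

#' Run the full sham + immobilized workflow
#'
#' Per group, independently: absent filter, expression-floor filter,
#' replicate medians, log2 ratios, fold-change direction summary, inclusion
#' filter, Bayesian agglomerative clustering, centers, selection and trend
#' classification; then the cross-group probe comparison, gene collapse,
#' over-representation analysis with cluster cross-tabulation, and (when an
#' IHC table is supplied) the per-week Kruskal-Wallis scoring. All stage
#' outputs are written under `output_dir` along with a JSON manifest echoing
#' the configuration and the count at every stage
#' (`n_initial = n_all_absent + n_below_floor + n_retained` per group).
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `output_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$sham_path, config$immobilized_path,
              config$probe_gene_map_path, config$gmt_paths, config$ihc_path))
    if (!is.null(p) && !file.exists(p))
      stop("input file not found: ", p, call. = FALSE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  sham <- run_group_stages(read_expression_tsv(config$sham_path), config,
                           config$output_dir, "sham")
  imm <- run_group_stages(read_expression_tsv(config$immobilized_path),
                          config, config$output_dir, "immobilized")

  map <- read_probe_gene_map(config$probe_gene_map_path)
  comparison <- collapse_comparison(compare_groups(sham$selected,
                                                   imm$selected), map)

  enrichments <- list()
  if (length(config$gmt_paths)) {
    ## background: all immobilized-group genes surviving preprocessing
    background <- collapse_to_genes(rownames(imm$medians), map)
    for (nm in names(config$gmt_paths)) {
      coll <- read_gmt(config$gmt_paths[[nm]], nm)
      res <- hypergeometric_enrichment(comparison$immobilized_only_genes,
                                       background, coll)
      res <- crosstab_clusters(res, imm$partition, map)
      write_enrichment_tsv(res, file.path(config$output_dir,
                                          paste0("enrichment_", nm, ".tsv")))
      enrichments[[nm]] <- res
    }
  }

  ihc <- NULL
  if (!is.null(config$ihc_path)) {
    scores <- score_fields(read_ihc_csv(config$ihc_path))
    ihc <- kruskal_wallis_by_week(scores)
    utils::write.table(ihc, file.path(config$output_dir, "ihc_kruskal.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("capclust")),
    config = list(selection_threshold = config$selection_threshold,
                  expression_floor = config$preprocess$expression_floor,
                  baseline_week = config$preprocess$baseline_week,
                  polynomial_order = config$cluster$polynomial_order,
                  inclusion_threshold = config$cluster$inclusion_threshold),
    sham = c(sham$counts, list(
      n_clustered = sham$n_clustered,
      n_clusters = length(sham$partition$clusters),
      n_selected_clusters = sum(vapply(sham$partition$clusters,
                                       `[[`, TRUE, "selected")),
      n_selected_probes = length(sham$selected))),
    immobilized = c(imm$counts, list(
      n_clustered = imm$n_clustered,
      n_clusters = length(imm$partition$clusters),
      n_selected_clusters = sum(vapply(imm$partition$clusters,
                                       `[[`, TRUE, "selected")),
      n_selected_probes = length(imm$selected))),
    comparison = list(
      n_common_probes = comparison$n_common,
      n_immobilized_only_probes = comparison$n_immobilized_only,
      n_common_genes = comparison$n_common_genes,
      n_immobilized_only_genes = comparison$n_immobilized_only_genes))
  for (g in c("sham", "immobilized")) {
    cnt <- manifest[[g]]
    stopifnot(cnt$n_initial == cnt$n_all_absent + cnt$n_below_floor +
                cnt$n_retained)
  }
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, sham = sham, immobilized = imm,
                 comparison = comparison, enrichments = enrichments,
                 ihc = ihc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
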