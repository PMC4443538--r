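#' Read a probe-to-gene mapping table
#'
#' Two-column tab-separated file with a header (`probe_id`, `gene`). In the
#' strict dialect every probe maps to exactly one gene; with
#' `permissive = TRUE` a probe listed with several genes keeps the first.
#'
#' @param path file path.
#' @param permissive keep the first gene of a multiply-annotated probe
#'   instead of raising an error?
#' @return Data frame with columns `probe_id` and `gene`.
#' @export
read_probe_gene_map <- function(path, permissive = FALSE) {
  map <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("probe_id", "gene") %in% names(map)))
    stop("probe-gene map must have header columns 'probe_id' and 'gene'",
         call. = FALSE)
  validate_probe_gene_map(map[c("probe_id", "gene")], permissive)
}

validate_probe_gene_map <- function(map, permissive = FALSE) {
  if (nrow(map) == 0L) stop("empty probe-gene map", call. = FALSE)
  if (any(!nzchar(map$gene)) || anyNA(map$gene))
    stop("probe-gene map contains empty gene symbols", call. = FALSE)
  dup <- duplicated(map$probe_id)
  if (any(dup)) {
    if (!permissive)
      stop("probe(s) mapped to multiple genes: ",
           paste(utils::head(unique(map$probe_id[dup]), 5), collapse = ", "),
           call. = FALSE)
    map <- map[!dup, , drop = FALSE]
  }
  map
}

#' Compare sham and immobilized selected probe sets
#'
#' Exact set intersection and difference of the probe sets belonging to the
#' selected clusters of the two independently analysed series: the
#' intersection is the "common" response (to surgery/time), the
#' immobilized-only difference is the immobilization-associated set.
#'
#' @param sham_selected,imm_selected character vectors of probe ids over the
#'   same probe namespace.
#' @return A list of class `group_comparison` with `sham`, `immobilized`,
#'   `common` and `immobilized_only` probe sets and their sizes.
#' @export
compare_groups <- function(sham_selected, imm_selected) {
  sham <- unique(as.character(sham_selected))
  imm <- unique(as.character(imm_selected))
  common <- intersect(sham, imm)
  only <- setdiff(imm, common)
  structure(list(sham = sham, immobilized = imm,
                 common = common, immobilized_only = only,
                 n_sham = length(sham), n_immobilized = length(imm),
                 n_common = length(common),
                 n_immobilized_only = length(only)),
            class = "group_comparison")
}

#' Collapse a probe set to distinct gene symbols
#'
#' Probes missing from the map are reported with a warning and excluded.
#'
#' @param probes character vector of probe ids.
#' @param map probe-gene map data frame (`probe_id`, `gene`), as from
#'   [read_probe_gene_map()].
#' @return Character vector of distinct gene symbols.
#' @export
collapse_to_genes <- function(probes, map) {
  map <- validate_probe_gene_map(map)
  probes <- unique(as.character(probes))
  if (length(probes) == 0L) return(character())
  hit <- match(probes, map$probe_id)
  if (anyNA(hit)) {
    warning(sum(is.na(hit)), " probe(s) absent from the probe-gene map ",
            "were excluded", call. = FALSE)
    hit <- hit[!is.na(hit)]
  }
  unique(map$gene[hit])
}

#' Gene-level counterpart of a group comparison
#'
#' Collapses each probe set to genes and computes the gene-level common and
#' immobilization-only sets as set operations on the collapsed sets (not as
#' the collapse of the probe-set difference): a gene with one common probe
#' and one immobilized-only probe is not immobilization-only.
#'
#' @param comparison a [compare_groups()] result.
#' @param map probe-gene map data frame.
#' @return The comparison augmented with `sham_genes`, `immobilized_genes`,
#'   `common_genes`, `immobilized_only_genes` and their sizes.
#' @export
collapse_comparison <- function(comparison, map) {
  stopifnot(inherits(comparison, "group_comparison"))
  sg <- collapse_to_genes(comparison$sham, map)
  ig <- collapse_to_genes(comparison$immobilized, map)
  cg <- intersect(sg, ig)
  og <- setdiff(ig, cg)
  comparison$sham_genes <- sg
  comparison$immobilized_genes <- ig
  comparison$common_genes <- cg
  comparison$immobilized_only_genes <- og
  comparison$n_sham_genes <- length(sg)
  comparison$n_immobilized_genes <- length(ig)
  comparison$n_common_genes <- length(cg)
  comparison$n_immobilized_only_genes <- length(og)
  comparison
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("group_comparison\n")
  cat(sprintf("  probes: sham %d, immobilized %d, common %d, immobilized-only %d\n",
              x$n_sham, x$n_immobilized, x$n_common, x$n_immobilized_only))
  if (!is.null(x$n_immobilized_genes))
    cat(sprintf("  genes:  sham %d, immobilized %d, common %d, immobilized-only %d\n",
                x$n_sham_genes, x$n_immobilized_genes, x$n_common_genes,
                x$n_immobilized_only_genes))
  invisible(x)
}
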