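#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: term name, description, then member gene
#' symbols. Parsing is delegated to `fgsea::gmtPathways()`.
#'
#' @param path GMT file path.
#' @param source_label optional label for the collection (e.g. "GO-BP").
#' @return A named list of character vectors (class `gene_set_collection`)
#'   with attribute `source`.
#' @export
read_gmt <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  if (!requireNamespace("fgsea", quietly = TRUE))
    stop("reading GMT files requires the 'fgsea' package", call. = FALSE)
  sets <- fgsea::gmtPathways(path)
  gene_set_collection(sets, source_label)
}

#' Construct a gene-set collection from a named list
#'
#' @param sets named list of character vectors of gene symbols.
#' @param source_label collection label.
#' @return The validated collection (class `gene_set_collection`).
#' @export
gene_set_collection <- function(sets, source_label = "custom") {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene-set terms must be uniquely named", call. = FALSE)
  if (any(lengths(sets) == 0L))
    stop("gene sets must be non-empty", call. = FALSE)
  structure(lapply(sets, unique), source = source_label,
            class = c("gene_set_collection", "list"))
}

#' Local hypergeometric / EASE over-representation analysis
#'
#' For each term, computes the one-sided upper-tail hypergeometric p-value
#' `P(X >= k)` of drawing `k` term genes in a query of size `n` from a
#' background of size `N` containing `K` term genes (term genes are
#' intersected with the background first). The EASE variant replaces `k` by
#' `max(k - 1, 0)` before the tail sum, which is conservative by
#' construction. Benjamini-Hochberg q-values are computed across the
#' collection; the raw p-value remains the primary column.
#'
#' @param query character vector of gene symbols; genes outside the
#'   background are dropped with a warning.
#' @param background character vector of gene symbols (e.g. all genes
#'   surviving preprocessing on the array).
#' @param collection a [gene_set_collection()].
#' @param ease also compute the EASE p-value? (default TRUE)
#' @return Data frame of class `enrichment_result`, sorted by p-value, with
#'   columns `term`, `k`, `n`, `K`, `N`, `p`, `p_ease`, `q` and a list column
#'   `overlap` of the overlapping gene symbols.
#' @export
hypergeometric_enrichment <- function(query, background, collection,
                                      ease = TRUE) {
  background <- unique(as.character(background))
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  query <- unique(as.character(query))
  outside <- setdiff(query, background)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the background were ",
            "dropped", call. = FALSE)
    query <- setdiff(query, outside)
  }
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(collection), function(term) {
    term_genes <- intersect(collection[[term]], background)
    K <- length(term_genes)
    overlap <- intersect(query, term_genes)
    k <- length(overlap)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    ke <- max(k - 1L, 0L)
    pe <- if (ease) stats::phyper(ke - 1, K, N - K, n, lower.tail = FALSE)
          else NA_real_
    data.frame(term = term, k = k, n = n, K = K, N = N,
               p = p, p_ease = pe, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$overlap <- lapply(names(collection), function(term)
    intersect(query, intersect(collection[[term]], background)))
  ord <- order(out$p, out$term)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source") <- attr(collection, "source")
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Cross-tabulate enriched-term genes by expression cluster
#'
#' For every term, counts how many of its overlapping genes have at least one
#' probe in each cluster of the partition (a gene spanning clusters counts
#' once per cluster), and reports the modal cluster with its percentage of
#' the overlap, rounded to a whole percent.
#'
#' @param results an [hypergeometric_enrichment()] result.
#' @param partition a `partition` whose assignments cover the relevant probes
#'   (or any data frame with columns `probe_id` and `cluster`).
#' @param map probe-gene map data frame (`probe_id`, `gene`).
#' @return `results` with added list column `cluster_breakdown` (named counts
#'   per cluster) and columns `modal_cluster`, `modal_count`, `modal_pct`.
#' @export
crosstab_clusters <- function(results, partition, map) {
  stopifnot(inherits(results, "enrichment_result"))
  assignments <- if (inherits(partition, "partition"))
    partition$assignments else partition
  stopifnot(all(c("probe_id", "cluster") %in% names(assignments)))
  map <- validate_probe_gene_map(map)
  gene_of <- map$gene[match(assignments$probe_id, map$probe_id)]
  breakdowns <- vector("list", nrow(results))
  modal_cluster <- character(nrow(results))
  modal_count <- integer(nrow(results))
  modal_pct <- rep(NA_real_, nrow(results))
  for (i in seq_len(nrow(results))) {
    genes <- results$overlap[[i]]
    if (length(genes) == 0L) {
      breakdowns[[i]] <- integer()
      modal_cluster[i] <- NA_character_
      next
    }
    hit <- !is.na(gene_of) & gene_of %in% genes
    ## count genes (not probes) once per cluster
    gc <- unique(data.frame(gene = gene_of[hit],
                            cluster = assignments$cluster[hit]))
    tab <- table(gc$cluster)
    breakdowns[[i]] <- stats::setNames(as.integer(tab), names(tab))
    if (length(tab)) {
      m <- which.max(tab)
      modal_cluster[i] <- names(tab)[m]
      modal_count[i] <- as.integer(tab[m])
      modal_pct[i] <- round(100 * tab[[m]] / length(genes))
    }
  }
  results$cluster_breakdown <- breakdowns
  results$modal_cluster <- modal_cluster
  results$modal_count <- modal_count
  results$modal_pct <- modal_pct
  results
}

#' Write an enrichment table mirroring a term-by-cluster report
#'
#' @param results an enrichment result (after [crosstab_clusters()] if
#'   breakdown columns are wanted).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(results, path) {
  flat <- results
  flat$overlap <- vapply(results$overlap, paste, "", collapse = ",")
  if (!is.null(results$cluster_breakdown))
    flat$cluster_breakdown <- vapply(results$cluster_breakdown, function(b)
      paste(sprintf("%s(%d)", names(b), b), collapse = " "), "")
  utils::write.table(as.data.frame(flat), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
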