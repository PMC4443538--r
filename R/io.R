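#' Write an expression dataset in the pipeline's TSV dialect
#'
#' Dialect: header row 1 holds `probe_id` then the sample ids; header rows
#' 2--4 hold `group`, `week`, `replicate`; each data row holds the probe id
#' then `intensity:call` cells (e.g. `153.2:P`). Intensities are written with
#' 17 significant digits so that `read_expression_tsv(write_expression_tsv(x))`
#' reproduces `x` exactly.
#'
#' @param dataset an [expression_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  s <- dataset$samples
  header <- c(paste(c("probe_id", s$sample_id), collapse = "\t"),
              paste(c("group", s$group), collapse = "\t"),
              paste(c("week", s$week), collapse = "\t"),
              paste(c("replicate", s$replicate), collapse = "\t"))
  cells <- matrix(sprintf("%.17g:%s", dataset$intensity, dataset$calls),
                  nrow(dataset$intensity))
  body <- paste(probe_ids(dataset),
                apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an expression dataset from the pipeline's TSV dialect
#'
#' Counterpart of [write_expression_tsv()]; malformed cells are reported with
#' their row and column coordinates.
#'
#' @param path input path.
#' @return An [expression_dataset()].
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 5L)
    stop("expression TSV must have 4 header rows and >= 1 probe row",
         call. = FALSE)
  hdr <- strsplit(lines[1:4], "\t", fixed = TRUE)
  labels <- vapply(hdr, `[[`, "", 1L)
  if (!identical(labels, c("probe_id", "group", "week", "replicate")))
    stop("malformed header rows: expected probe_id/group/week/replicate",
         call. = FALSE)
  n_samp <- length(hdr[[1]]) - 1L
  if (any(lengths(hdr) != n_samp + 1L))
    stop("header rows have inconsistent lengths", call. = FALSE)
  samples <- data.frame(sample_id = hdr[[1]][-1],
                        group = hdr[[2]][-1],
                        week = as.numeric(hdr[[3]][-1]),
                        replicate = as.integer(hdr[[4]][-1]),
                        stringsAsFactors = FALSE)
  body <- strsplit(lines[-(1:4)], "\t", fixed = TRUE)
  bad_len <- which(lengths(body) != n_samp + 1L)
  if (length(bad_len))
    stop("row ", bad_len[1] + 4L, ": expected ", n_samp + 1L, " columns, got ",
         lengths(body)[bad_len[1]], call. = FALSE)
  probes <- vapply(body, `[[`, "", 1L)
  flat <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  parts <- regmatches(flat, regexpr(":", flat, fixed = TRUE), invert = TRUE)
  ok <- lengths(parts) == 2L
  vals <- rep(NA_real_, length(flat))
  calls <- rep(NA_character_, length(flat))
  vals[ok] <- suppressWarnings(
    as.numeric(vapply(parts[ok], `[[`, "", 1L)))
  calls[ok] <- vapply(parts[ok], `[[`, "", 2L)
  bad <- which(!ok | is.na(vals) | !calls %in% c("P", "M", "A") | vals <= 0)
  if (length(bad)) {
    row <- (bad[1] - 1L) %/% n_samp + 1L
    col <- (bad[1] - 1L) %% n_samp + 1L
    stop(sprintf("malformed cell '%s' at data row %d (probe '%s'), sample column %d ('%s')",
                 flat[bad[1]], row, probes[row], col, samples$sample_id[col]),
         call. = FALSE)
  }
  intensity <- matrix(vals, nrow = length(probes), ncol = n_samp, byrow = TRUE,
                      dimnames = list(probes, samples$sample_id))
  call_m <- matrix(calls, nrow = length(probes), ncol = n_samp, byrow = TRUE,
                   dimnames = dimnames(intensity))
  expression_dataset(intensity, call_m, samples)
}

#' Write / read the IHC counts table (CSV)
#'
#' Plain CSV with columns `rat`, `group`, `week`, `field`, `examiner`,
#' `percent`.
#'
#' @param table IHC data frame.
#' @param path file path.
#' @return `path` (write) or the data frame (read).
#' @export
write_ihc_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ihc_csv
#' @export
read_ihc_csv <- function(path) {
  if (!file.exists(path)) stop("IHC file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("rat", "group", "week", "field", "examiner", "percent")
  if (!all(req %in% names(d)))
    stop("IHC CSV must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  d
}

#' Write a partition's probe assignments and cluster summary
#'
#' @param partition a `partition`.
#' @param assignments_path,summary_path output TSV paths (NULL to skip one).
#' @return The partition, invisibly.
#' @export
write_partition_tsv <- function(partition, assignments_path = NULL,
                                summary_path = NULL) {
  stopifnot(inherits(partition, "partition"))
  if (!is.null(assignments_path))
    utils::write.table(partition$assignments, assignments_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path))
    utils::write.table(partition_summary(partition), summary_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(partition)
}
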