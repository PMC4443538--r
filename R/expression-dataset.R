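#' Expression dataset container
#'
#' An `expression_dataset` bundles a probe-by-sample intensity matrix, the
#' aligned detection-call matrix (Present/Marginal/Absent symbols as produced
#' by MAS5-style summarization), and per-sample metadata. It is the raw input
#' of the preprocessing stage; intensities are on an arbitrary positive
#' MAS5-like scale (target value 100).
#'
#' @param intensity numeric matrix, probes in rows, samples in columns; all
#'   values must be strictly positive.
#' @param calls character matrix of detection calls (`"P"`, `"M"` or `"A"`),
#'   same dimensions and dimnames as `intensity`.
#' @param samples data frame with one row per column of `intensity` and
#'   columns `sample_id`, `group`, `week`, `replicate`.
#'
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(intensity, calls, samples) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("`intensity` must be a numeric matrix", call. = FALSE)
  if (!is.matrix(calls) || !identical(dim(calls), dim(intensity)))
    stop("`calls` must be a character matrix with the same shape as `intensity`",
         call. = FALSE)
  if (is.null(rownames(intensity)))
    stop("`intensity` must have probe ids as rownames", call. = FALSE)
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop("intensities must be finite and strictly positive", call. = FALSE)
  req <- c("sample_id", "group", "week", "replicate")
  if (!is.data.frame(samples) || !all(req %in% names(samples)))
    stop("`samples` must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (nrow(samples) != ncol(intensity))
    stop("`samples` must have one row per sample column", call. = FALSE)
  bad <- which(!calls %in% c("P", "M", "A"))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(calls))
    stop(sprintf(
      "unknown detection call %s for probe '%s', sample '%s'",
      dQuote(calls[bad[1]]), rownames(intensity)[i[1]],
      samples$sample_id[i[2]]), call. = FALSE)
  }
  colnames(intensity) <- samples$sample_id
  dimnames(calls) <- dimnames(intensity)
  structure(
    list(intensity = intensity, calls = calls,
         samples = as.data.frame(samples)),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d probes x %d samples\n",
              nrow(x$intensity), ncol(x$intensity)))
  cat("  groups: ", paste(unique(x$samples$group), collapse = ", "), "\n",
      sep = "")
  cat("  weeks:  ", paste(sort(unique(x$samples$week)), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$intensity)

#' Probe identifiers of a dataset
#' @param dataset an `expression_dataset`.
#' @return Character vector of probe ids.
#' @export
probe_ids <- function(dataset) rownames(dataset$intensity)

#' Restrict a dataset to a subset of probes
#' @param dataset an `expression_dataset`.
#' @param probes character vector of probe ids to keep (order preserved).
#' @return The subsetted `expression_dataset`.
#' @export
subset_probes <- function(dataset, probes) {
  stopifnot(inherits(dataset, "expression_dataset"))
  missing <- setdiff(probes, probe_ids(dataset))
  if (length(missing))
    stop("unknown probe ids: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  expression_dataset(dataset$intensity[probes, , drop = FALSE],
                     dataset$calls[probes, , drop = FALSE],
                     dataset$samples)
}
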