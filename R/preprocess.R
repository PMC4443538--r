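#' Preprocessing configuration
#'
#' Settings for the two filtering rules and the log2-ratio transform. The
#' defaults mirror a MAS5-summarized chip scaled to a target value of 100:
#' probes called absent in every sample are dropped, then probes whose
#' per-week median never reaches the expression floor are dropped, and
#' remaining per-week medians are expressed as log2 ratios against the
#' baseline week.
#'
#' @param expression_floor positive scalar; a probe is removed when its
#'   per-week median intensity is below this floor at every week (default 100,
#'   the MAS5 target value).
#' @param baseline_week integer; the reference week whose median forms the
#'   denominator of the log2 ratios (default 1).
#' @param absent_symbol detection-call symbol treated as absent (default "A").
#'
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(expression_floor = 100, baseline_week = 1,
                              absent_symbol = "A") {
  stopifnot(is.numeric(expression_floor), expression_floor > 0)
  structure(list(expression_floor = expression_floor,
                 baseline_week = as.integer(baseline_week),
                 absent_symbol = absent_symbol),
            class = "preprocess_config")
}

#' Remove probes called absent in every sample
#'
#' A probe is removed if and only if its detection call equals the absent
#' symbol in every sample of the dataset; all other probes are retained with
#' values untouched. The removed probe ids are attached as the
#' `"removed"` attribute and the count is reported.
#'
#' @param dataset an [expression_dataset()].
#' @param config a [preprocess_config()].
#' @return The filtered `expression_dataset`, with attribute `removed` (the
#'   dropped probe ids).
#' @export
filter_absent <- function(dataset, config = preprocess_config()) {
  stopifnot(inherits(dataset, "expression_dataset"))
  all_absent <- rowSums(dataset$calls != config$absent_symbol) == 0L
  kept <- subset_probes(dataset, probe_ids(dataset)[!all_absent])
  attr(kept, "removed") <- probe_ids(dataset)[all_absent]
  message(sprintf("filter_absent: removed %d of %d probes (all-absent), %d retained",
                  sum(all_absent), nrow(dataset$intensity), sum(!all_absent)))
  kept
}

#' Remove probes below the expression floor at every week
#'
#' Operates on an absent-filtered dataset: a probe is removed if and only if
#' its per-week median intensity is below `expression_floor` at all weeks;
#' retention requires at least one week at or above the floor.
#'
#' @inheritParams filter_absent
#' @return The filtered `expression_dataset`, with attribute `removed`.
#' @export
filter_low_expression <- function(dataset, config = preprocess_config()) {
  stopifnot(inherits(dataset, "expression_dataset"))
  med <- median_by_timepoint(dataset)
  below <- rowSums(med >= config$expression_floor) == 0L
  kept <- subset_probes(dataset, rownames(med)[!below])
  attr(kept, "removed") <- rownames(med)[below]
  message(sprintf("filter_low_expression: removed %d of %d probes (< %g at all weeks), %d retained",
                  sum(below), nrow(med), config$expression_floor, sum(!below)))
  kept
}

#' Per-week replicate medians
#'
#' Collapses replicate arrays to one value per probe per week using the
#' standard sample median (even replicate counts take the midpoint of the two
#' central order statistics).
#'
#' @param dataset an [expression_dataset()]; every week must have at least one
#'   replicate.
#' @return Numeric matrix of medians, probes in rows, one column per week in
#'   increasing week order (class `median_profiles`).
#' @export
median_by_timepoint <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  weeks <- sort(unique(dataset$samples$week))
  out <- matrix(NA_real_, nrow(dataset$intensity), length(weeks),
                dimnames = list(probe_ids(dataset), as.character(weeks)))
  for (j in seq_along(weeks)) {
    cols <- dataset$samples$week == weeks[j]
    if (!any(cols))
      stop("no replicate for week ", weeks[j], call. = FALSE)
    sub <- dataset$intensity[, cols, drop = FALSE]
    out[, j] <- apply(sub, 1L, stats::median)
  }
  class(out) <- c("median_profiles", class(out))
  out
}

#' Log2-ratio profiles against the baseline week
#'
#' For each probe, computes `log2(median_week / median_baseline)` at every
#' non-baseline week, in week order. The baseline week's ratio is identically
#' zero and is excluded by default; `include_baseline = TRUE` appends the
#' zero column for plotting parity.
#'
#' @param medians a `median_profiles` matrix from [median_by_timepoint()].
#' @param config a [preprocess_config()] supplying the baseline week.
#' @param include_baseline keep the identically-zero baseline column?
#' @return Numeric matrix of log2 ratios, probes in rows, non-baseline weeks
#'   in columns (class `log2_ratio_profiles`).
#' @export
log2_ratio_profiles <- function(medians, config = preprocess_config(),
                                include_baseline = FALSE) {
  weeks <- as.numeric(colnames(medians))
  base <- which(weeks == config$baseline_week)
  if (length(base) != 1L)
    stop("baseline week ", config$baseline_week, " not present in medians",
         call. = FALSE)
  if (any(medians <= 0)) {
    bad <- rownames(medians)[which(rowSums(medians <= 0) > 0)[1]]
    stop("non-positive median for probe '", bad,
         "': log2 ratio undefined", call. = FALSE)
  }
  ratios <- log2(medians / medians[, base])
  keep <- if (include_baseline) seq_along(weeks) else seq_along(weeks)[-base]
  out <- ratios[, keep, drop = FALSE]
  class(out) <- c("log2_ratio_profiles", "matrix", "array")
  out
}

#' Run both filters and report stage counts
#'
#' Convenience wrapper applying [filter_absent()] then
#' [filter_low_expression()], returning the filtered dataset together with the
#' bookkeeping counts (`n_initial = n_all_absent + n_below_floor + n_retained`).
#'
#' @inheritParams filter_absent
#' @return A list with elements `dataset` (filtered), `n_initial`,
#'   `n_all_absent`, `n_below_floor`, `n_retained`.
#' @export
preprocess_dataset <- function(dataset, config = preprocess_config()) {
  n0 <- nrow(dataset$intensity)
  step1 <- filter_absent(dataset, config)
  step2 <- filter_low_expression(step1, config)
  list(dataset = step2,
       n_initial = n0,
       n_all_absent = length(attr(step1, "removed")),
       n_below_floor = length(attr(step2, "removed")),
       n_retained = nrow(step2$intensity))
}
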