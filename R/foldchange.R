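#' Signed fold changes and bin labels versus the baseline week
#'
#' For each probe and each non-baseline week, computes the ratio
#' `r = median_week / median_baseline`, the signed fold change
#' (`r` when `r >= 1`, `-1/r` otherwise, so magnitudes are symmetric across
#' directions), and a bin label among `up_1.5_2`, `up_ge2`, `down_1.5_2`,
#' `down_ge2`, `none`. Bins are half-open on the magnitude: `[1.5, 2)` and
#' `[2, Inf)`; anything below 1.5-fold is `none`.
#'
#' @param medians a `median_profiles` matrix from [median_by_timepoint()].
#' @param baseline_week reference week (default 1).
#' @return A list of class `fold_change_table` with matrices `ratio`, `sfc`
#'   and `bin` (probes x non-baseline weeks).
#' @export
compute_fold_changes <- function(medians, baseline_week = 1) {
  weeks <- as.numeric(colnames(medians))
  base <- which(weeks == baseline_week)
  if (length(base) != 1L)
    stop("baseline week ", baseline_week, " not present in medians",
         call. = FALSE)
  stopifnot(all(medians > 0))
  ratio <- medians[, -base, drop = FALSE] / medians[, base]
  sfc <- ifelse(ratio >= 1, ratio, -1 / ratio)
  mag <- abs(sfc)
  bin <- matrix("none", nrow(ratio), ncol(ratio), dimnames = dimnames(ratio))
  bin[mag >= 1.5 & mag < 2 & sfc > 0] <- "up_1.5_2"
  bin[mag >= 2 & sfc > 0] <- "up_ge2"
  bin[mag >= 1.5 & mag < 2 & sfc < 0] <- "down_1.5_2"
  bin[mag >= 2 & sfc < 0] <- "down_ge2"
  structure(list(ratio = ratio, sfc = sfc, bin = bin,
                 weeks = weeks[-base], baseline_week = baseline_week),
            class = "fold_change_table")
}

#' Bin levels used in a fold-change table
#' @keywords internal
fc_bins <- c("up_1.5_2", "up_ge2", "down_1.5_2", "down_ge2", "none")

#' Direction summary of a fold-change table
#'
#' Tabulates per-week bin counts and counts distinct probes changing in each
#' direction: a probe counts once per direction no matter how many weeks it
#' crosses the 1.5-fold threshold, and a probe crossing in both directions
#' (at different weeks) appears in both totals and is flagged.
#'
#' @param table a [compute_fold_changes()] result.
#' @return A list of class `direction_summary` with `per_week_counts`
#'   (bins x weeks), `up_total`, `down_total`, `both_directions` (flagged
#'   probe ids), and logical event matrices `up_at`, `down_at`.
#' @export
summarize_directions <- function(table) {
  stopifnot(inherits(table, "fold_change_table"))
  bin <- table$bin
  counts <- vapply(seq_len(ncol(bin)), function(j)
    table(factor(bin[, j], levels = fc_bins)), integer(length(fc_bins)))
  dimnames(counts) <- list(fc_bins, colnames(bin))
  up_at <- bin == "up_1.5_2" | bin == "up_ge2"
  down_at <- bin == "down_1.5_2" | bin == "down_ge2"
  up_probes <- rownames(bin)[rowSums(up_at) > 0]
  down_probes <- rownames(bin)[rowSums(down_at) > 0]
  structure(list(per_week_counts = counts,
                 up_total = length(up_probes),
                 down_total = length(down_probes),
                 up_probes = up_probes,
                 down_probes = down_probes,
                 both_directions = intersect(up_probes, down_probes),
                 up_at = up_at, down_at = down_at),
            class = "direction_summary")
}

#' Attribution percentage of a direction to a subset of weeks
#'
#' The fraction (as a percentage, rounded to one decimal) of the distinct
#' probes changing in `direction` at any week whose change occurs at one of
#' the named `weeks`. Percentages over a partition of the weeks need not sum
#' to 100 because a probe can cross the threshold at several weeks.
#'
#' @param summary a [summarize_directions()] result.
#' @param direction `"up"` or `"down"`.
#' @param weeks weeks attributing the event (matched against column names).
#' @return A list with `count`, `total` and `percent` (`NA` when `total` is 0).
#' @export
attribution <- function(summary, direction = c("up", "down"), weeks) {
  stopifnot(inherits(summary, "direction_summary"))
  direction <- match.arg(direction)
  at <- if (direction == "up") summary$up_at else summary$down_at
  total <- if (direction == "up") summary$up_total else summary$down_total
  cols <- as.character(weeks)
  if (!all(cols %in% colnames(at)))
    stop("weeks not present in the fold-change table: ",
         paste(setdiff(cols, colnames(at)), collapse = ", "), call. = FALSE)
  count <- sum(rowSums(at[, cols, drop = FALSE]) > 0)
  percent <- if (total == 0) NA_real_ else round(100 * count / total, 1)
  list(count = count, total = total, percent = percent)
}

#' @export
print.direction_summary <- function(x, ...) {
  cat("direction_summary\n")
  print(x$per_week_counts)
  cat(sprintf("distinct probes up >= 1.5-fold at any week:   %d\n", x$up_total))
  cat(sprintf("distinct probes down >= 1.5-fold at any week: %d\n", x$down_total))
  if (length(x$both_directions))
    cat(sprintf("probes crossing in both directions: %d\n",
                length(x$both_directions)))
  invisible(x)
}
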