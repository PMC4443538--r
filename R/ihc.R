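#' Score immunohistochemistry fields from two-examiner counts
#'
#' For every (rat, field), averages the two examiners' percent-positive
#' counts and records the absolute inter-rater difference; within each rat
#' the single field with the largest difference is marked removed (ties
#' remove the lowest field index). With the four-field design this leaves
#' three fields per rat for the statistics.
#'
#' @param table data frame with columns `rat`, `group`, `week`, `field`,
#'   `examiner`, `percent` (percent positive in \[0, 100\]); exactly two
#'   examiner rows per (rat, field).
#' @return Data frame of class `field_scores` with one row per (rat, field):
#'   `rat`, `group`, `week`, `field`, `mean`, `inter_rater_diff`, `removed`.
#' @export
score_fields <- function(table) {
  req <- c("rat", "group", "week", "field", "examiner", "percent")
  if (!is.data.frame(table) || !all(req %in% names(table)))
    stop("IHC table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(table$percent < 0 | table$percent > 100))
    stop("percent positive must lie in [0, 100]", call. = FALSE)
  key <- interaction(table$rat, table$field, drop = TRUE)
  n_per <- table(key)
  if (any(n_per != 2L)) {
    bad <- names(n_per)[n_per != 2L][1]
    stop("field ", bad, " does not have exactly 2 examiner rows",
         call. = FALSE)
  }
  agg <- do.call(rbind, lapply(split(table, key), function(d) {
    data.frame(rat = d$rat[1], group = d$group[1], week = d$week[1],
               field = d$field[1],
               mean = mean(d$percent),
               inter_rater_diff = abs(diff(d$percent)),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$rat, agg$field), , drop = FALSE]
  agg$removed <- FALSE
  for (r in unique(agg$rat)) {
    i <- which(agg$rat == r)
    worst <- i[which.max(agg$inter_rater_diff[i])]  # first max = lowest field
    agg$removed[worst] <- TRUE
  }
  rownames(agg) <- NULL
  class(agg) <- c("field_scores", "data.frame")
  agg
}

## H statistic with tie correction from first principles; defined as 0 when
## every observation ties (the tie-correction denominator vanishes there).
kw_statistic <- function(values, groups) {
  if (length(unique(values)) == 1L) return(0)
  ks <- stats::kruskal.test(values, factor(groups))
  unname(ks$statistic)
}

#' Per-week Kruskal-Wallis comparison of sham and immobilized field scores
#'
#' Pools the retained fields (3 per rat in the four-field design) within each
#' week and compares the two groups with the rank-based Kruskal-Wallis test
#' (tie-corrected H, chi-square approximation with groups - 1 degrees of
#' freedom). When every value ties the statistic is defined as 0 with p = 1.
#' An exact permutation p-value over all group splits is available for the
#' small samples typical of this design. Weeks missing a group are skipped
#' with a warning.
#'
#' @param scores a [score_fields()] result (rows with `removed = TRUE` are
#'   excluded).
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @param exact also compute the exact permutation p-value? Enumerates all
#'   `choose(n, n1)` splits, so use only at small n.
#' @param max_exact_splits upper bound on the splits enumerated per week;
#'   weeks exceeding it report `p_exact = NA` with a warning.
#' @return Data frame with one row per analysable week: `week`, `H`, `p`,
#'   `p_exact` (NA unless `exact`), group medians and `significant`.
#' @export
kruskal_wallis_by_week <- function(scores, alpha = 0.05, exact = FALSE,
                                   max_exact_splits = 1e5) {
  stopifnot(inherits(scores, "data.frame"))
  use <- scores[!scores$removed, , drop = FALSE]
  out <- list()
  for (wk in sort(unique(use$week))) {
    d <- use[use$week == wk, , drop = FALSE]
    grps <- unique(d$group)
    if (length(grps) < 2L) {
      warning("week ", wk, ": only one group present, skipped", call. = FALSE)
      next
    }
    vals <- d$mean
    g <- factor(d$group)
    if (length(unique(vals)) == 1L) {
      H <- 0; p <- 1
    } else {
      ks <- stats::kruskal.test(vals, g)
      H <- unname(ks$statistic); p <- ks$p.value
    }
    p_exact <- NA_real_
    if (exact && choose(length(vals), sum(g == levels(g)[1])) >
          max_exact_splits) {
      warning("week ", wk, ": too many splits for exact enumeration, ",
              "reporting NA", call. = FALSE)
    } else if (exact) {
      idx1 <- which(g == levels(g)[1])
      splits <- utils::combn(length(vals), length(idx1))
      h_obs <- kw_statistic(vals, g)
      h_perm <- apply(splits, 2L, function(s) {
        gp <- rep(levels(g)[2], length(vals))
        gp[s] <- levels(g)[1]
        kw_statistic(vals, gp)
      })
      p_exact <- mean(h_perm >= h_obs - 1e-12)
    }
    meds <- tapply(vals, g, stats::median)
    row <- data.frame(week = wk, H = H, p = p, p_exact = p_exact,
                      stringsAsFactors = FALSE)
    for (nm in names(meds)) row[[paste0("median_", nm)]] <- unname(meds[nm])
    row$significant <- p < alpha
    out[[length(out) + 1L]] <- row
  }
  if (!length(out)) stop("no week with both groups present", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
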