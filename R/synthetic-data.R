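#' Simulation configuration for planted-trajectory expression data
#'
#' Describes a synthetic MAS5-like dataset emulating a two-group, five-week,
#' replicated single-channel array study: log-normally distributed baseline
#' intensities rescaled so the trimmed mean of all values is about 100 (the
#' MAS5 target value), planted polynomial log2-ratio trajectories in probe
#' clusters, replicate noise on the log2 scale, a fixed fraction of probes
#' called absent in every sample, and a fixed fraction of the remainder kept
#' below the expression floor at every week.
#'
#' @param n_probes total number of probe sets.
#' @param cluster_spec list of planted clusters, each
#'   `list(coef = <polynomial coefficients in log2-ratio space over
#'   standardized non-baseline time>, size = <member count>)`; sizes must sum
#'   to `n_probes`. A flat cluster (`coef = 0`) plays the role of unchanged
#'   probes.
#' @param n_replicates_per_cell arrays per (group, week) cell (default 4).
#' @param weeks strictly increasing time points; the first is the baseline
#'   (default 1, 2, 4, 8, 16).
#' @param baseline_log2_mean,baseline_log2_sd mean and sd of the log2
#'   baseline intensity (defaults 9 and 1.5, spanning the MAS5 scale).
#' @param replicate_noise_sd replicate noise sd on the log2 scale.
#' @param absent_fraction fraction of probes called absent in every sample.
#' @param low_floor_fraction fraction of the non-absent probes forced below
#'   the expression floor at every week.
#' @param marginal_rate rate of "M" calls among present probes (default 2%),
#'   exercising call-parsing robustness (the filters treat only "A"
#'   specially).
#' @param expression_floor the floor used to plant low-expressed probes
#'   (default 100).
#' @param seed integer seed; identical configs give identical datasets.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes, cluster_spec,
                       n_replicates_per_cell = 4,
                       weeks = c(1, 2, 4, 8, 16),
                       baseline_log2_mean = 9, baseline_log2_sd = 1.5,
                       replicate_noise_sd = 0.25,
                       absent_fraction = 0, low_floor_fraction = 0,
                       marginal_rate = 0.02,
                       expression_floor = 100,
                       seed = 1L) {
  sizes <- vapply(cluster_spec, function(cl) as.integer(cl$size), 1L)
  if (sum(sizes) != n_probes)
    stop("cluster_spec member counts (", sum(sizes),
         ") must sum to n_probes (", n_probes, ")", call. = FALSE)
  props <- c(absent_fraction, low_floor_fraction, marginal_rate)
  if (any(props < 0 | props > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (replicate_noise_sd <= 0)
    stop("replicate_noise_sd must be positive", call. = FALSE)
  if (any(diff(weeks) <= 0))
    stop("weeks must be strictly increasing", call. = FALSE)
  structure(list(n_probes = as.integer(n_probes), cluster_spec = cluster_spec,
                 n_replicates_per_cell = as.integer(n_replicates_per_cell),
                 weeks = weeks,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 replicate_noise_sd = replicate_noise_sd,
                 absent_fraction = absent_fraction,
                 low_floor_fraction = low_floor_fraction,
                 marginal_rate = marginal_rate,
                 expression_floor = expression_floor,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Planted log2-ratio trajectories of a configuration
#'
#' Evaluates each planted cluster's polynomial on the standardized
#' non-baseline weeks (the same standardization the clustering design uses).
#'
#' @param config a [sim_config()].
#' @return Matrix, clusters x non-baseline weeks, of true center values.
#' @export
planted_centers <- function(config) {
  wnb <- config$weeks[-1]
  out <- t(vapply(config$cluster_spec, function(cl) {
    coef <- cl$coef
    X <- time_design(wnb, length(coef) - 1L)
    drop(X %*% coef)
  }, numeric(length(wnb))))
  dimnames(out) <- list(sprintf("planted_%d", seq_along(config$cluster_spec)),
                        as.character(wnb))
  out
}

#' Generate a synthetic expression dataset with planted structure
#'
#' Produces one `expression_dataset` for the requested group label together
#' with the planted truth. Exactly `round(absent_fraction * n_probes)` probes
#' are called "A" in every sample (their intensities remain positive: absence
#' is a call, not a zero); exactly `round(low_floor_fraction * remaining)`
#' probes have every per-week median below the expression floor; the
#' remaining probes follow `baseline * 2^(cluster trajectory + replicate
#' noise)` and are guaranteed at least one week median at or above the floor.
#' The same seed yields identical output.
#'
#' @param config a [sim_config()].
#' @param group group label for the samples (default "immobilized").
#' @return A list with `dataset` (an [expression_dataset()]) and `truth`, a
#'   list with `assignments` (data frame `probe_id`, `cluster`, `status` in
#'   planted/absent/low_expressed) and `centers` (from [planted_centers()]).
#' @export
generate_expression_dataset <- function(config, group = "immobilized") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_probes
  weeks <- config$weeks
  reps <- config$n_replicates_per_cell
  probes <- sprintf("probe_%06d", seq_len(n))

  sizes <- vapply(config$cluster_spec, function(cl) as.integer(cl$size), 1L)
  label <- rep(seq_along(sizes), sizes)

  n_abs <- round(config$absent_fraction * n)
  absent_idx <- sort(sample.int(n, n_abs))
  rest <- setdiff(seq_len(n), absent_idx)
  n_low <- round(config$low_floor_fraction * length(rest))
  low_idx <- sort(rest[sample.int(length(rest), n_low)])
  status <- rep("planted", n)
  status[absent_idx] <- "absent"
  status[low_idx] <- "low_expressed"

  samples <- expand.grid(replicate = seq_len(reps), week = weeks,
                         KEEP.OUT.ATTRS = FALSE)
  samples <- samples[order(samples$week, samples$replicate), ]
  samples <- data.frame(
    sample_id = sprintf("%s_wk%02d_r%d", group, samples$week,
                        samples$replicate),
    group = group, week = samples$week, replicate = samples$replicate,
    stringsAsFactors = FALSE)

  centers <- planted_centers(config)
  ## trajectory per probe per sample: 0 at the baseline week
  traj_full <- cbind(0, centers)[, match(samples$week, weeks), drop = FALSE]

  baseline <- 2^stats::rnorm(n, config$baseline_log2_mean,
                             config$baseline_log2_sd)
  noise <- matrix(stats::rnorm(n * nrow(samples), 0,
                               config$replicate_noise_sd),
                  n, nrow(samples))
  intensity <- baseline * 2^(traj_full[label, , drop = FALSE] + noise)
  dimnames(intensity) <- list(probes, samples$sample_id)

  ## rescale so the 2%-trimmed mean of all values sits at the MAS5 target
  tm <- mean(intensity, trim = 0.02)
  intensity <- intensity * 100 / tm

  floor <- config$expression_floor
  ## plant the below-floor probes: uniform positives strictly under the floor
  if (n_low > 0)
    intensity[low_idx, ] <- matrix(
      stats::runif(n_low * nrow(samples), 0.1 * floor, 0.9 * floor),
      n_low, nrow(samples))
  ## guarantee the planted probes at least one week median at the floor
  planted_idx <- which(status == "planted")
  if (length(planted_idx)) {
    med <- vapply(weeks, function(w)
      apply(intensity[planted_idx, samples$week == w, drop = FALSE], 1L,
            stats::median), numeric(length(planted_idx)))
    maxmed <- apply(matrix(med, length(planted_idx)), 1L, max)
    bump <- maxmed < floor
    if (any(bump))
      intensity[planted_idx[bump], ] <-
        intensity[planted_idx[bump], , drop = FALSE] *
        (1.05 * floor / maxmed[bump])
  }

  calls <- matrix("P", n, nrow(samples), dimnames = dimnames(intensity))
  m_mask <- matrix(stats::runif(n * nrow(samples)) < config$marginal_rate,
                   n, nrow(samples))
  calls[m_mask] <- "M"
  calls[absent_idx, ] <- "A"

  truth <- list(
    assignments = data.frame(probe_id = probes,
                             cluster = label,
                             status = status,
                             stringsAsFactors = FALSE),
    centers = centers)
  list(dataset = expression_dataset(intensity, calls, samples),
       truth = truth)
}

#' Generate a synthetic two-examiner IHC count table
#'
#' Emulates percent-positive DAB counts: per rat, `n_fields` microscope
#' fields each counted by two independent examiners. The true field value is
#' the cell mean plus field-to-field biological variation; each examiner
#' observes it with independent error `examiner_sd` (0 makes the two
#' examiners identical). All values are clipped to \[0, 100\].
#'
#' @param n_rats_per_cell rats per (group, week) cell.
#' @param group_effects data frame with columns `group`, `week`, `mean`
#'   (percent positive in \[0, 100\]) defining the cell means.
#' @param examiner_sd sd of examiner error (>= 0).
#' @param field_sd sd of between-field variation (default 5).
#' @param n_fields fields per rat (default 4).
#' @param seed integer seed.
#' @return Data frame with columns `rat`, `group`, `week`, `field`,
#'   `examiner`, `percent`.
#' @export
generate_ihc_dataset <- function(n_rats_per_cell, group_effects,
                                 examiner_sd, field_sd = 5, n_fields = 4,
                                 seed = 1L) {
  if (examiner_sd < 0) stop("examiner_sd must be >= 0", call. = FALSE)
  if (field_sd < 0) stop("field_sd must be >= 0", call. = FALSE)
  stopifnot(all(c("group", "week", "mean") %in% names(group_effects)))
  if (any(group_effects$mean < 0 | group_effects$mean > 100))
    stop("cell means must lie in [0, 100]", call. = FALSE)
  set.seed(seed)
  rows <- list()
  rat_no <- 0L
  for (i in seq_len(nrow(group_effects))) {
    g <- group_effects$group[i]; w <- group_effects$week[i]
    mu <- group_effects$mean[i]
    for (r in seq_len(n_rats_per_cell)) {
      rat_no <- rat_no + 1L
      truth <- pmin(100, pmax(0, mu + stats::rnorm(n_fields, 0, field_sd)))
      for (f in seq_len(n_fields)) {
        obs <- pmin(100, pmax(0, truth[f] + stats::rnorm(2, 0, examiner_sd)))
        rows[[length(rows) + 1L]] <- data.frame(
          rat = sprintf("rat_%03d", rat_no), group = g, week = w,
          field = f, examiner = c("E1", "E2"), percent = obs,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
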