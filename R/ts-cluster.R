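#' Clustering model configuration
#'
#' The clustering engine models each log2-ratio trajectory as a polynomial
#' regression on standardized time with a conjugate normal--inverse-gamma
#' prior, so the marginal likelihood of any set of trajectories is available
#' in closed form and clusters are merged greedily while the Bayes factor
#' favours merging. With an order-3 polynomial on four time points the
#' per-series design is saturated; the proper prior keeps the marginal
#' likelihood finite and merge decisions are driven by agreement across
#' series rather than per-series fit.
#'
#' @param polynomial_order non-negative integer degree of the time polynomial
#'   (default 3).
#' @param prior_mean prior mean of the regression coefficients (recycled to
#'   length `polynomial_order + 1`; default 0).
#' @param prior_scale positive scalar `tau`; the prior coefficient covariance
#'   is `sigma^2 * tau^2 * I` (default 1).
#' @param noise_prior_shape,noise_prior_rate shape `a0` and rate `b0` of the
#'   inverse-gamma prior on the noise variance `sigma^2` (defaults 1 and 0.1,
#'   a weak prior centred on fold-change-scale noise).
#' @param inclusion_threshold profiles enter the clustering only if some
#'   absolute log2 ratio strictly exceeds this value (default 1, i.e. 2-fold).
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(polynomial_order = 3, prior_mean = 0,
                           prior_scale = 1, noise_prior_shape = 1,
                           noise_prior_rate = 0.1,
                           inclusion_threshold = 1) {
  stopifnot(polynomial_order >= 0, prior_scale > 0,
            noise_prior_shape > 0, noise_prior_rate > 0)
  p <- polynomial_order + 1L
  structure(list(polynomial_order = as.integer(polynomial_order),
                 prior_mean = rep_len(prior_mean, p),
                 prior_scale = prior_scale,
                 noise_prior_shape = noise_prior_shape,
                 noise_prior_rate = noise_prior_rate,
                 inclusion_threshold = inclusion_threshold),
            class = "cluster_config")
}

#' Polynomial design matrix on standardized time
#'
#' Weeks are centred and scaled to unit variance before the Vandermonde
#' expansion `1, x, x^2, ..., x^order`, which keeps the design well
#' conditioned out to week 16.
#'
#' @param weeks numeric vector of time points.
#' @param order polynomial degree.
#' @return Numeric matrix with `length(weeks)` rows and `order + 1` columns.
#' @export
time_design <- function(weeks, order) {
  x <- if (length(weeks) > 1L && stats::sd(weeks) > 0)
    (weeks - mean(weeks)) / stats::sd(weeks) else weeks - mean(weeks)
  outer(x, 0:order, `^`)
}

#' Restrict profiles to those crossing the fold-change threshold
#'
#' Retains a profile iff `max_t |value_t|` strictly exceeds the inclusion
#' threshold (1 in log2 units, i.e. more than 2-fold up or down at one or
#' more time points).
#'
#' @param profiles a `log2_ratio_profiles` matrix.
#' @param config a [cluster_config()].
#' @return The retained rows of `profiles`.
#' @export
inclusion_filter <- function(profiles, config = cluster_config()) {
  keep <- apply(abs(profiles), 1L, max) > config$inclusion_threshold
  out <- profiles[keep, , drop = FALSE]
  class(out) <- class(profiles)
  out
}

## -- conjugate marginal likelihood ------------------------------------------

## Sufficient-statistic evaluator. All member trajectories of a cluster share
## the same per-series design X1 (T x p), so a cluster of m members stacks to
## X'X = m * X1'X1, X'y = X1' * colSums(Y), y'y = sum(Y^2). The normal--
## inverse-gamma evidence then needs only (m, s, yty).
make_logml_engine <- function(weeks, config) {
  X1 <- time_design(weeks, config$polynomial_order)
  p <- ncol(X1)
  G <- crossprod(X1)                      # X1'X1
  Tn <- nrow(X1)
  tau <- config$prior_scale
  m0 <- config$prior_mean
  a0 <- config$noise_prior_shape
  b0 <- config$noise_prior_rate
  L0 <- diag(p) / tau^2
  logdet_L0 <- -2 * p * log(tau)
  L0m0 <- L0 %*% m0
  m0L0m0 <- drop(crossprod(m0, L0m0))
  cache <- new.env(parent = emptyenv())
  ## logML for a cluster of m members with trajectory sum s and sum of squares
  ## yty; closed form of the multivariate Student-t evidence.
  function(m, s, yty) {
    key <- as.character(m)
    ent <- cache[[key]]
    if (is.null(ent)) {
      Ln <- L0 + m * G
      ch <- chol(Ln)
      ent <- list(ch = ch, logdet = 2 * sum(log(diag(ch))))
      cache[[key]] <- ent
    }
    b <- L0m0 + crossprod(X1, s)          # L0 m0 + X'y
    mun <- backsolve(ent$ch, forwardsolve(t(ent$ch), b))
    quad <- drop(crossprod(b, mun))       # mun' Ln mun
    n <- m * Tn
    an <- a0 + n / 2
    bn <- b0 + 0.5 * (yty + m0L0m0 - quad)
    -(n / 2) * log(2 * pi) + 0.5 * (logdet_L0 - ent$logdet) +
      a0 * log(b0) - an * log(bn) + lgamma(an) - lgamma(a0)
  }
}

#' Marginal log-likelihood of a set of trajectories under one cluster model
#'
#' Stacks the member trajectories into a single polynomial regression on the
#' standardized time design and integrates the Gaussian likelihood over the
#' conjugate normal--inverse-gamma prior on (coefficients, noise variance).
#' The value is the closed-form multivariate Student-t evidence; no sampling
#' is involved, and it is invariant to the stacking order of the rows.
#'
#' @param profiles numeric matrix (rows are trajectories over the same weeks)
#'   or a single numeric vector.
#' @param config a [cluster_config()].
#' @param weeks numeric time points of the columns; defaults to the column
#'   names of `profiles`.
#' @return The marginal log-likelihood (scalar).
#' @export
marginal_log_likelihood <- function(profiles, config = cluster_config(),
                                    weeks = NULL) {
  if (is.vector(profiles)) profiles <- matrix(profiles, nrow = 1L)
  if (nrow(profiles) == 0L) stop("empty profile set", call. = FALSE)
  if (is.null(weeks)) weeks <- as.numeric(colnames(profiles))
  if (any(is.na(weeks))) stop("supply `weeks` or name the profile columns",
                              call. = FALSE)
  engine <- make_logml_engine(weeks, config)
  engine(nrow(profiles), colSums(profiles), sum(profiles^2))
}

## -- greedy Bayes-factor agglomeration --------------------------------------

#' Agglomerative Bayesian clustering of log2-ratio trajectories
#'
#' Starts from singleton clusters and repeatedly merges the pair with the
#' largest log Bayes factor `logML(merged) - logML(A) - logML(B)`, stopping
#' when no pair has a strictly positive log Bayes factor; the number of
#' clusters is therefore emergent. All candidate pairs are evaluated at every
#' step, and ties on the log Bayes factor are broken toward the pair whose
#' smallest member probe id sorts first (then the partner's smallest id), so
#' the result is deterministic and invariant to input row order up to
#' cluster relabelling.
#'
#' @param profiles a `log2_ratio_profiles` matrix (rows are probes, rownames
#'   are probe ids, column names are weeks).
#' @param config a [cluster_config()].
#' @return A list of class `partition` with `clusters` (each a list with
#'   `members`, `logml`, and later `center`, `selected`, `trend`),
#'   `assignments` (data frame probe_id, cluster), `score` (sum of cluster
#'   marginal log-likelihoods), and `trace` (data frame of merges with log
#'   Bayes factors, all strictly positive).
#' @export
agglomerate <- function(profiles, config = cluster_config()) {
  if (is.vector(profiles)) profiles <- matrix(profiles, nrow = 1L,
                                              dimnames = list("profile_1", NULL))
  n <- nrow(profiles)
  stopifnot(n >= 1L)
  ids <- rownames(profiles)
  if (is.null(ids) || !all(nzchar(ids))) {
    ids <- sprintf("profile_%d", seq_len(n))
    rownames(profiles) <- ids
  }
  if (anyDuplicated(ids))
    stop("profile row names (probe ids) must be unique", call. = FALSE)
  weeks <- as.numeric(colnames(profiles))
  if (any(is.na(weeks))) weeks <- seq_len(ncol(profiles))
  engine <- make_logml_engine(weeks, config)

  ## process in probe-id order so the tie rule is order-free
  ord <- order(ids)
  profiles <- profiles[ord, , drop = FALSE]
  ids <- ids[ord]

  size <- rep(1L, n)
  ssum <- t(profiles)                      # p(=T) x n matrix of colSums
  yty <- rowSums(profiles^2)
  logml <- vapply(seq_len(n), function(i) engine(1L, ssum[, i], yty[i]),
                  numeric(1))
  members <- as.list(seq_len(n))           # indices into ids
  minid <- ids                             # smallest member id per cluster
  alive <- rep(TRUE, n)

  pair_bf <- function(i, j) {
    engine(size[i] + size[j], ssum[, i] + ssum[, j], yty[i] + yty[j]) -
      logml[i] - logml[j]
  }

  ## symmetric BF matrix over alive clusters (NA on dead/diagonal)
  bf <- matrix(NA_real_, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L))
      for (j in (i + 1L):n)
        bf[i, j] <- pair_bf(i, j)
  }

  trace <- list()
  step <- 0L
  while (TRUE) {
    if (sum(alive) < 2L) break
    best <- max(bf, na.rm = TRUE)
    if (!(best > 0)) break
    cand <- which(bf >= best - 1e-12, arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      a <- pmin(minid[cand[, 1]], minid[cand[, 2]])
      b <- pmax(minid[cand[, 1]], minid[cand[, 2]])
      cand <- cand[order(a, b), , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    step <- step + 1L
    trace[[step]] <- data.frame(step = step,
                                cluster_a = minid[i], cluster_b = minid[j],
                                size_a = size[i], size_b = size[j],
                                log_bayes_factor = bf[i, j])
    ## merge j into i
    size[i] <- size[i] + size[j]
    ssum[, i] <- ssum[, i] + ssum[, j]
    yty[i] <- yty[i] + yty[j]
    logml[i] <- engine(size[i], ssum[, i], yty[i])
    members[[i]] <- c(members[[i]], members[[j]])
    minid[i] <- min(minid[i], minid[j])
    alive[j] <- FALSE
    bf[j, ] <- NA_real_; bf[, j] <- NA_real_
    for (k in which(alive)) {
      if (k == i) next
      v <- pair_bf(min(i, k), max(i, k))
      bf[min(i, k), max(i, k)] <- v
    }
  }

  live <- which(alive)
  ## stable cluster order: by smallest member probe id
  live <- live[order(minid[live])]
  clusters <- lapply(seq_along(live), function(ci) {
    i <- live[ci]
    list(members = ids[sort(members[[i]])],
         logml = logml[i],
         center = NULL, selected = NA, trend = NA_character_)
  })
  assignments <- data.frame(
    probe_id = unlist(lapply(clusters, `[[`, "members")),
    cluster = rep(seq_along(clusters),
                  vapply(clusters, function(cl) length(cl$members), 1L)),
    stringsAsFactors = FALSE)
  part <- structure(list(clusters = clusters,
                         assignments = assignments,
                         score = sum(logml[live]),
                         trace = if (length(trace))
                           do.call(rbind, trace) else
                             data.frame(step = integer(), cluster_a = character(),
                                        cluster_b = character(), size_a = integer(),
                                        size_b = integer(),
                                        log_bayes_factor = numeric()),
                         weeks = weeks,
                         profiles = profiles,
                         config = config),
                    class = "partition")
  cluster_centers(part)
}

#' Compute (or recompute) per-week cluster centers
#'
#' The center of a cluster is the per-week arithmetic mean of its member
#' log2-ratio trajectories; the operation is idempotent.
#'
#' @param partition a [agglomerate()] result.
#' @return The partition with each cluster's `center` filled in.
#' @export
cluster_centers <- function(partition) {
  stopifnot(inherits(partition, "partition"))
  partition$clusters <- lapply(partition$clusters, function(cl) {
    cl$center <- colMeans(partition$profiles[cl$members, , drop = FALSE])
    cl
  })
  partition
}

#' Flag clusters whose center exceeds the selection threshold
#'
#' A cluster is selected iff the maximum absolute center value over weeks
#' strictly exceeds `threshold` (default 1 in log2 units, i.e. a more than
#' 2-fold mean change at some week). Unselected clusters are retained but
#' flagged.
#'
#' @param partition a partition with centers computed.
#' @param threshold selection threshold in |log2| units.
#' @return The partition with `selected` flags set.
#' @export
select_clusters <- function(partition, threshold = 1) {
  stopifnot(inherits(partition, "partition"))
  partition$clusters <- lapply(partition$clusters, function(cl) {
    cl$selected <- max(abs(cl$center)) > threshold
    cl
  })
  partition
}

#' Classify a cluster center trajectory as increased, decreased or variable
#'
#' `"increased"` when every center value is above `-tolerance` and the
#' maximum exceeds `threshold`; `"decreased"` when every value is below
#' `tolerance` and the minimum is below `-threshold`; `"variable"` otherwise.
#' The tolerance absorbs small excursions across zero (default 0.25 log2
#' units).
#'
#' @param center numeric center trajectory (or a cluster list with `$center`).
#' @param threshold magnitude a monotone trend must reach (default 1).
#' @param tolerance allowed excursion on the wrong side of zero.
#' @return One of `"increased"`, `"decreased"`, `"variable"`.
#' @export
classify_trend <- function(center, threshold = 1, tolerance = 0.25) {
  if (is.list(center)) center <- center$center
  if (all(center >= -tolerance) && max(center) > threshold) "increased"
  else if (all(center <= tolerance) && min(center) < -threshold) "decreased"
  else "variable"
}

#' Fill trend classes for every cluster of a partition
#'
#' @inheritParams select_clusters
#' @param tolerance passed to [classify_trend()].
#' @return The partition with `trend` set on each cluster.
#' @export
classify_partition_trends <- function(partition, threshold = 1,
                                      tolerance = 0.25) {
  stopifnot(inherits(partition, "partition"))
  partition$clusters <- lapply(partition$clusters, function(cl) {
    cl$trend <- classify_trend(cl$center, threshold, tolerance)
    cl
  })
  partition
}

#' Cluster-level summary table of a partition
#'
#' @param partition a partition (centers computed).
#' @return Data frame with one row per cluster: id, size, per-week center
#'   values, marginal log-likelihood, selected flag and trend class.
#' @export
partition_summary <- function(partition) {
  stopifnot(inherits(partition, "partition"))
  wk <- partition$weeks
  rows <- lapply(seq_along(partition$clusters), function(i) {
    cl <- partition$clusters[[i]]
    ctr <- as.list(cl$center)
    names(ctr) <- paste0("center_wk", wk)
    cbind(data.frame(cluster = i, size = length(cl$members)),
          as.data.frame(ctr),
          data.frame(logml = cl$logml,
                     selected = cl$selected,
                     trend = cl$trend))
  })
  do.call(rbind, rows)
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d profiles in %d clusters (score %.3f)\n",
              nrow(x$profiles), length(x$clusters), x$score))
  invisible(x)
}

#' Probe ids belonging to the selected clusters of a partition
#'
#' @param partition a partition after [select_clusters()].
#' @return Character vector of member probe ids of all selected clusters.
#' @export
selected_probes <- function(partition) {
  stopifnot(inherits(partition, "partition"))
  unlist(lapply(partition$clusters,
                function(cl) if (isTRUE(cl$selected)) cl$members else NULL),
         use.names = FALSE)
}
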