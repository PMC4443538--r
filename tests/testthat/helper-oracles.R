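# Independent oracles used to verify closed-form / greedy computations.
# These deliberately avoid the code paths they check.

# Dense-grid trapezoid double integration of the order-0 model evidence over
# (beta, log sigma^2). Independent of the closed-form normal--inverse-gamma
# route: integrates the raw likelihood x prior on a grid.
grid_logml_order0 <- function(Y, tau = 1, a0 = 1, b0 = 0.1,
                              nb = 1501, ns = 1200) {
  y <- as.vector(Y)
  n <- length(y)
  sy <- sum(y)
  ssy <- sum(y^2)
  bgrid <- seq(min(y, 0) - 15, max(y, 0) + 15, length.out = nb)
  ugrid <- seq(-16, 8, length.out = ns)          # u = log sigma^2
  s2 <- exp(ugrid)
  # log integrand as nb x ns matrix (likelihood + coef prior + IG prior,
  # with the e^u Jacobian of the log-variance substitution)
  quad <- outer(-2 * bgrid * sy + n * bgrid^2, rep(1, ns)) + ssy
  lp <- -(n / 2) * log(2 * pi) -
    outer(rep(1, nb), (n / 2) * ugrid) -
    sweep(quad, 2, 2 * s2, "/") +
    outer(bgrid^2, -1 / (2 * tau^2 * s2), "*") -
    outer(rep(1, nb), 0.5 * (ugrid + log(2 * pi * tau^2))) +
    outer(rep(1, nb),
          a0 * log(b0) - lgamma(a0) - (a0 + 1) * ugrid - b0 / s2 + ugrid)
  M <- max(lp)
  log(sum(exp(lp - M)) * diff(bgrid[1:2]) * diff(ugrid[1:2])) + M
}

# Semi-analytic oracle for any polynomial order: the coefficients are
# marginalized through the Gaussian covariance I + tau^2 X X' and the noise
# variance is integrated numerically against its inverse-gamma prior.
mvn_logml <- function(Y, weeks, order = 3, tau = 1, a0 = 1, b0 = 0.1) {
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1L)
  X1 <- capclust::time_design(weeks, order)
  m <- nrow(Y)
  y <- as.vector(t(Y))
  n <- length(y)
  X <- X1[rep(seq_len(nrow(X1)), m), , drop = FALSE]
  K <- diag(n) + tau^2 * tcrossprod(X)
  ch <- chol(K)
  ld <- 2 * sum(log(diag(ch)))
  q <- sum(backsolve(ch, y, transpose = TRUE)^2)
  logf <- function(s2) -0.5 * (n * log(2 * pi * s2) + ld + q / s2) +
    a0 * log(b0) - lgamma(a0) - (a0 + 1) * log(s2) - b0 / s2
  M <- stats::optimize(logf, c(1e-8, 500), maximum = TRUE)$objective
  log(stats::integrate(Vectorize(function(s2) exp(logf(s2) - M)),
                       1e-8, 500, rel.tol = 1e-10,
                       subdivisions = 2000L)$value) + M
}

# All set partitions of 1..n as restricted-growth strings.
enumerate_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, k) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(k + 1L)) recurse(c(labels, lab), max(k, lab))
  }
  recurse(integer(), 0L)
  out
}

# Score of an arbitrary partition: sum of per-block marginal log-likelihoods.
partition_score <- function(Y, labels, config) {
  sum(vapply(split(seq_len(nrow(Y)), labels), function(idx)
    capclust::marginal_log_likelihood(Y[idx, , drop = FALSE], config),
    numeric(1)))
}

# Brute-force upper-tail hypergeometric probability: enumerate every
# possible query draw of size n from a background of size N containing K
# term genes, and count draws overlapping the term in >= k genes.
brute_hyper_tail <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  term <- seq_len(K)
  mean(apply(draws, 2L, function(d) sum(d %in% term) >= k))
}

# Kruskal-Wallis H from first principles (rank formula with tie correction).
manual_kw_H <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  num <- sum(tapply(r, groups, function(ri)
    length(ri) * (mean(ri) - (n + 1) / 2)^2))
  H <- 12 * num / (n * (n + 1))
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr == 0) 0 else H / corr
}

# Exact permutation p-value of H over all group-label splits.
perm_kw_p <- function(values, groups) {
  g <- factor(groups)
  idx1 <- which(g == levels(g)[1])
  splits <- utils::combn(length(values), length(idx1))
  h_obs <- manual_kw_H(values, g)
  h_all <- apply(splits, 2L, function(s) {
    gp <- rep(levels(g)[2], length(values))
    gp[s] <- levels(g)[1]
    manual_kw_H(values, gp)
  })
  mean(h_all >= h_obs - 1e-12)
}

# Adjusted Rand index between two labelings (chance-corrected agreement).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
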