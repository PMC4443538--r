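# Fixture builders shared across tests.

WEEKS <- c(1, 2, 4, 8, 16)
NB_WEEKS <- WEEKS[-1]

# Profile matrix with proper dimnames from row vectors.
profiles <- function(..., ids = NULL) {
  m <- rbind(...)
  if (is.null(ids)) ids <- sprintf("p%03d", seq_len(nrow(m)))
  dimnames(m) <- list(ids, NB_WEEKS)
  class(m) <- c("log2_ratio_profiles", "matrix", "array")
  m
}

# Minimal expression dataset straight from an intensity matrix; calls all "P"
# unless overridden.
toy_dataset <- function(intensity, calls = NULL, group = "immobilized",
                        weeks = WEEKS, reps = 1) {
  n_samp <- length(weeks) * reps
  stopifnot(ncol(intensity) == n_samp)
  if (is.null(rownames(intensity)))
    rownames(intensity) <- sprintf("p%03d", seq_len(nrow(intensity)))
  samples <- data.frame(
    sample_id = sprintf("%s_w%02d_r%d", group, rep(weeks, each = reps),
                        rep(seq_len(reps), length(weeks))),
    group = group, week = rep(weeks, each = reps),
    replicate = rep(seq_len(reps), length(weeks)),
    stringsAsFactors = FALSE)
  if (is.null(calls))
    calls <- matrix("P", nrow(intensity), n_samp)
  capclust::expression_dataset(intensity, calls, samples)
}

# Two well-separated planted trajectories + one flat bulk; used by the
# recovery tests. Separation between the two active centers is > 1 log2 unit
# at several weeks.
recovery_config <- function(seed, n_probes = 200, noise_sd = 0.1) {
  capclust::sim_config(
    n_probes = n_probes,
    cluster_spec = list(
      list(coef = c(1.6, 1.0, 0, 0), size = round(n_probes * 0.2)),
      list(coef = c(-1.8, -0.9, 0.3, 0), size = round(n_probes * 0.2)),
      list(coef = 0, size = n_probes - 2 * round(n_probes * 0.2))),
    replicate_noise_sd = noise_sd,
    absent_fraction = 0.1, low_floor_fraction = 0.1,
    seed = seed)
}

# Cell-mean table for the IHC generator.
ihc_effects <- function(sham, imm, weeks = c(2, 4, 8, 16)) {
  data.frame(group = rep(c("sham", "immobilized"), each = length(weeks)),
             week = rep(weeks, 2),
             mean = c(rep_len(sham, length(weeks)),
                      rep_len(imm, length(weeks))),
             stringsAsFactors = FALSE)
}
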