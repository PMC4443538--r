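# capclust

Time-course expression clustering and scoring for immobilization-induced
joint-contracture studies.

Rigid immobilization of a knee joint produces a flexion contracture — a
chronic loss of passive range of motion attributed largely to the posterior
capsule. One way to study the process is to profile the capsule
transcriptome over a 16-week immobilization time course (weeks 1, 2, 4, 8,
16; sham-operated and immobilized series; four replicate arrays per group
and week, MAS5-summarized with detection calls) and ask which genes change,
in which temporal pattern, and whether the pattern is specific to
immobilization rather than surgery. `capclust` implements that entire
analysis as a tested R package:

* **Preprocessing** — remove probes called absent in every sample, then
  probes whose per-week replicate median never reaches the expression floor
  (100, the MAS5 target value); collapse replicates to medians and form
  log2 ratios against week 1.
* **Fold-change binning** — signed fold changes (`r` or `-1/r`), binned
  per direction into `[1.5, 2)` and `[2, Inf)`, with distinct-probe
  direction totals and per-week attribution percentages.
* **Trajectory clustering** — a working re-implementation of the CAGED
  engine (Cluster Analysis of Gene Expression Dynamics): each log2-ratio
  trajectory is an order-3 polynomial regression on standardized time with
  a conjugate normal–inverse-gamma prior, so the marginal likelihood of any
  candidate cluster is a closed-form Student-t evidence

  `log ML(Y) = -n/2·log 2π + ½(log|Λ₀| − log|Λₙ|) + a₀·log b₀ − aₙ·log bₙ + log Γ(aₙ) − log Γ(a₀)`,

  and clusters are merged greedily while the log Bayes factor
  `log ML(A∪B) − log ML(A) − log ML(B)` is positive. The number of
  clusters is emergent. Centers, a strict |center| > 1 log2 selection
  rule, and increased/variable/decreased trend classes follow.
* **Group comparison** — selected probe sets of the two independent series
  are intersected; immobilization-only probes are collapsed to genes
  (gene-level set difference, so a gene with a common probe is never
  immobilization-only).
* **Enrichment** — local hypergeometric and EASE over-representation
  against GMT collections with BH q-values, and a term-by-cluster
  cross-tabulation with modal-cluster percentages.
* **IHC scoring** — two-examiner percent-positive field counts: per-field
  examiner means, removal of each rat's most discordant field, and
  per-week Kruskal–Wallis comparison (exact permutation option for small
  samples).
* **Synthetic data** — a generator planting trajectory clusters, detection
  calls, exact absent/below-floor fractions, and IHC group effects, so the
  full pipeline is testable against known truth (no raw arrays are
  publicly available for this design).

## Worked example

```r
library(capclust)

cfg <- sim_config(
  n_probes = 300,
  cluster_spec = list(
    list(coef = c(1.6, 1.0, 0, 0),  size = 60),    # increasing, > 2-fold
    list(coef = c(-1.8, -0.9, 0.3, 0), size = 60), # decreasing
    list(coef = 0, size = 180)),                   # unchanged bulk
  replicate_noise_sd = 0.15, absent_fraction = 0.15,
  low_floor_fraction = 0.2, seed = 42)
sim <- generate_expression_dataset(cfg, group = "immobilized")

pp <- preprocess_dataset(sim$dataset)
#> filter_absent: removed 45 of 300 probes (all-absent), 255 retained
#> filter_low_expression: removed 51 of 255 probes (< 100 at all weeks), 204 retained

ratios <- log2_ratio_profiles(median_by_timepoint(pp$dataset))
part <- classify_partition_trends(select_clusters(
  agglomerate(inclusion_filter(ratios), cluster_config())))
print(partition_summary(part), digits = 3)
#>   cluster size center_wk2 center_wk4 center_wk8 center_wk16 logml selected
#> 1       1   43      0.713       1.06        1.7        3.00  38.0     TRUE
#> 2       2   40     -0.780      -1.21       -1.9       -2.52  28.1     TRUE
#>       trend
#> 1 increased
#> 2 decreased
```

Reading the output: of 300 simulated probes, 45 were all-absent and 51 never
reached the floor, leaving 204; 83 profiles changed more than 2-fold at some
week and entered the clustering, which recovered the two planted
trajectories exactly (adjusted Rand index 1 against the planted labels) —
an increasing cluster reaching 3 log2 units (8-fold) by week 16 and a
decreasing one reaching −2.5, both selected by the |center| > 1 rule and
classified by trend. Members of the unchanged bulk that survived filtering
were excluded by the 2-fold inclusion filter, as designed.

## The analysis workflow

`analysis/01_simulate.R` … `06_ihc.R` run the full study narrative on a
4,000-probe synthetic chip — simulation, per-series preprocessing,
fold-change summaries, clustering, cross-group comparison with enrichment,
and IHC scoring — writing stage tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
# ... through
Rscript analysis/06_ihc.R
```

`run_pipeline()` performs the same orchestration programmatically from a
`pipeline_config()` of input paths, writing per-stage outputs and a JSON
manifest whose stage counts are asserted against the planted truth in the
test suite.

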