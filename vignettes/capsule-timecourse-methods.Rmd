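---
title: "Methods: time-course expression clustering for immobilization studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-course expression clustering for immobilization studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Prolonged immobilization of a joint produces a flexion contracture: a
chronic loss of passive range of motion attributed largely to the posterior
knee capsule. `capclust` implements an analysis workflow for the
transcriptional side of that process: bulk expression of the posterior
capsule measured on a single-channel microarray in two independent series
(sham-operated and immobilized), at weeks 1, 2, 4, 8 and 16, with four
replicate arrays per group and week. The workflow filters probes, bins fold
changes, clusters expression trajectories with a Bayesian model-based
agglomeration, compares the two series, tests gene-set over-representation
locally, and scores two-examiner immunohistochemistry counts. Because no raw
arrays are publicly available for this design, the package carries a
first-class synthetic-data module so every stage is testable end to end
against planted truth.

## Preprocessing

Inputs are MAS5-style: positive intensities scaled to a target value of 100,
with per-value Present/Marginal/Absent detection calls. Two filters apply,
per series:

1. **Absent filter.** A probe is removed iff its call is "A" in *every*
   sample of the series. A single "P" or "M" anywhere retains it.
2. **Expression floor.** After collapsing replicates to per-week medians, a
   probe is removed iff its median is below the floor (default 100) at
   *every* week; one week at or above the floor retains it.

The floor rule deserves a note: the source design's bookkeeping only
balances if whole probes, not individual values, are removed, so the
all-weeks per-probe reading is implemented. Replicate medians use the
standard convention (midpoint of central order statistics for even counts);
the design nominally has four arrays per cell and the code accepts any
replicate count.

Trajectories are log2 ratios of each week's median against the week-1
median. Week 1 is identically zero and is excluded from the trajectory
vectors by default (an `include_baseline` flag appends it for plotting);
including a zero-variance point would distort the clustering likelihood.

## Fold-change binning

Signed fold change is `r` for `r >= 1` and `-1/r` otherwise, so magnitude
thresholds act symmetrically. Bins are half-open on the magnitude:
`[1.5, 2)` and `[2, Inf)` per direction, `none` below 1.5. The boundary
value 2.0 is assigned to the upper bin; the source phrasing ("1.5 to 2.0 and
2.0 more than") leaves the edge ambiguous and this choice keeps the upper
bin non-empty at its own boundary. Direction summaries count a probe once
per direction regardless of how many weeks it crosses the threshold; a probe
crossing both ways is counted in both totals and flagged, and attribution
percentages (share of a direction's probes with the event at named weeks)
are rounded to one decimal. Attribution over a partition of the weeks need
not sum to 100%.

## The clustering model

The engine re-implements the CAGED idea — Bayesian model-based clustering of
expression dynamics — with the polynomial model variant. Each trajectory
\(y\) over the non-baseline weeks is modelled as

\[ y = X\beta + \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2 I), \]

where \(X\) is the Vandermonde design \(1, x, x^2, x^3\) (order 3 by
default) on weeks centred and scaled to unit variance — standardization
keeps the design well conditioned out to week 16. The prior is the conjugate
normal--inverse-gamma family

\[ \beta \mid \sigma^2 \sim N(m_0, \sigma^2 \tau^2 I), \qquad
   \sigma^2 \sim \mathrm{InvGamma}(a_0, b_0), \]

with defaults \(m_0 = 0\), \(\tau = 1\), \(a_0 = 1\), \(b_0 = 0.1\) — a weak
prior whose scale matches log2-ratio noise. The marginal likelihood of any
set of trajectories (stacked into one regression) is then available in
closed form as a multivariate Student-t evaluation; no sampling is used, and
the value is invariant to stacking order. With order 3 on four time points
the per-series design is saturated: the proper prior keeps every evidence
finite, and merge decisions are driven entirely by agreement *across*
series, which is exactly what a trajectory-clustering engine should measure.

Agglomeration is greedy: start from singletons; at each step evaluate, for
every cluster pair, the log Bayes factor
\(\log \mathrm{ML}(A \cup B) - \log \mathrm{ML}(A) - \log \mathrm{ML}(B)\);
merge the best pair if its log Bayes factor is strictly positive, else stop.
The number of clusters is therefore emergent. All pairs are evaluated at
every step (quadratic, exact, no pruning heuristics — acceptable at the
filtered-set scale of a few hundred to a few thousand profiles, where a
3,000-profile run is minutes of work). Ties on the log Bayes factor (within
1e-12) are broken toward the pair whose smallest member probe id sorts
first, then the partner's smallest id, making results deterministic and
invariant to input row order up to cluster relabelling. Sufficient
statistics (member count, trajectory sum, sum of squares) make each
evidence evaluation O(1) beyond a cached 4x4 Cholesky per cluster size.

Only profiles exceeding 2-fold (strictly above 1.0 in |log2|) at one or more
weeks enter the clustering. Cluster centers are per-week means of member
trajectories; clusters are *selected* when some |center| strictly exceeds 1
log2 unit; selected clusters are classed as increased / decreased /
variable, where a monotone class requires every center value on the right
side of zero up to a tolerance of 0.25 log2 units (the source does not state
its rule; the tolerance is this package's declared convention, absorbing
small early excursions without reclassifying clearly monotone
trajectories). Two open modelling questions are resolved as follows: the
engine clusters log2 *ratios* (week-1-referenced), which is what the
trajectory figures in this literature show, and the prior hyperparameters
are this package's defaults, not a claim about any historical CAGED run.

## Cross-group comparison and enrichment

Sham and immobilized series never mix before this point. The probe sets of
the selected clusters are intersected: the intersection is the shared
response (surgery, time, handling), and immobilized-only probes form the
immobilization-associated set. Probes collapse to genes via a two-column
map; the strict dialect requires one gene per probe (a permissive flag keeps
the first listed). Gene-level immobilization-only membership is computed as
the set difference of the *collapsed* gene sets, not the collapse of the
probe difference — a gene with one common and one immobilized-only probe is
not immobilization-only. This is the only reading under which probe and gene
counts can both balance.

Over-representation uses the one-sided upper-tail hypergeometric p-value
with term genes intersected with the background first; the EASE variant
discounts the overlap by one gene before the tail sum and is conservative by
construction. The default background is all genes surviving preprocessing on
the array. Benjamini--Hochberg q-values are reported, but raw p remains the
primary column, matching how such tables are usually printed. Web-service
enrichment (DAVID, KEGG, Reactome) is deliberately replaced by local GMT
collections: the historical term databases are not versioned or
reproducible, so correctness lives in the statistic, which is tested against
brute-force enumeration. The cross-tabulation assigns a gene to a cluster if
any of its probes is a member, counts a gene once per cluster, and reports
the modal cluster with its whole-percent share of the term overlap.

## IHC field scoring

Percent-positive counts come as 4 microscope fields per rat, each counted by
two independent examiners. Per field the examiner mean and absolute
difference are computed; per rat the single most discordant field is removed
(ties remove the lowest field index), leaving three fields. Weeks are
analysed separately with the Kruskal--Wallis test on the pooled retained
fields (tie-corrected H, chi-square reference with one degree of freedom for
two groups). Kruskal--Wallis is kept for two groups rather than swapping in
a rank-sum test, mirroring the workflow this package re-implements. Pooling
fields within groups treats fields as the unit of analysis and
pseudo-replicates rats; this matches the stated design ("remaining three
fields per rat") but should be read accordingly. When every value ties, the
tie-correction denominator vanishes; H is defined as 0 with p = 1. An exact
permutation p-value over all group splits is available for small samples and
refuses enumeration beyond `max_exact_splits` (default 1e5) rather than
stalling.

## The synthetic-data generator

The generator emulates the study conditions: 2 groups x 5 weeks x 4
replicate arrays, a ~31k-probe chip when run at chip scale, log-normal
baseline intensities (log2 mean 9, sd 1.5) rescaled so the 2%-trimmed mean
of all intensities sits at the MAS5 target of 100, planted polynomial
trajectory clusters in log2-ratio space on the same standardized time axis
the clustering uses, i.i.d. replicate noise on the log2 scale, an exact
rounded fraction of probes called absent in every sample, and an exact
rounded fraction of the remainder held below the expression floor at every
week. Detection calls are "P" with a 2% "M" rate among present probes, so
parsers meet all three symbols while the filters treat only "A" specially.
Three constructive details matter:

* Absent probes keep positive intensities — absence is a call, not a zero.
* Below-floor probes carry P/M calls so they survive the absent filter and
  genuinely exercise the floor filter.
* Planted (active) probes whose simulated medians all land below the floor
  are rescaled multiplicatively to put one week at the floor; the rescaling
  cancels in log2 ratios, so planted trajectories are untouched.

Cluster sizes must sum to `n_probes`; the absent and below-floor statuses
are sampled on top and recorded in the truth table, so the planted filter
counts are exact by construction. The IHC generator draws a true field
value per field (cell mean + between-field noise, default sd 5) observed by
both examiners with independent error; `examiner_sd = 0` makes the two
examiners byte-identical, and all values are clipped to [0, 100].

What the generator does *not* emulate: probe-level CEL structure, spatial
artifacts, MAS5's actual call algorithm, probe-gene annotation noise,
correlated replicate effects, or heavy-tailed array noise. The source design
does not state its arrays' noise model; the defaults here (replicate noise
sd 0.15--0.25 log2) are realistic for property testing, not estimates of
the real data. Passing recovery tests therefore demonstrates correctness of
the machinery under the planted model, not performance on real arrays.

## Numerical choices

* All threshold comparisons that the workflow states as strict are strict:
  the 2-fold inclusion filter (`> 1.0` in |log2|) and the |center| `> 1`
  selection both exclude exact boundary values.
* Evidence computations go through Cholesky factors; prior covariance is
  full-rank, so no finite input can produce a singular system.
* Greedy merging stops at the first step with no strictly positive log
  Bayes factor; scores along the merge trace are non-decreasing by
  construction and asserted in tests.
* The permutation p-value counts splits with `H >= H_obs - 1e-12`,
  including the observed labeling.
* Degenerate inputs are defined, not crashed: empty fold-change tables
  report not-applicable attributions; all-tied Kruskal--Wallis returns
  H = 0, p = 1; a rat with two fields retains one.

## Problem sizes

The bundled analysis workflow simulates a 4,000-probe chip (18% all-absent,
34% of the remainder below floor, ~800 active probes), which runs the full
pipeline in a few minutes; the test suite verifies chip-scale filter
bookkeeping at 31,099 probes, clustering recovery on 200-probe instances
over 10 seeds (adjusted Rand index against planted labels), greedy-vs-
exhaustive agreement on 8-profile instances (all 4,140 set partitions
scored), evidence against dense-grid and Gaussian-marginalized quadrature
oracles, enrichment against complete draw enumeration at N = 20, and
Kruskal--Wallis size (500 null simulations) and power (500 alternative
simulations). These sizes are the package's own choices for a desk-scale,
fully reproducible validation.

## Known limitations

* The greedy agglomeration is a local search; it is exact on well-separated
  fixtures (verified exhaustively at n = 8) but carries no global optimality
  guarantee in general.
* Real chips map some probes to several genes; the strict one-gene dialect
  pushes that resolution upstream.
* Field-level pooling in the IHC test inflates effective sample size when
  rats differ systematically; a rat-mean analysis would be the conservative
  alternative.
* The autoregressive trajectory model found in other model-based clustering
  engines is intentionally out of scope; only the polynomial model is
  implemented.
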