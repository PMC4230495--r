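---
title: "Non-specific filtering of Beta-distributed methylation data: methods and design"
author: "methylGOF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-specific filtering of Beta-distributed methylation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylGOF)
```

## The problem

Cluster analysis of DNA methylation arrays starts by discarding most probes:
of the tens or hundreds of thousands of CpGs measured, only a fraction vary
for biological reasons, and unsupervised methods work best on that fraction.
A *non-specific* filter ranks features by a label-blind statistic and keeps
the top of the list.

Methylation is measured as a proportion (the Illumina "beta value",
methylated signal over total signal), bounded in (0, 1) and well described
per CpG by a Beta distribution across samples.  For `X ~ Beta(alpha, beta)`
the mean is `mu = alpha / (alpha + beta)` and the variance
`mu (1 - mu) / (phi + 1)` with precision `phi = alpha + beta` — the variance
is a function of the mean, maximal near `mu = 0.5`.  Ranking by plain
standard deviation (SD-b) therefore biases selection toward mid-range CpGs.
That bias is harmless, even helpful, when the clusters of interest differ at
cell-type-specific CpGs; it is a liability when the interesting subgroup is a
*minority* of samples that coordinately hypermethylates normally unmethylated
CpG islands (the CpG island methylator phenotype, CIMP): those features have
means near 0, small absolute variance, and sink in an SD ranking.

## Goodness-of-fit filters on the variance-stabilized scale

The cumulative distribution function is the exact variance-stabilizing
transform for Beta data: if `X ~ Beta(alpha, beta)` then `Y = I_X(alpha, beta)`
(the regularized incomplete beta function) is Uniform(0, 1), with mean 1/2 and
variance 1/12, *whatever* the mean of `X`.  A feature whose samples come from
a single Beta lands on that target after transforming with its own fitted
parameters; a feature containing a mixture (two sample subgroups with
different methylation) does not.  Departure from the target is therefore a
mean-unbiased measure of "interesting variation".

Per feature, the package fits `(alpha, beta)` by the method of moments
(`fitBetaMoM()`),

    alpha = x_bar (x_bar (1 - x_bar) / s^2 - 1),
    beta  = (1 - x_bar) (x_bar (1 - x_bar) / s^2 - 1),

with the 1/N variance convention throughout (rankings are unchanged by the
N/(N-1) factor; we keep one divisor everywhere for internal consistency:
SD-b, SD-m, the transformed-moment SDs, and the cross-feature scales).  Three
goodness-of-fit statistics are built on the fit:

* **TM-GOF** (`tmGof()`): transform the feature, record `(y_bar, s_y)`, and
  score the standardized Euclidean distance from `(1/2, sqrt(1/12))`, with
  the standardization SDs `s_ybar` and `s_sy` estimated *across features*.
* **TQ-GOF** (`tqGof()`): compare the empirical quantiles of the transformed
  feature against the Uniform quantiles on an interior grid, summing absolute
  differences.
* **BQ-GOF** (`bqGof()`): stay on the raw scale and sum, over the same grid,
  the absolute differences between the empirical CDF evaluated at the fitted
  Beta's quantiles and the grid probabilities.

The comparison set consists of the classical filters: SD on beta values
(SD-b), SD on M-values (`log2(x / (1 - x))`, SD-m), median absolute deviation
(MAD), the Hartigan dip statistic (DIP), and the inverse precision
`1 / (alpha + beta)` from the same moment fit.  Three rank combiners (best
rank BR, average of best two AR, weighted average of best four WAR with
weights 4:3:2:1) summarize the eight single filters, and `hybridSelect()`
pools the top-500 lists of two filters (SD-b with TM-GOF being the intended
pairing, as the two prioritize largely disjoint feature sets).

### Numerical choices

* **Quantile grid.**  "25 quantile points" are placed at `p_k = k/26`,
  `k = 1..25`: interior and symmetric, avoiding the endpoint quantiles where
  fitted Betas degenerate.  The grid size is a parameter (`nQuantiles`).
* **Empirical CDF / quantiles.**  The ECDF is right-continuous,
  `F(x) = #{x_i <= x} / n`; empirical quantiles use the inverse-ECDF (type 1)
  convention, `Q(p) = x_(ceiling(p n))`.
* **Boundary handling.**  Proportions are clipped to `[1e-6, 1 - 1e-6]`
  (`clipBoundary()`) before any logit or likelihood computation.
* **Unfittable features.**  With the 1/N variance, data strictly inside
  (0, 1) always satisfy `s^2 < x_bar (1 - x_bar)`, so the moment fit exists
  except for constant (zero-variance) features.  Filters that need the fit
  (Precision, BQ-GOF, TM-GOF, TQ-GOF) give such features the largest observed
  score plus one and flag them — a feature no single Beta can describe is
  maximal evidence of mixture — and exclude them from the cross-feature scale
  estimation in TM-GOF.
* **Orientation and ties.**  Every statistic is stored "larger = more
  interesting"; rank values give the largest statistic rank P with ties
  averaged, so `mean(rank) = (P + 1)/2` always.  Top-k selection breaks ties
  by lexicographic feature ID for reproducibility.

### The dip statistic

No dip implementation is available among this package's dependencies, so
`hartiganDip()` implements the classical modal-interval algorithm directly:
the greatest convex minorant and least concave majorant of the ECDF are
compared over a shrinking candidate modal interval, and the ECDF's deviations
from the hulls outside that interval accumulate into the statistic.  The
implementation was verified against an independent linear-programming oracle
that minimizes, over all piecewise-linear unimodal CDFs and all mode
placements (including the junction-slope condition across a mode inside a
gap), the sup-distance to the ECDF; the test suite retains a scaled-down LP
cross-check plus exact fixed points (`dip = 1/4` for an equal two-point
mixture, `1/6` for three equidistant points, the `1/(2n)` floor).  Constant
features return the floor `1/(2n)` so the DIP ranking stays well defined.

## The simulator

`simulateDataset()` generates two-group feature-by-sample matrices with
2000 features, 200 samples, and a random 10% informative subset by default;
group sizes follow a ratio (1:9, 1:1, 9:1) with group 1 the CIMP-like group.
Each feature-and-group draws iid from `Beta(mu * phi, (1 - mu) * phi)`.
Replicates keep the 1800 null parameter sets fixed and re-draw the
informative positions and parameter pairs, reproducing the replicate protocol
of a simulation study; all randomness flows from `seed + replicate`.

`buildParameterLibrary()` stands in for parameter estimates from a real
CIMP / non-CIMP cancer cohort:

| knob | default | rationale |
|---|---|---|
| null means | 40% in (0.02, 0.15), 35% in (0.85, 0.98), 25% in (0.2, 0.8) | methylation-like bimodality with a substantial mid-range fraction, so that SD-style filters have genuinely variable null features to pick |
| null precision `phi` | log-uniform in (5, 200) | spans noisy to tight probes |
| informative `mu_2` (majority group) | uniform in (0.02, 0.15) | normally unmethylated CpG-island-like loci, the substrate of CIMP hypermethylation |
| informative `phi_2` | log-uniform in (30, 300) | unmethylated island probes are tight on Infinium arrays |
| shift `delta` | Exponential(mean 0.8), truncated at 4 | `mu_1 = plogis(qlogis(mu_2) + delta)`: most informative loci shift modestly on the logit scale, a minority strongly; the effect size `theta` (log odds ratio of the group means) equals `-delta` |
| `phi_1 / phi_2` | uniform in (0.1, 1) | the hypermethylated minority has higher variance, further inflated in practice by estimating per-group parameters from few samples |

An effect-size cap (`thetaCap`, applied to `|theta|` since the sign merely
encodes group order) restricts the informative candidates to weak shifts,
which is what separates the filters: uncapped data sets contain a few
enormous effects that let *any* filter's top list carry the clustering.

**What the generator does and does not emulate.**  It reproduces the
qualitative structure relevant to filter comparison — low-mean informative
features invisible to SD ranking, minority-group variance inflation,
mid-range noisy nulls that SD ranks first — under exact per-group Beta
sampling.  It does not emulate array noise, probe-design effects, batch
effects, or cell-type mixtures within a group, and no parametric stand-in
reproduces every marginal of a real cohort's empirical parameter pool.  One
measurable consequence: the SD-class filters' enrichment AUC here hovers
near, but not exactly at, one half, and drifts with the group ratio (below
0.5 at 1:9, slightly above at 1:1), because the exact cancellation between
"informative features have low base SD" and "the minority adds variance"
holds only at particular ratios.  Passing tests therefore demonstrate the
filters' behaviour under this generative structure, not a quantitative
reproduction of any particular cohort.

## Recursive Beta-mixture clustering

To score filters by cluster recovery, `recursivePartition()` splits samples
recursively under a two-component mixture of products of independent Betas
(`fitBetaMixture()`): the E-step computes per-sample responsibilities from
summed per-feature Beta log-densities; the M-step re-estimates per-feature
`(alpha, beta)` by responsibility-weighted method of moments and the mixing
weight by mean responsibility.  This moment-based M-step is not the exact
likelihood maximizer, so the observed log-likelihood is monitored and the
iteration stops (keeping the previous state) if an update ever fails to
improve it; the reported trajectory is nondecreasing by construction.
Moment updates are clamped: means to `[1e-6, 1 - 1e-6]`, precisions to at
most `1e6`.

A split is accepted iff the two-component BIC beats the one-Beta-per-feature
BIC — parameter counts `2 x 2P + 1` versus `2P` — and both children hold at
least `minNode` samples (default 5).  On structure-free data the penalty
rejects the root split and one big cluster is returned, which makes the
"single-cluster" error ceiling (`min(n1, n2)/n`) the natural score for a
filter whose top list carries no signal.  This is deliberately a simplified
recursive partitioning, not a re-implementation of any published mixture
clustering package: hard binary recursion with plain BIC is all the scoring
harness requires.

**Initialization** uses two deterministic starts — Lloyd 2-means on the
per-sample mean methylation and on the per-sample SD, each seeded at the
min/max observations — keeping the best final likelihood.  A random restart
would attach RNG draws to column order and break the package's invariant
that permuting samples permutes labels identically; users wanting extra
random starts can request them (`nRandomStarts`), which is the only use of
the `seed` argument.

## Evaluation

`rocPoints()` scores a ranking against the informative truth over all list
lengths, with trapezoid AUC; `averageRoc()` averages replicate curves
pointwise; `aucCI()` is a normal-approximation interval over replicate AUCs.
`sensSpecAtK()` reports the fixed-list operating point: with 200 informative
of 2000 features and a top-100 list, the best possible true-positive fraction
is 0.5 and the worst false-positive fraction 100/1800 = 0.056, the diagonal
that frames fixed-list comparisons.  `misclassificationRate()` compares the
top two clusters against a two-group truth under the best label assignment
(never exceeding 1/2), and `adjustedRand()` is the Hubert–Arabie
pair-counting index (returning 1 in the degenerate case where both
partitions are trivial and hence identical).

The study harnesses (`enrichmentStudy()`, `clusterRecoveryStudy()`) run the
replicate protocol end to end.  The package's own acceptance checks use
50 replicates of the default 2000 x 200 design per group ratio — enough for
replicate standard errors of the mean AUC around 0.005 — and top-100/200/400
lists for the clustering stage; smaller configurations in the unit tests
(hundreds of features, tens of samples) exercise the same code paths where
exact values, not power, are at stake.

## Known limitations

* The moment fit is used everywhere (per the filters' definitions); maximum
  likelihood would differ slightly for heavily skewed features.
* The outlier pre-filter (`outlierFeatureMask()`, median +/- 3 IQR) removes
  exactly the coordinate-outlier features that mark a rare hypermethylated
  subtype; it is intended for tissue-level structure hunting, and the
  package keeps it out of the default pipeline.
* Misclassification scoring is defined for two-group truths only.
* The Beta mixture treats features as independent within a component;
  correlated CpGs (islands, domains) effectively overweight their region in
  the split decision.
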