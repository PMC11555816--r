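---
title: "Dynamic network entropy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic network entropy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynent)
```

# The problem

Short, non-stationary expression time courses — a yeast cell-cycle
synchronisation experiment is the canonical example — pose two linked
problems: the regulatory structure among a handful of genes changes as the
cells move through phases, and any single structure-learning run on the full
series mixes those regimes together. `dynent` addresses this by (i) cutting
the series into stationary *plateau intervals*, (ii) learning one directed
network per interval with the K2 (Cooper–Herskovits) score, (iii) screening
the union of those networks with a correlation-based *network entropy*, and
(iv) ranking the genes of the screened network by the entropy drop their
deletion causes. A partial-least-squares simulation compares competing
networks by prediction error.

# Plateau segmentation

The diagnostic statistic for a gene $G$ on an interval $[s,t]$ is the ratio
of the interval mean absolute deviation to the whole-series one,

$$RB(s,t) = \frac{\tfrac1n\sum_{i \in [s,t]} |G(i) - \mu_G(s,t)|}
                 {\tfrac1N\sum_{i \in [1,T]} |G(i) - \mu_G(1,T)|},$$

small values flagging a plateau (`rbStatistic()`, `rbProfile()`). The
operational merge decision, however, is a two-sample distribution-equality
test between adjacent intervals at level `alpha` (default 0.01):
consecutive base windows (default 20 min) are merged left-to-right to a
fixpoint whenever the test does not reject (`segmentSeries()`).

Two design points deserve a note:

* **Pooling across genes.** The stationarity requirement applies to all
  genes jointly, and at a 10-minute sampling interval a 20-minute window
  holds only two observations per gene — far below what any two-sample test
  needs to reject at $\alpha = 0.01$ (the smallest attainable
  Kolmogorov–Smirnov p-value for 2 vs 2 is 1/3). The default therefore
  pools the values of all genes within each interval, giving 16-vs-16
  comparisons on an 8-gene series, which holds the nominal level under the
  null and detects a strong mean shift essentially always. A per-gene AND
  rule (`pooling = "per-gene"`) and a Mann–Whitney variant
  (`test = "wilcox"`) are available; the per-gene rule is only useful when
  windows contain many observations. Pooling assumes the genes are on a
  common scale, which the z-score normalisation guarantees.
* **Raw values, not RB values.** The merge test compares the
  (post-imputation, normalised) expression values themselves. Testing the
  per-gene RB values of adjacent windows instead would be blind to mean
  shifts, since RB measures only within-window dispersion; RB is therefore
  reported as a diagnostic, not used for the decision.

# Preprocessing

* **Missingness filter**: genes whose missing fraction exceeds
  `maxRate` (default 0.15) are dropped (`filterByMissingRate()`).
* **Imputation** (`imputeMissing()`): interior gaps are filled by
  piecewise-cubic spline interpolation over time. FMM end conditions are
  used rather than natural ones because they reproduce data lying exactly
  on a cubic polynomial, which is the behaviour one wants from a
  "cubic" imputation; genes with fewer than four observed points fall back
  to linear interpolation, and masked endpoints take the nearest observed
  value (endpoints cannot be interpolated).
* **Normalisation** (`normalizeSeries()`): per-gene z-score by default
  (min–max available). The segmentation pooling and the discretisation
  thresholds both benefit from a common scale.
* **Discretisation** (`discretizeSeries()`): three states from the per-gene
  mean $\mu$ and sample standard deviation $s$. The published rule assigns
  state 2 only at exact equality with $\mu + s$, an event of probability
  zero on continuous data, which collapses the code to two states; the
  default `"symmetric"` rule uses $\mu \pm s$ so that state 2 covers the
  central band (roughly 68% of a Gaussian gene), and the `"literal"` mode
  preserves the asymmetric rule for fidelity. The quantity added to the
  mean is treated as a standard deviation, not a variance: only then are
  the units commensurable.

# Per-interval K2 learning

For gene $i$ with parent set $\pi_i$ over $r$ states, the score is the
Cooper–Herskovits marginal likelihood

$$score(i, \pi_i) = \prod_{j=1}^{q_i} \frac{(r-1)!}{(N_{ij}+r-1)!}
  \prod_{k=1}^{r} N_{ijk}!$$

with $N_{ijk}$ the number of interval observations in which gene $i$ shows
state $k$ while its parents show configuration $j$, and $q_i$ counting only
configurations actually observed (unobserved ones contribute empty
products). All arithmetic is done in log space with `lfactorial()`; raw
factorials overflow at modest sample sizes. `k2Search()` runs the greedy
parent search per gene along a fixed ordering, stopping when no candidate
increases the score or `maxParents` (default 3) is reached, with ties
broken by the lowest original gene index so runs are deterministic. Parents
are restricted to ordering predecessors, so each interval network is a DAG
by construction; the union across intervals (`unionNetwork()`) may contain
cycles, and edges found in the supplied prior edge list are marked
`confirmed` while the rest stay `unconfirmed`.

K2 requires a node ordering that the method itself cannot supply. The
case-study convention (cyclins and kinases upstream, transcription factors
and inhibitors downstream: CLN1, CLN2, CDC28, SWE1, CDC5, CDH1, SWI5,
SIC1) is a configuration input, not a default baked into the code. The
number of states defaults to $r = 3$, matching the three-level
discretisation.

# Network entropy and the edge screen

For node $i$ with neighbours $nb(i)$ (in- and out-edges viewed
undirected),

$$H_i = -\sum_{j \in nb(i)} p_{ij}\log p_{ij},\qquad
  p_{ij} = \frac{|corr(k_i,k_j)|}{\sum_{m \in nb(i)} |corr(k_i,k_m)|},$$

where the correlation is Pearson when both series pass a Shapiro–Wilk
normality check at level 0.05 and Spearman otherwise
(`corrWithNormalitySwitch()`). Logs are natural by default (configurable).
Isolated nodes score 0, and the *network entropy* is the sum over nodes —
the simplest aggregate that makes edge-addition and node-deletion deltas
well defined. Entropy is computed once on the whole post-imputation series,
not per interval.

`screenEdges()` tests every unconfirmed edge against *contexts*: subsets of
the other unconfirmed edges in its group, added to the confirmed
subnetwork. A violation is a context in which adding the edge raises total
entropy by more than `a` (case-study value 0.3); the edge is admitted when
its violation count stays below `b` (100 and 200 for the two case-study
groups). As printed, the published pseudocode resets its counter instead of
incrementing it and compares the removal direction, so every edge would
always be admitted; the corrected counting semantics implemented here is
the only reading under which `a`, `b` and the group-specific `b` values do
anything, and the verbatim behaviour is kept behind `mode = "literal"`.
Context enumeration is lexicographic and capped by `maxContext`; groups of
more than 20 unconfirmed edges are refused without a cap (the context count
is exponential in the group size). How unconfirmed edges are partitioned
into groups is a free configuration input, as is the meaning of the two
thresholds relative to the total context count.

# Sensitivity ranking

`sensitivityScores()` deletes each node (with its incident edges) in turn,
recomputes all surviving entropies from scratch — the surviving nodes'
$p_{ij}$ renormalise over their reduced neighbourhoods — and reports
$g_i = c - d_i$, the drop from the intact total $c$. Larger drops mark more
vital nodes. Ties rank by original gene order. On a star with equal
correlations the hub scores $\ln k$ and each leaf $\ln k - \ln(k-1)$, which
is the package's closed-form test case.

# PLS validation

`fitPLS()` models each gene with parents as a linear combination of its
parents' series, $x_i(t) = \beta_0 + \sum_{j \in pa(i)} \beta_j x_j(t)$, by
partial least squares with `min(nComponents, |pa(i)|)` components (default
2); non-parents have exactly zero coefficients, and parentless genes use
their training mean. With a single parent, one-component PLS is
mathematically identical to simple least squares and is computed in closed
form. `simulateError()` draws expression from the fitted normal marginals
and reports the mean relative error $|pred - drawn|/(|drawn| + \epsilon)$
with $\epsilon = 10^{-8}$ (z-scored data makes near-zero denominators
common), averaged over genes with parents.

One caveat matters when *comparing* networks: with independent per-gene
draws (the default, and the simplest reading of "generate data from the
normal distribution"), a parent draw carries no information about its
child's draw, so a richer network can only add prediction variance and the
true network cannot win. Network comparisons should therefore use
`joint = "mvnorm"` (multivariate normal draws with the empirical
covariance), which preserves the dependence the models exploit, or
`predictionError()` on the observed series. The package's own validation
uses the joint mode.

# The synthetic generator

`generateSynthetic()` emulates the case-study data shape: 8 genes, 17
timepoints at 10-minute spacing by default, piecewise-stationary segments
each carrying a linear-Gaussian DAG (parentless genes
$N(\text{segment mean}, 1)$, children a weighted parent sum plus
$N(0, 0.1^2)$ noise, default weight 0.9), segment changes shifting the
baseline means by 2 units, and a configurable uniformly-random missing
rate. Generation is contemporaneous (matching the PLS model), not a
dynamical system, which keeps the planted truth identifiable by the
pipeline's own assumptions. It does **not** emulate microarray noise
(dye bias, probe effects, heteroscedasticity), autocorrelated dynamics, or
feedback loops, so green tests certify the algorithmic chain, not
performance on real chips. Because 17 points cannot support reliable K2
recovery, the recovery benchmarks use a dense profile (two segments of 200
points, three planted edges each, window 50); the validation suite runs 20
seeds of that profile and 50-seed level/power sweeps for the segmentation,
sizes chosen to keep the whole suite under a minute of simulation while
leaving the Monte-Carlo rates far from their thresholds.

# Degenerate inputs and numerical choices

* Constant genes abort normalisation, correlation and the normality screen
  with the offending gene named; a constant whole series makes RB
  undefined and is an error.
* Empty parent sets, empty intervals and zero observations use the
  empty-product convention (`k2Score` = 0 in log space).
* Zero correlations drop out of the entropy sum ($p\log p \to 0$); a node
  whose neighbour correlations are all zero scores 0.
* All stochastic steps (`generateSynthetic()`, `simulateError()`) take
  explicit seeds and restore the caller's RNG state, so pipelines are
  bit-reproducible given a configuration.

# Limitations

* The K2 ordering is an assumption, not an inference; a wrong ordering
  reverses or hides edges. An ensemble over random orderings is left to
  the caller (run `k2Search()` over permutations and union the results).
* The screen's thresholds `a` and `b` and the edge grouping are free
  parameters with no internal calibration; too-strict values delete true
  edges, too-lax ones keep everything.
* The entropy is built from marginal pairwise correlations and ignores
  edge direction; regulation that manifests only conditionally will be
  invisible to it.
* The bundled `synthetic_cdc28_like.tsv` is a simulated stand-in with the
  case study's gene names and shape, for exercising the published
  parameter set offline; results on it say nothing about the real
  microarray course.
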