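# dynent

Dynamic network entropy for time-resolved gene regulatory networks.

`dynent` is for researchers who have a short multivariate expression time
course — typically a synchronised cell-cycle experiment with a handful of
regulators sampled every few minutes — and want to know (a) how the
regulatory structure changes over the course, and (b) which gene is the
most *vital* node of the resulting network. The case study the package is
built around is the 8-regulator yeast cell-cycle module (CLN1, CLN2, CDC28,
SWE1, CDC5, CDH1, SWI5, SIC1) over a 0–160 min course.

## Method

The pipeline chains five stages, each an exported function:

1. **Preprocess** — filter genes by missing rate (≤ 15% by default), impute
   gaps by cubic spline, z-score per gene, discretise into three states by
   the per-gene mean ± standard deviation
   (`filterByMissingRate`, `imputeMissing`, `normalizeSeries`,
   `discretizeSeries`).
2. **Segment** — cut the course into stationary *plateau intervals*: base
   windows are merged whenever a two-sample Kolmogorov–Smirnov test on the
   pooled gene values does not reject at α = 0.01. The plateau ratio
   RB(s,t) = (interval mean absolute deviation) / (whole-series mean
   absolute deviation) is reported per gene and interval
   (`segmentSeries`, `rbStatistic`, `rbProfile`).
3. **Learn** — per interval, greedy K2 structure search over a fixed gene
   ordering with the Cooper–Herskovits score

   score(i, π_i) = ∏_j (r−1)!/(N_ij+r−1)! ∏_k N_ijk!

   computed in log space; the interval networks are unioned and edges found
   in a prior (literature) edge list are marked *confirmed*
   (`k2Score`, `k2Search`, `learnIntervalNetworks`, `unionNetwork`).
4. **Screen** — node entropy H_i = −Σ_j p_ij log p_ij with
   p_ij = |corr(k_i,k_j)| / Σ_m |corr(k_i,k_m)| over network neighbours
   (Pearson if both series pass a normality check, Spearman otherwise);
   total entropy is the sum over nodes. Each unconfirmed edge is tested in
   all contexts formed from the other unconfirmed edges of its group and
   admitted when fewer than `b` contexts see an entropy increase above `a`
   (`networkEntropy`, `screenEdges`).
5. **Rank & validate** — sensitivity g_i = total entropy drop when node i
   is deleted (largest drop = most vital gene), and per-gene PLS models
   restricted to network parents scored by mean relative prediction error
   on simulated normal data (`sensitivityScores`, `fitPLS`,
   `simulateError`).

A seeded synthetic generator with known piecewise-stationary ground truth
(`synthConfig`, `generateSynthetic`, `recoveryReport`) makes the whole
chain testable without any external data. See the methods vignette
(`vignettes/dynamic-network-entropy.Rmd`) for assumptions and design
rationale.

## Worked example

The package bundles a small **synthetic** stand-in for the case-study
dataset (same shape: 8 named regulators, 17 timepoints at 10-min spacing,
a few missing entries, a regime change at 80 min — see
`inst/scripts/make_synthetic_fixture.R`):

```r
library(dynent)
src   <- system.file("extdata", "synthetic_cdc28_like.tsv",  package = "dynent")
prior <- system.file("extdata", "synthetic_prior_edges.tsv", package = "dynent")

es <- readExpressionTSV(src)
es
#> ExpressionSeries: 8 genes x 17 timepoints (0-160 min), 5 missing

es  <- normalizeSeries(imputeMissing(filterByMissingRate(es, 0.15)))
seg <- segmentSeries(es, window = 20, alpha = 0.01)
seg
#> Segmentation: 2 intervals, boundaries [0, 80, 160] (alpha=0.01, window=20, test=ks/pooled)

ds   <- discretizeSeries(es)
nets <- learnIntervalNetworks(ds, seg,
          ordering = c("CLN1","CLN2","CDC28","SWE1","CDC5","CDH1","SWI5","SIC1"))
un   <- unionNetwork(nets, readPriorTSV(prior))
un
#> RegNetwork: 8 nodes, 7 edges (confirmed: 2, unconfirmed: 5, candidate-added: 0)

scr <- screenEdges(un, expr = es, a = 0.3, b = c(100, 200), groups = list(1:2, 3:5))
rk  <- sensitivityScores(scr, expr = es)
rk
#> SensitivityRanking: baseline entropy 3.5754; top: CLN1 > CDC28 > SWE1
round(sensitivity(rk), 4)
#>   CLN1   CLN2  CDC28   SWE1   CDC5   CDH1   SWI5   SIC1
#> 2.4792 0.4051 1.7875 1.7862 1.0963 0.4060 0.4032 0.4053
```

The segmentation finds the planted regime change at 80 min; the union
network carries 7 edges of which the 2 listed in the prior are confirmed;
and CLN1 — the root regulator of the first planted segment — is the most
sensitive node: deleting it costs 2.48 nats of the 3.58-nat total entropy.

`runPipeline(config)` chains all stages from a JSON/list config and writes
every artifact (TSV networks, JSON segmentation/ranking/error report plus a
manifest); `inst/scripts/dne.R` exposes the same stages as shell
subcommands (`preprocess`, `segment`, `learn`, `screen`, `rank`,
`validate`, `simulate`, `run-all`).

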