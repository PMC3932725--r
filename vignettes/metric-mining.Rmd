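---
title: "Mining batteries of image similarity metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining batteries of image similarity metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metricmine)
```

## The problem

Registration algorithms (and image-processing pipelines generally) are
sensitive to their parameters: sweeping a handful of settings over a few
algorithms easily produces a hundred-plus candidate images of wildly varying
quality, and no single similarity metric is a trustworthy judge of all of
them. Every metric encodes a different notion of similarity, some metrics
are biased toward particular modalities, and a few are notoriously
inconsistent with the rest. `metricmine` takes the meta-algorithmic view:
evaluate every candidate against the reference under a *battery* of p = 11
metrics, log everything to a relational store, and mine the resulting n × p
score table to extract a consensus ranking and to diagnose which metrics
(dis)agree.

## The metric battery

For a reference image $\mathcal{R}$ and candidate $\mathcal{S}$ on the same
voxel grid of size $N$, the battery computes, with population ($1/N$)
normalisation throughout:

| name | raw definition | kind |
|------|----------------|------|
| `msd` | $\frac{1}{N}\sum_x (R(x)-S(x))^2$ | intensity distance |
| `adi` | $\frac{1}{N}\sum_x |R(x)-S(x)|$ | intensity distance |
| `edi` | Shannon entropy (bits) of the binned difference image $R-S$ | statistical distance |
| `mif` | $\mathcal{I}(\mathcal{R},\mathcal{S}) = H_R + H_S - H_{RS}$ | statistical similarity |
| `nmi` | $\mathcal{I}/H_{RS} + 1 = (H_R+H_S)/H_{RS}$ | statistical similarity |
| `ncc` | $\operatorname{cov}(R,S)/(\sigma_R \sigma_S)$ | intensity similarity |
| `cor` | $1 - \frac{1}{N}\sum_i N(i)\,\sigma^2(i)/\sigma^2$ (correlation ratio) | statistical similarity |
| `woo` | $1 - \frac{1}{N}\sum_i N(i)\,\sigma(i)/\mu(i)$ (Woods) | statistical similarity |
| `red` | $\mathcal{I}/(H_R+H_S)$ (redundancy) | statistical similarity |
| `uni` | $1 - \mathcal{I}/H_{RS}$ | statistical distance |
| `aum` | $1 - \mathcal{I}/\max(H_R,H_S)$ | statistical distance |

Here $H$ denotes Shannon entropy in bits of the binned intensity
distributions, the index $i$ runs over intensity bins of $\mathcal{R}$, and
$\mu(i), \sigma^2(i)$ are the mean and population variance of the
*candidate's* exact intensities at the voxels falling in reference bin $i$.
The correlation ratio and Woods criterion are therefore asymmetric in
$(\mathcal{R}, \mathcal{S})$ — we fix conditioning on the reference — while
the other nine metrics are symmetric.

To make values comparable across metrics, every raw value is mapped to a
**score in [0, 1] with 1 optimal**. The mappings are this package's own
convention: distances are normalised by their attainable maximum and
subtracted from 1 (`msd` by $D^2$ and `adi` by $D$, where $D$ is the shared
dynamic range of the pair; `edi` by $\log_2 B_d$); `ncc` is affinely mapped
from $[-1,1]$; the entropy ratios use their natural $[0,1]$ ranges (`mif` is
normalised by $\min(H_R,H_S)$, an uncertainty-coefficient form, so an exact
copy scores 1); `cor` and `woo` are already ratios and are clamped. The
Woods raw value can be negative when within-bin spread is large relative to
the bin mean; it clamps to 0. Out-of-range values elsewhere indicate a
numerical problem and clamp with a warning.

### Binning and masking

The source formulations leave binning open, so the package fixes a
convention and exposes it: equal-width bins over the **union of both
images' intensity ranges** (so an identical pair bins identically), default
$B = 64$ for marginals, $(64, 64)$ for joints and 64 for the difference
image — a common default for histogram-based mutual information that also
makes small integer-valued test images bin exactly (one distinct value per
bin whenever the values are at most 64 equally spaced levels). Bins are
half-open with the last bin closed, so range maxima are counted. Entropies
are in bits; the base cancels in every ratio-form metric. An optional
background mask (off by default) excludes voxels at a given background
value, since large uniform backgrounds can otherwise dominate voxelwise
measures.

### Degenerate inputs

A constant image has zero variance and zero marginal entropy. `ncc` and
`cor` raise a typed degenerate-input error; the Woods criterion does so
when every occupied bin mean lies below its $\varepsilon$ threshold
(default `1e-8`; bins with near-zero means are skipped and counted, never
shifted). The mutual-information family instead returns flagged degenerate
results (score 1 for a voxelwise-identical constant pair, else 0). In the
battery these failures become `NA` cells marked in a `missing` attribute —
never fabricated values — and the mining stage either drops those rows
(default) or imputes the column mean rank.

## Rank-based robust PCA

Raw scores from different metrics live on incomparable scales. Replacing
each column by its within-column ranks (ascending, average ranks on ties)
removes all scaling concerns: any strictly increasing transform of a metric
leaves the analysis unchanged, which is exactly the invariance a
multi-metric consensus should have. PCA is then performed by
eigen-decomposition of the **Spearman rank correlation matrix** of the
table — a nonparametric, outlier-resistant variant of PCA. For tie-free
tables this is equivalent to PCA of the rank covariance, because every rank
column has the same a-priori-known population variance $(n^2-1)/12$; with
ties the two differ slightly and we use the correlation form, which the
method names explicitly. The test suite verifies both routes produce the
same eigenstructure on tie-free tables.

Eigenvector signs are arbitrary, so two conventions make the output
deterministic: each loading vector's largest-magnitude entry is made
positive, and PC1 is re-oriented, if necessary, so that its candidate
scores correlate positively with the row-mean rank (the naive consensus).
Candidates are ranked by descending oriented PC1 score; ties break by
row-mean rank, then lexicographically by run id. There is no randomness
anywhere in the mining stage.

The Spearman matrix also drives the metric diagnostics:
average-linkage hierarchical clustering at distance $1 - \rho$ groups
mutually consistent metrics and isolates inconsistent ones (in practice the
entropy-of-difference and Woods metrics are the usual suspects), and
`consistency_report()` reports the minimum pairwise correlation within a
named "consistent core" and flags metrics whose mean correlation with that
core falls below a threshold (default 0, i.e. anticorrelation).

## The synthetic benchmark

No external image data ships with the package. `make_phantom()` builds a
smooth multi-blob image — a sum of 6 anisotropic Gaussian blobs with seeded
random centers, widths and amplitudes on a dark background — and
`perturb()` degrades it with the three failure modes a registration sweep
actually produces: rigid misalignment (in-plane rotation plus translation,
linear interpolation, background edge padding), multiplicative
low-frequency bias shading, and additive Gaussian noise. A single
`severity` knob scales all components, so severity 0 reproduces the
reference voxelwise and the ground-truth quality ordering is known by
construction. The defaults at severity 1 — 1.5 voxels translation per axis,
8° rotation, ±20 % bias amplitude, noise at 5 % of the unit blob
amplitude — were chosen once as a realistic mix of gross misregistration
and subtle degradation for grids of side 8–32 voxels.

Phantom intensities are quantized to 64 gray levels (acquired images are
integer-valued anyway). This also makes the reference an exact fixed point
of the binned statistical metrics: with at most 64 distinct levels, the
64-bin histograms separate every level, so a perfect candidate achieves
score 1 on *all* eleven metrics, including the bin-conditioned `cor` and
`woo`. With continuous intensities those two would hover just below 1 at
identity because equal-width bins retain within-bin spread — a property of
binned conditioning itself, not of the implementation.

What passing the synthetic benchmark does **not** show: phantoms are not
anatomically realistic, the perturbation model does not imitate any
specific registration algorithm's failure modes, candidates degrade along
a single severity axis rather than the many axes of a real parameter sweep,
and all candidates live on the reference grid (the package never resamples
or reasons about affine space). Results on real registration campaigns
depend on metric/modality fit in ways no phantom can certify.

## Campaign bookkeeping and the store

`parameter_grid()` / `enumerate_grid()` enumerate Cartesian parameter
products in deterministic lexicographic order (first declared axis
slowest), and the shipped fixture
`inst/extdata/campaign_registration.json` encodes a representative
four-algorithm registration sweep — 30 runs of linear AIR, 90 of AIR warp
(three warp models over the linear grid), 60 of FSL FLIRT, 6 of MINC
Tracc, 186 in all. Runs and metric values are logged to an embedded
single-file SQLite database (schema in `inst/extdata/schema.sql`, plain
SQL so a client-server backend is a drop-in): one transaction per battery,
so a crash mid-evaluation never leaves a partial row of metrics, and
independent workers can log disjoint runs concurrently. Timestamps are UTC
ISO-8601 and parameter assignments are stored as canonically ordered JSON
for deterministic diffs.

## Numerical choices

* Population (1/N) moments everywhere, matching the 1/N normalisations of
  the raw formulas.
* Conditional variances use a two-pass (centered) computation so
  bin-constant data gives exactly zero — the one-pass form loses ~8 digits
  to cancellation, which is visible when asserting that identity pairs
  score exactly 1.
* The entropy-of-difference metric is implemented as a genuine Shannon
  entropy (with the minus sign) of the binned difference distribution,
  normalised by $\log_2$ of its bin count; the quantity's name, its use and
  its degenerate cases all require an entropy even where shorthand
  notations omit the sign.
* Joint histograms are accumulated with integer `tabulate()` on flattened
  bin indices; marginalising the joint reproduces the marginal histograms
  exactly, by construction.
* Mutual information is clamped at 0 against floating-point negatives.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at desk scale: phantoms of shape 16 × 16 × 8 (2048 voxels, with
12 × 12 × 8 used in a few property loops), candidate sets of n = 50 over a
0–1 severity grid repeated over 10 seeds, one full 186-candidate campaign,
and exhaustive oracle sweeps over all pairs of 4-voxel 3-level images plus
seeded samples of 8-voxel 4-level pairs. These sizes exercise every code
path while keeping the whole suite in the tens of seconds.

## A worked pipeline

```{r, eval = FALSE}
cs <- make_candidate_set(n = 50, severity_grid = seq(0, 1, length.out = 50),
                         seed = 1, shape = c(16, 16, 8))
tab <- evaluate_battery(cs$reference, cs$candidates)

store <- store_open("runs.sqlite")
store_log_table(store, tab)
tab2 <- store_fetch_table(store)
store_close(store)

mining <- mine_table(tab2)
head(mining$ranking)
consistency_report(mining$spearman,
                   subset = setdiff(metric_names(), c("edi", "woo")))

parallel_coordinates(tab2, file = "parallel.png")
correlation_heatmap(mining$spearman, file = "heatmap.png")
pc_scatter(mining$pca, file = "pcs.png")
```

The same pipeline is scriptable from a shell via the installed `metricmine`
executable (`simulate`, `evaluate`, `mine`, `report`, `export`).

## Known limitations

* Metrics assume voxelwise-comparable grids; there is no resampling,
  reorientation or affine-space reasoning.
* Only intensity-based and statistical metrics are implemented; feature-,
  surface- and deformation-based measures are out of scope, as is running
  any registration optimiser.
* The score normalisations are a convention of this package; raw values are
  always retained alongside so any other convention can be applied
  downstream.
* Binned conditioning makes `cor`/`woo` (and all histogram metrics) depend
  on the bin count; the default of 64 is a choice, not a law, and is
  exposed everywhere.
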