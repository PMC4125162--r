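---
title: "Height-structured habitat metrics and avian richness models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Height-structured habitat metrics and avian richness models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Broad-scale models of bird species richness have traditionally relied on
two-dimensional habitat structure: land-cover patches, their sizes, shapes
and edges. Continental canopy-height products (30 m grids of
basal-area-weighted tree height) make a third dimension available, but
summary statistics of height (mean, SD, min, max) ignore *where* the tall
and short vegetation sits. Two landscapes with identical height histograms
can be ecologically very different depending on whether tall trees cluster
or scatter.

`canopyrich` implements a pipeline that quantifies this spatial
arrangement of canopy height and asks whether it improves richness models:

1. clip a circular landscape buffer (default radius 19 km, about half a
   survey route's length, enclosing roughly 1100 km²) around each route
   centroid;
2. compute four metric sets per buffer (26 metrics);
3. estimate detection-adjusted route richness with the first-order
   jackknife, averaged over a window of years (default 1998–2002);
4. compare linear and random-forest models with and without the
   height-structured metrics.

## The four metric sets

**Set A — summary height statistics.** `MEAN`, `SD`, `MIN`, `MAX` of
height over vegetated (height > 0), non-nodata cells. SD is the population
SD, as is every SD in the package (the convention of the standard
patch-metric literature).

**Set B — traditional patch metrics.** The binary vegetated /
non-vegetated map is segmented into 8-connected patches. `B.NP` is the
patch count, `B.AREA.MN`/`B.AREA.SD` the mean/SD patch area in hectares,
`B.TE` the total vegetated/background edge in meters (4-neighbour faces;
window boundary and nodata faces are *not* edges, which avoids buffer-size
artifacts), `B.ED = B.TE / area` in m/ha, and `B.FRAC.MN`/`B.FRAC.SD`
summarize the per-patch fractal dimension index

$$\mathrm{FRAC} = \frac{2\,\ln(0.25\,P)}{\ln A},$$

with perimeter $P$ in m and area $A$ in m²; FRAC is exactly 1 for squares
and approaches 2 for maximally convoluted shapes. ($A = 1\,\mathrm{m}^2$
makes the denominator zero; such patches are excluded from the mean/SD.
They cannot occur at the 30 m default resolution.)

**Set C — height-structured patch metrics.** Heights are classified by
global thresholds (default class boundaries 5, 10, 15, 25 m above a
vegetation cutoff of 0 m, i.e. five vegetated classes; configurable).
A vegetated cell with height $h$ belongs to class $j$ iff
$t_{j-1} < h \le t_j$, with the top class open. Same-class 8-connected
cells form *vertical patches*; boundaries between 4-adjacent cells of
different classes are *vertical edges*, each weighted by a depth
$d_{ik} \in [0,1]$ from a contrast matrix. The default contrast is

$$d_{ik} = \frac{|m_i - m_k|}{\max_j m_j - \min_j m_j},$$

where $m_j$ are class midpoints (the open-topped class midpoint is the top
threshold plus half the previous class width), and the
vegetated/background boundary carries maximal depth 1. `C.NP`,
`C.AREA.MN/SD`, `C.TE`, `C.FRAC.MN/SD` are the set-B analogues over
vertical patches. In addition:

* `C.CWED` (contrast-weighted edge density)
  $= \sum_{ik} e_{ik} d_{ik} / A \times 10^4$ m/ha, where $e_{ik}$ is the
  shared boundary length of classes $i,k$. Background faces are included
  at depth 1 — consistent with their treatment in `C.TE` and ECON, so
  habitat/non-habitat remains the maximal contrast.
* `C.ECON.MN/SD`: per-patch edge contrast index, the length-weighted mean
  depth of a patch's boundary. Patches whose entire boundary is window
  border or nodata have no defined ECON and are dropped from the
  summaries.
* `C.SHDI` $= -\sum_i p_i \ln p_i$ over *vegetated* class area
  proportions (background is excluded, so a fully forested one-class
  landscape has SHDI 0).

Because every vegetated/background face counts in both `B.TE` and `C.TE`
and height segmentation can only add internal boundaries, `C.TE >= B.TE`
and `C.NP >= B.NP` always hold; the test suite asserts both on random
landscapes.

**Set D — co-occurrence texture.** Heights (including non-vegetated zeros)
are linearly binned into $g = 32$ grey levels over the window's min–max
range; a single whole-window grey-level co-occurrence matrix (GLCM) is
pooled over the four 1-pixel offsets (0°, 45°, 90°, 135°),
symmetrized, and normalized. Pairs touching nodata or the window edge are
skipped (buffers are circles inside square arrays). From the normalized
$P$:

* entropy $-\sum P \ln P$,
* contrast $\sum (i-j)^2 P$,
* angular second moment (ASM) $\sum P^2$,
* homogeneity $\sum P / (1 + (i-j)^2)$,
* dissimilarity $\sum |i-j| P$.

32 levels balance grey-level resolution against sparse-matrix noise in a
~1.2M-cell buffer; the whole-window (rather than moving-window) GLCM
matches the landscape scale at which metrics enter the models. Both
choices are configurable.

## Detection-adjusted richness

A survey route-year is a species × occasion detection matrix; occasions
are the 50 protocol stops by default. The first-order jackknife

$$\hat S = S_{obs} + f_1 \frac{k-1}{k}$$

adds to the raw species count $S_{obs}$ a correction driven by $f_1$, the
number of species detected in exactly one of the $k$ occasions; it derives
from closed-population multiple-recapture theory and allows detection
probability to vary among species. `k` is configurable because
pre-processing programs in this tradition sometimes group stops into
fewer occasions; the package default keeps the 50 stops as occasions.
Records flagged unacceptable or surveyed by first-year observers are
removed first; yearly estimates are averaged over the available years of
the window. Guild richness restricts the detection matrix to the guild's
species before estimation.

## Model comparison

For each guild the package computes Pearson correlations (untransformed
values — matching the linear-model framework; no multiple-testing
adjustment is applied to this screen) of all 26 metrics with mean
richness, selects the **best-performing height-structured metrics
(BPHMs)** — the 2 metrics from set C and 2 from set D with the highest
mean |r| across guilds, ties broken alphabetically with a warning — and
fits:

* six linear models (`A`, `B`, `C`, `D`, `A+BPHM`, `B+BPHM`) by OLS,
  reporting adjusted $r^2 = 1-(1-R^2)(n-1)/(n-p-1)$ and the Gaussian
  profile AIC $n \ln(\mathrm{RSS}/n) + 2(p+2)$. The AIC constant
  convention is internal and documented; only differences between models
  on the same data are meaningful. Rank-deficient designs are an error
  naming the collinear columns; a (near-)zero residual sum of squares is
  an error rather than an infinite AIC. Predictors enter on their raw
  scales (adjusted r², AIC and the RF are scale-equivariant where it
  matters; the choice is recorded here so comparisons are internally
  valid).
* 95% confidence intervals for adjusted-r² and AIC from a
  case-resampling bootstrap of routes (3000 replicates by default) with
  the bias-corrected and accelerated (BCa) interval: bias correction
  $z_0 = \Phi^{-1}(\#\{t^* < t_0\}/B)$ and acceleration
  $a = \sum (\bar t - t_i)^3 / (6 [\sum (\bar t - t_i)^2]^{3/2})$ from
  leave-one-out jackknife replicates. Whole routes are resampled (metrics
  and richness are route-level observations), not residuals. A degenerate
  bootstrap distribution falls back to the percentile interval with a
  warning; a constant statistic yields a zero-width interval.
* seven random forests (the same six predictor sets plus the
  all-inclusive 26-metric model). The forest is implemented in C++ inside
  the package: CART regression trees grown on bootstrap samples,
  `mtry = max(1, floor(p/3))` candidate variables per split and minimum
  split size 5 (the customary regression defaults; only the tree count,
  2000, is treated as a protocol constant — enough for the OOB residual
  error to converge, which the test suite checks as ±0.03 across seeds).
  Explained variance is $1 - \mathrm{MSE}_{OOB}/\mathrm{Var}(y)$ on
  ensemble out-of-bag predictions. Importance is permutation %IncMSE: the
  mean increase of a tree's OOB MSE when the metric is permuted among
  that tree's OOB cases, expressed as a percentage of the mean per-tree
  OOB MSE. (The classical implementation's "scaled" variant divides by
  the SD of the increases, yielding a z-score; we report a true
  percentage. Rankings, which are all the analysis uses, agree.)

The whole suite is reproducible bit-for-bit from one master seed: the
bootstrap uses R's RNG, the forest a dedicated C++ RNG seeded per model.

## The synthetic world

The generator exists so every stage is testable without external data; its
defaults are the package's stated world and are not tuned to test
outcomes.

**Landscapes.** A Gaussian random field (FFT convolution with a Gaussian
kernel, periodic boundaries) is thresholded at the vegetation fraction to
give the vegetated mask, with the smoothing length set by
`autocorr_range`. Vegetated heights are drawn from a normal truncated at
zero and *placed by rank-reordering onto a second smoothed field*, so
`clustering` controls how strongly tall trees aggregate without changing
the marginal height distribution (the test suite verifies both the
invariance of the sorted heights and the rise of Moran's I). Nodata cells
are uniform random. For route simulation the parameters are drawn per
route from wide ranges — vegetation fraction 0.15–0.95, mean height
5–30 m, height SD 1–10 m, autocorrelation range 0–1200 m, clustering
0–10, nodata 0–0.1 — chosen to span sparse woodland to closed forest and
fine- to coarse-grained mosaics, the breadth a continental sample of
forested landscapes shows. The nodata variation matters beyond realism:
with strictly identical buffer areas, edge density is an exact multiple of
total edge and the set-B linear design would be rank-deficient — a
degeneracy real clipped buffers do not have.

**Surveys.** True richness per route and guild is
$\mathrm{round}(\alpha_g + s_g \sum_j \beta_j z_j + \varepsilon)$, linear
in standardized metrics, clipped to $[1, \text{pool size}]$. Guild
structure is emulated by three overlapping species pools (a broad
woodland pool and smaller forest-edge and interior-forest pools) whose
responses are scaled copies ($s_g$ = 1, 0.8, 0.15) of the configured
effect vector — mirroring a strongly responding broad guild, a moderately
responding edge guild and a weakly responding interior guild. Because
pools overlap, a guild's *realized* richness (count of its members
present) can exceed its own draw; both the drawn target and the realized
truth are reported. Each present species carries a per-occasion detection
probability drawn from `detect_prob_range` (default 0.2–0.8), and each
route-year additionally draws a detectability multiplier from
`detectability_range` (default 0.05–0.5) emulating observer skill and
survey conditions. The multiplier is essential: with 50 occasions and
per-stop probabilities of 0.2+, cumulative detection is effectively
perfect, every singleton count is zero and the jackknife degenerates to
the raw count. Route-varying detectability is also why detection
adjustment helps at all — it creates route-specific undercounts that the
jackknife partially recovers, and it is the documented reason surveys
filter first-year observers. Quality flags are independent Bernoulli
draws.

**What the world does not emulate** — and hence what a green test does
not establish: roadside placement bias of routes, species abundance
structure (presence/detection only), spatial autocorrelation of richness
between routes, ecoregion stratification, and real species lists (guilds
are synthetic labels).

## Known limitations

* **Correlated-metric importance.** When richness is planted on ENTROPY
  and C.CWED, the all-inclusive random forest reliably ranks ENTROPY
  first but splits the remaining importance between C.CWED and its
  proxies (C.TE, HOMOGENEITY): spatial smoothness is a common latent
  factor of most heterogeneity metrics, so permutation importance spreads
  over correlated predictors. The acceptance suite states the strict
  top-2 criterion and reports its failure honestly; the model-improvement
  criterion (A+BPHM vs A with non-overlapping BCa intervals) passes by a
  wide margin. On independent predictors the forest recovers planted
  top-2 ranks, which the unit tests verify.
* The exact height-class thresholds and contrast weights of any
  particular study are configurable inputs; the defaults (5/10/15/25 m,
  midpoint-difference contrast) span typical canopy heights but are
  necessarily a choice.
* The pixel-based global-threshold segmentation is deliberately the
  simplest delineation of vertical patches; region- or edge-based
  segmentation is out of scope.
* GeoTIFF I/O is not available in this build environment; rasters are
  exchanged as ESRI ASCII grids.
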