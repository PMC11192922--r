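---
title: "Methods: entropy-weighted forest security indexing, hotspot detection and GWR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy-weighted forest security indexing, hotspot detection and GWR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestsec)
```

`forestsec` implements a three-stage spatial analysis of regional forest
ecological security: a composite index built from a pressure-state-response
(PSR) indicator panel with entropy weighting, local Getis-Ord Gi\*
hot/cold-spot classification of that index, and a geographically weighted
regression (GWR) of the index on socioeconomic drivers. This vignette
documents the models, the defaults and why they were chosen, the numerical
conventions, and what the synthetic-data tests do and do not demonstrate.

## The composite index

The input is a panel $X = (x_{ij})_{m \times n}$ of $m$ (unit, year) rows
and $n$ indicators, each indicator labelled with a PSR *block* (status,
pressure, response) and an *orientation* (positive = good for security,
negative = bad). Each column is min-max standardized,

$$y_{ij} = \frac{x_{ij} - x_{\min,j}}{x_{\max,j} - x_{\min,j}}
\quad\text{(forward)},\qquad
y_{ij} = \frac{x_{\max,j} - x_{ij}}{x_{\max,j} - x_{\min,j}}
\quad\text{(reverse)},$$

with the direction chosen so that larger $y$ always means "more of what the
block measures": positive status indicators enter forward; negative
pressure indicators enter the pressure block forward (more raw pressure,
larger $y$); positive response indicators enter the pressure block reverse
(more maintenance, smaller net pressure). This makes the pressure index a
pure *net pressure*, so the composite below is monotone in security. The
directional labels attached to standardization in published descriptions of
this index family are not mutually consistent; the mapping above is the one
that preserves monotonicity, and it is recorded here as a package design
decision.

Weights come from the entropy-weight method. With column proportions
$p_{ij} = y_{ij} / \sum_i y_{ij}$, the normalized Shannon entropy is

$$H_j = -\frac{\sum_{i=1}^m p_{ij}\ln p_{ij}}{\ln m},
\qquad 0\ln 0 := 0,$$

and the weight of indicator $j$ within its block is
$w_j = (1 - H_j) / \sum_{j'} (1 - H_{j'})$. Note the normalizer is $\ln m$
(the number of rows being summed over), the value for which a uniform
column attains $H = 1$; some published write-ups print the number of
indicators here, which cannot be right dimensionally. Weights are computed
separately for the status block (giving the status index $Z = \sum_j w_j
y_{ij}$) and for the combined pressure + response block (giving the net
pressure index $Y$), so that both lie in $[0,1]$ and each block's weights
sum to one. The composite is the geometric mean

$$\mathrm{ESI} = \sqrt{Z\,(1 - Y)} \in [0, 1].$$

Conventions for degenerate inputs: a constant column standardizes to 0.5
everywhere and receives entropy 1, hence weight 0 — a column with no
ordering information cannot influence the index and cannot cause division
by zero. If *every* column in a block is uninformative the block falls back
to equal weights. Standardization and weights are pooled across all years
in the panel, because comparing index levels between years requires a
common scale; per-year standardization would re-base the index each year.

## Hot and cold spots

The spatial clustering stage works on one year's index values $x_j \ge 0$
over $n$ units with centroid coordinates. Distances are great-circle
(haversine, Earth radius 6,371,000 m). The spatial weights are a binary
distance band including the focal unit ($w_{ii} = 1$, the Gi\* "star"
convention); the default band is the largest nearest-neighbor distance,
the smallest choice that leaves no unit without a neighbor. The local
statistic is the share of total attribute mass inside the band,

$$G_i^*(d) = \frac{\sum_j w_{ij}(d)\, x_j}{\sum_j x_j},$$

standardized with the Getis-Ord randomization moments:
$z_i = \left(\sum_j w_{ij}x_j - \bar{x}W_i\right) \big/
\left(S\sqrt{[\,n S_{1i} - W_i^2\,]/(n-1)}\right)$ with
$W_i = \sum_j w_{ij}$, $S_{1i} = \sum_j w_{ij}^2$ and
$S = \sqrt{\overline{x^2} - \bar{x}^2}$. A constant attribute, or a band
covering every unit, gives $z_i = 0$ by convention. A permutation test in
the suite confirms the moments are calibrated: on a 30-unit layout the
fraction of $|z| > 1.96$ under random relabelling is close to the nominal
5%.

The z-scores are then cut into four classes — cold, secondary cold,
secondary hot, hot — by exact Fisher-Jenks natural breaks: the contiguous
partition of the sorted values minimizing total within-class sum of squared
deviations, found by dynamic programming and verified in the tests against
exhaustive enumeration for $n \le 12$. Ties between equally good
partitions are broken toward the lexicographically smallest break indices,
so the classification is deterministic across platforms; if all values are
equal, the first classes become singletons and labels follow sorted
position. Classification is applied to z-scores rather than raw ratios,
since the standardized statistic is what carries the hot/cold
interpretation.

## Geographically weighted regression

The driver analysis fits, at every observation location $i$,

$$y_i = \beta_0(u_i, v_i) + \sum_{k=1}^p \beta_k(u_i, v_i)\,x_{ik} +
\varepsilon_i,$$

by weighted least squares with fixed Gaussian kernel weights
$w_{ij} = \exp[-(d_{ij}/b)^2]$ (self-weight 1). The bandwidth $b$ is in
meters; it is selected by minimizing the leave-one-out cross-validation
score $CV(b) = \sum_i [y_i - \hat{y}_{\ne i}(b)]^2$, in which the focal
observation is excluded ($w_{ii} = 0$) — with self-weight retained the
criterion would collapse to interpolation at $b \to 0$. The search scans a
20-point logarithmic grid over $[d_{\min},\, 2 d_{\max}]$ to bracket the
minimum and refines by golden-section search on the log scale to $10^{-3}$
relative tolerance; the suite checks the result against a dense 500-point
grid. A bandwidth so small that some held-out fit is singular scores
$+\infty$.

Diagnostics use the hat matrix $S$ whose row $i$ is
$\mathbf{x}_i^\top (X^\top W_i X)^{-1} X^\top W_i$: $R^2 = 1 -
\mathrm{RSS}/\mathrm{TSS}$, adjusted $R^2$ with $\mathrm{tr}(S)$ effective
parameters, and the corrected AIC

$$\mathrm{AICc} = 2n\ln\hat\sigma + n\ln 2\pi +
\frac{n\,(n + \mathrm{tr}(S))}{n - 2 - \mathrm{tr}(S)},
\qquad \hat\sigma^2 = \mathrm{RSS}/n.$$

Numerical conventions: a singular local normal matrix gets a ridge jitter
of $10^{-8}$ times its mean diagonal and the location is flagged
(`ridged`); irrecoverable singularity is an error naming the location.
Fits are cross-sectional — one year at a time, as in studies built on
five-yearly resource inventories. Predictors enter as given, with an
optional z-score standardization flag; published provincial coefficient
tables suggest some upstream transformation of the drivers, but with raw
inputs unavailable it cannot be pinned down, so no silent transformation
is applied. Distances default to haversine meters, with a planar option
because metric bandwidths reported alongside unspecified projected
coordinate systems are not reproducible exactly.

## The synthetic-data generator

Every stage is testable without external data. `gen_coordinates()` lays
units on a near-square lattice inside a China-like bounding box (lon
75-130°E, lat 20-50°N), optionally jittered ±20% of the cell size.
`gen_indicator_panel()` emulates a provincial PSR panel (default 30 units,
years 2013 and 2018 — the shape of a two-wave provincial cross-section):
positive status indicators uniform on plausible positive ranges, negative
pressure indicators log-normal (density- and emission-like heavy tails),
response indicators uniform fractions. Optionally one unit is forced to
the column-wise optimum of every indicator, which makes it a provable ESI
maximizer — a useful known-answer test for the whole index stage.

`gen_gwr_dataset()` draws drivers i.i.d. uniform $[0,1]$ (so coefficient
magnitudes are directly interpretable) and assembles the response exactly
from the generating model with chosen coefficient surfaces and Gaussian
noise. The defaults are $n = 100$ jittered locations, noise sd 0.05, seed
42, a planar intercept surface, a Gaussian-bump surface on the first
driver and a constant surface on the second. The bump width is 15° —
about a quarter of the region and several times the typical inter-point
spacing — chosen so the spatial variation is resolvable by a local
estimator at the default sample size; a much sharper surface is simply not
identifiable from 100 points at any bandwidth, and would test the sample
size rather than the estimator. Recovery on the default dataset (checked
in the suite): correlation with the true surface above 0.9 for the
spatially varying coefficients, and median absolute error below 0.1 for
all three. For the constant surface a correlation is undefined (the truth
has zero variance), so its recovery is scored by median absolute error
only.

What the generator does *not* emulate: the covariance structure of real
provincial statistics (indicators are drawn independently), spatially
autocorrelated noise, and measurement error in the drivers. Passing tests
therefore demonstrate correctness of the estimators under their own
assumptions, not robustness to real-world violations of them.

Determinism: all generators take an explicit seed and restore the caller's
RNG state, and the generating-model identity ($y$ reconstructable from the
stored surfaces, drivers and noise draws) is asserted bit-for-bit in the
tests. R's default Mersenne-Twister generator is part of the contract.

## Problem sizes used in the checks

The test suite and the reproduction script run at the study's natural
sizes: 30-unit layouts for the index and hotspot stages, 2,000
permutations for the Gi\* calibration check, $n = 100$ for GWR surface
recovery with bandwidth selection, 500-point reference grids for the
bandwidth search check, and exhaustive-enumeration oracles up to $n = 12$
for Jenks. The OLS-limit check (all local fits converge to the global OLS
solution as $b \to \infty$) is run on a regional-extent layout: at
$b = 10^9$ m a continental-extent layout still leaves kernel variation of
order $(d/b)^2 \approx 3\times10^{-5}$, visible in the sixth decimal of
the coefficients, whereas the property being tested is the limit itself.

## Known limitations

* The exact provincial index values and regression tables of the original
  provincial study are not reproducible: the underlying yearbook indicator
  matrix was never published. The packaged coefficient tables are
  transcriptions of the published *outputs*, used for summary-statistic
  reproduction, not refitting.
* The distance-band form and threshold behind published Gi\* maps, and the
  projection behind published metric bandwidths, are unstated in that
  literature; the defaults here (no-isolate band, haversine meters) are
  reasonable conventions, not reconstructions.
* Entropy weights are data-driven: adding or removing units changes the
  weights and hence the index. This is inherent to the method.
* GWR coefficients are exploratory descriptions of spatial heterogeneity;
  no significance testing of local coefficients is provided.
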