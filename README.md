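# forestsec

Tools for evaluating regional **forest ecological security** and analysing
its spatial structure and socioeconomic drivers. The package targets the
common provincial-scale study design: a pressure-state-response (PSR)
indicator panel per region and year, a composite security index, a map of
spatial clusters, and a spatially varying regression of the index on
drivers such as urbanization, industrial structure and foreign direct
investment (FDI).

Three stages, each usable on its own:

1. **Composite index.** Indicators $x_{ij}$ are min-max standardized with
   direction set by their PSR block and orientation, weighted by the
   entropy-weight method ($w_j \propto 1 - H_j$, per block), and combined
   into a status index $Z$, a net-pressure index $Y$ and the composite
   $\mathrm{ESI} = \sqrt{Z\,(1-Y)} \in [0,1]$.
2. **Hot/cold spots.** Local Getis-Ord
   $G_i^* = \sum_j w_{ij} x_j / \sum_j x_j$ on a binary distance band
   (self included), standardized with the randomization moments, then cut
   into four levels (cold / secondary cold / secondary hot / hot) by exact
   Fisher-Jenks natural breaks.
3. **GWR.** Local weighted least squares
   $y_i = \beta_0(u_i,v_i) + \sum_k \beta_k(u_i,v_i) x_{ik} + \varepsilon_i$
   with fixed Gaussian kernel $\exp[-(d_{ij}/b)^2]$, leave-one-out
   cross-validated bandwidth, and hat-matrix diagnostics
   ($R^2$, adjusted $R^2$, residual squares, AICc).

A synthetic-data module generates indicator panels and varying-coefficient
regression datasets with known ground truth, so every stage is testable
with no external downloads, and `inst/extdata/` packages transcriptions of
published per-province GWR coefficient tables for 2013 and 2018 (30
mainland Chinese provinces; two provinces romanize identically as "Shanxi"
and carry ids `Shanxi_1`/`Shanxi_2`).

## Worked example

```r
library(forestsec)

panel <- gen_indicator_panel(n_units = 30, years = c(2013, 2018), seed = 42)
esi <- compute_esi(panel)
esi
#> Forest ecological security index: 60 (unit, year) rows
#>   ESI mean 0.605, range [0.315, 0.819]

sub <- esi$index[esi$index$year == 2018, ]
hs <- hotspot_analysis(sub, sub$ESI)
hs
#> Gi* hotspot analysis of 30 units (band 770395 m)
#>
#>           cold secondary_cold  secondary_hot            hot
#>              3             13              9              5
```

The index is bounded in $[0,1]$ by construction; 0.6 means moderate
security. The band is the largest nearest-neighbor distance (no isolated
unit); the four classes partition the Gi\* z-scores, so the five "hot"
units are those whose neighborhoods concentrate the highest index values.

```r
sim <- gen_gwr_dataset()            # n = 100, known coefficient surfaces
fit <- gwr_fit(sim$data, response = "y", predictors = c("x1", "x2"))
fit
#> GWR fit: n = 100, bandwidth = 570485.9, tr(S) = 45.09
#>   R2 = 0.980 (adj 0.964), RSS = 0.1729, AICc = -177.977
cor(fit$coefficients[, "x1"], sim$beta_true[, "x1"])
#> [1] 0.904086
```

The selected bandwidth (~570 km) is found by LOOCV; the correlation shows
the local coefficients tracking the true Gaussian-bump surface of the
first driver.

Summary statistics of the packaged provincial tables:

```r
t18 <- load_gwr_table(2018)
round(column_mean(t18, "urbanization"), 3)
#> [1] -0.652
sign_count(t18, "fdi", "positive")
#> [1] 14
extremes(t18, "fdi", 1)$top
#>         id     name value
#> 1 Xinjiang Xinjiang 0.096
```

Urbanization depresses the security index everywhere in 2018 (mean local
coefficient −0.652), FDI has turned positive in 14 of 30 provinces, with
the strongest positive FDI effect in Xinjiang.

## Analysis workflow

`analysis/` contains the staged workflow, each script a thin driver over
the package that logs what it finds and writes tables under `results/`:

```sh
Rscript analysis/01_simulate.R         # synthetic panel, drivers, GWR truth
Rscript analysis/02_esi.R              # entropy weights, Z, Y, ESI
Rscript analysis/03_hotspots.R         # Gi*, Jenks classes per year
Rscript analysis/04_gwr.R              # per-year GWR + surface recovery
Rscript analysis/05_published_tables.R # published-table summary statistics
```

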