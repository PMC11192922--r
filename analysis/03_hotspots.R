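#!/usr/bin/env Rscript
# Stage 2 — spatial clustering of the index.
#
# Per year: binary distance-band weights (default band = largest
# nearest-neighbor distance, so no unit is isolated), local Getis-Ord Gi*
# with randomization z-scores, and a 4-class Jenks partition of the
# z-scores into cold / secondary cold / secondary hot / hot areas.

library(forestsec)

esi <- read.csv("results/esi.csv")
for (yr in sort(unique(esi$year))) {
  sub <- esi[esi$year == yr, ]
  hs <- hotspot_analysis(sub, sub$ESI)
  write_report(hs, "results", prefix = paste0(yr, "_"))
  counts <- table(hs$table$hotclass)
  message(sprintf("%d: band %.0f km; %s", yr, hs$threshold / 1000,
                  paste(names(counts), counts, sep = "=", collapse = ", ")))
  hot <- hs$table$id[hs$table$hotclass == "hot"]
  message("  hot spots: ", paste(hot, collapse = ", "))
}
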