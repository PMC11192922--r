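#!/usr/bin/env Rscript
# Stage 1 — entropy-weighted forest ecological security index.
#
# Standardizes the ten PSR indicators (pooled over both years so levels are
# comparable), derives entropy weights per block, and composes
# ESI = sqrt(Z * (1 - Y)) per (unit, year).

library(forestsec)

panel <- read_indicator_panel("results/panel.csv")
esi <- compute_esi(panel)
write_report(esi, "results")

idx <- esi$index
message(sprintf("ESI over %d rows: mean %.3f, range [%.3f, %.3f]",
                nrow(idx), mean(idx$ESI), min(idx$ESI), max(idx$ESI)))
for (yr in sort(unique(idx$year))) {
  sub <- idx[idx$year == yr, ]
  message(sprintf("  %d: best %s (%.3f), worst %s (%.3f)", yr,
                  sub$id[which.max(sub$ESI)], max(sub$ESI),
                  sub$id[which.min(sub$ESI)], min(sub$ESI)))
}
w <- esi$weights
message("heaviest status indicator: ",
        w$indicator[w$block == "status"][which.max(w$weight[w$block == "status"])])
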