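#!/usr/bin/env Rscript
# Stage 0 — simulate the study inputs.
#
# The published raw inputs (the provincial yearbook indicator matrix and the
# driver observations) are not deposited, so the workflow demonstrates every
# stage on synthetic data with the same shape: a 30-unit, 2-year PSR
# indicator panel, a matching driver table, and a varying-coefficient GWR
# dataset with known ground truth for estimator validation.

library(forestsec)

out <- "results"
dir.create(out, showWarnings = FALSE)
seed <- 42

panel <- gen_indicator_panel(n_units = 30, years = c(2013, 2018),
                             seed = seed)
write.csv(as.data.frame(panel), file.path(out, "panel.csv"),
          row.names = FALSE)
message(sprintf("indicator panel: %d rows x %d indicators -> %s",
                nrow(panel), nrow(default_indicator_spec()),
                file.path(out, "panel.csv")))

# drivers: urbanization fraction, tertiary/secondary ratio, FDI amount;
# the esi column is a placeholder overwritten by the pipeline with the
# computed index
set.seed(seed + 1)
drivers <- data.frame(
  as.data.frame(panel)[, c("id", "name", "lon", "lat", "year")],
  urbanization = runif(nrow(panel), 0.2, 0.9),
  industrial_structure = runif(nrow(panel), 0.4, 2.5),
  fdi = rlnorm(nrow(panel), log(50), 1),
  esi = 0.5)
write.csv(drivers, file.path(out, "drivers.csv"), row.names = FALSE)
message("driver table -> ", file.path(out, "drivers.csv"))

# ground-truth GWR dataset (planar intercept, Gaussian-bump x1, constant x2)
sim <- gen_gwr_dataset(n = 100, noise_sd = 0.05, seed = seed)
write.csv(sim$data, file.path(out, "gwr_sim.csv"), row.names = FALSE)
truth <- data.frame(sim$units, sim$beta_true)
write.csv(truth, file.path(out, "gwr_truth.csv"), row.names = FALSE)
message(sprintf("GWR simulation: n = %d, noise sd = %.2f -> %s + %s",
                100, 0.05, file.path(out, "gwr_sim.csv"),
                file.path(out, "gwr_truth.csv")))
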