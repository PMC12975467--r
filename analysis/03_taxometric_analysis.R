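#!/usr/bin/env Rscript
# Stage 3 — the fixed-base-rate taxometric analysis.
#
# Runs MAMBAC, MAXEIG and L-Mode on each synthetic dataset against 100
# simulated taxonic and 100 simulated dimensional comparison datasets at
# the assumed taxon base rate of 0.25, reports the per-method CCFIs,
# their mean and the band interpretation, and writes the full report
# file set (report.json, validity.csv, curves_<method>.csv) per dataset.
# Run 01_simulate_data.R first.

library(taxometry)

seed <- 20260903L
for (name in c("bss_like_taxonic", "sidas_like_taxonic",
               "bss_like_dimensional", "sidas_like_dimensional")) {
  cfg <- run_config(file.path("results/data", paste0(name, ".csv")),
                    base_rate = 0.25, n_sets = 100L, seed = seed,
                    enforce_validity = FALSE,
                    out_dir = file.path("results", name))
  res <- run_full_analysis(cfg)
  cat("\n==", name, "\n")
  print(res)
}
message("reports under results/<dataset>/")
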