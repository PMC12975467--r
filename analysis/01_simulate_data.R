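#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study datasets.
#
# The analysed questionnaire data are not publicly deposited, so the
# workflow runs on synthetic stand-ins: two taxonic datasets shaped like
# the published indicator tables (547 cases x 3 bounded factor scores;
# 989 cases x 3 bounded 0-10 item scores) plus their structure-matched
# dimensional counterparts.  Each matrix is written as CSV with a sidecar
# JSON recording the generating spec and (for taxonic data) the true
# membership oracle.

library(taxometry)

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260901L

write_set <- function(name, sim) {
  csv <- file.path(out_dir, paste0(name, ".csv"))
  write.csv(as.data.frame(as.matrix(sim$matrix)), csv, row.names = FALSE)
  sidecar <- file.path(out_dir, paste0(name, ".json"))
  meta <- list(spec = sim$spec[c("structure", "n", "k", "base_rate",
                                 "separation", "within_r", "loadings",
                                 "seed")],
               membership = sim$membership)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  message(sprintf("%-18s %4d cases x %d indicators -> %s",
                  name, nrow(sim$matrix), ncol(sim$matrix), csv))
}

for (preset in c("bss_like", "sidas_like")) {
  write_set(paste0(preset, "_taxonic"),
            simulate_taxonic(preset_spec(preset, seed = seed)))
  write_set(paste0(preset, "_dimensional"),
            simulate_dimensional(preset_spec(preset,
                                             structure = "dimensional",
                                             seed = seed)))
}
message("done: synthetic study datasets under ", out_dir)
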