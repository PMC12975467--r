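#!/usr/bin/env Rscript
# Stage 2 — descriptive screening and the indicator validity gate.
#
# For each synthetic dataset: per-indicator mean, SD, skewness, excess
# kurtosis, and Cohen's d between the putative taxon (top 25% of the
# standardized total score) and its complement.  Indicators need
# d >= 1.25 to enter the taxometric analyses.  Run 01_simulate_data.R
# first.

library(taxometry)

dir.create("results", showWarnings = FALSE)
for (name in c("bss_like_taxonic", "sidas_like_taxonic")) {
  m <- load_indicator_matrix(file.path("results/data",
                                       paste0(name, ".csv")))
  v <- validity_report(m, base_rate = 0.25, threshold = 1.25)
  cat("\n==", name, "\n")
  print(v)
  out <- file.path("results", paste0("validity_", name, ".csv"))
  write.csv(as.data.frame(v), out, row.names = FALSE)
  n_valid <- sum(v$valid)
  message(sprintf("%d of %d indicators valid -> %s",
                  n_valid, nrow(v), out))
}
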