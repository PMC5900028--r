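#!/usr/bin/env Rscript
# Parameterise the original (constant-slope) and soil-water-modified
# Ball-Berry models on the Exp. I drying data by nonlinear least squares,
# and report estimates with asymptotic 95% confidence bounds.
# Reads results/data/exp1_drying_*.csv (run 01 first);
# writes results/parameters.csv.

suppressMessages(library(ballberry))

fits <- list()
for (co2 in c(400, 800)) {
  dat <- read_gas_exchange(sprintf("results/data/exp1_drying_%d.csv", co2))
  for (variant in c("original", "modified")) {
    fit <- fit_bb(dat, variant)
    fits[[sprintf("%d ppm %s", co2, variant)]] <- fit
    cat("\n==", co2, "ppm,", variant, "model ==\n")
    print(fit)
  }
}

tab <- parameterization_table(fits)
write.csv(tab, "results/parameters.csv", row.names = FALSE)
cat("\nWrote results/parameters.csv\n")
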