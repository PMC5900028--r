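#!/usr/bin/env Rscript
# Compare WUE ~ VPD regression lines across irrigation regimes by ANCOVA,
# per CO2 level and model variant: per-regime slope/intercept (+/- SE) and
# r2 with significance stars, a slope-homogeneity F-test, and — when a
# common slope is tenable — compact letters on adjusted intercepts.
# Reads the per-observation predictions from 03; writes
# results/ancova_wue_vpd.txt.

suppressMessages(library(ballberry))

sink("results/ancova_wue_vpd.txt", split = TRUE)
for (co2 in c(400, 800)) for (variant in c("original", "modified")) {
  pred <- do.call(rbind, lapply(c("FI", "DI", "PRI"), function(trt)
    read.csv(sprintf("results/pred_%s_%d_%s.csv", trt, co2, variant))))
  pred <- pred[pred$valid, ]
  cat(sprintf("\n== %d ppm, WUE predicted by the %s model ==\n",
              co2, variant))
  print(wue_vpd_ancova(pred))
}
sink()
cat("\nWrote results/ancova_wue_vpd.txt\n")
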