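#!/usr/bin/env Rscript
# Validate the parameterised models on the independent Exp. II split-root
# data: predict stomatal conductance for every observation under each
# irrigation regime and score observed vs predicted g_s (r2, MAE, RMSE)
# for both model variants. Writes per-observation predictions and a metric
# summary; the headline comparison is whether the soil-water-modified model
# beats the original, especially under PRI.
# Reads results/data/ and results/parameters.csv (run 01 and 02 first).

suppressMessages(library(ballberry))

pars <- read.csv("results/parameters.csv")
param_of <- function(co2, variant) {
  row <- pars[grepl(paste0("^", co2, " "), pars$label) &
              pars$variant == variant, ]
  if (variant == "modified")
    bb_params(row$slope, row$g0, beta = row$beta)
  else bb_params(row$slope, row$g0, variant = "original")
}

rows <- list()
for (co2 in c(400, 800)) for (trt in c("FI", "DI", "PRI")) {
  dat <- read_gas_exchange(sprintf("results/data/exp2_%s_%d.csv", trt, co2))
  for (variant in c("original", "modified")) {
    v <- validate_bb(param_of(co2, variant), dat)
    m <- v$metrics
    rows[[length(rows) + 1L]] <- data.frame(
      co2 = co2, treatment = trt, variant = variant, r2 = m$r2,
      mae = m$mae, rmse = m$rmse, n = m$n)
    write.csv(v$predictions,
              sprintf("results/pred_%s_%d_%s.csv", trt, co2, variant),
              row.names = FALSE)
  }
}
metrics <- do.call(rbind, rows)
write.csv(metrics, "results/validation_metrics.csv", row.names = FALSE)

cat("Observed vs predicted g_s on Exp. II:\n")
print(metrics, digits = 3)
wide <- reshape(metrics[, c("co2", "treatment", "variant", "r2")],
                idvar = c("co2", "treatment"), timevar = "variant",
                direction = "wide")
better <- wide$r2.modified >= wide$r2.original
cat(sprintf("\nModified model r2 >= original in %d of %d regime/CO2 cells\n",
            sum(better), length(better)))
cat("Wrote results/validation_metrics.csv and results/pred_*.csv\n")
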