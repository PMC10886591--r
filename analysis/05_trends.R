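#!/usr/bin/env Rscript
# Step 5 — concentration trends.
#
# Merges the measured structure table with the extracted kinetics, screens
# each condition group with the iterative Grubbs test (alpha 0.05), fits
# per-sample-type multiple linear regressions of every parameter on
# fibrinogen and thrombin concentration, and writes the models and the
# sign-trend table. Censored lags are excluded from the lag regression.

library(clotquant)

structure_tab <- read.csv("results/data/structure.csv")
kin <- read.csv("results/kinetics.csv")
resp <- merge(structure_tab[c("well", "diameter_nm", "pore_um",
                              "percent_area", "length_um")],
              kin, by = "well")
resp$lag_s[resp$lag_censored | resp$lag_undefined] <- NA

params <- c("diameter_nm", "pore_um", "percent_area", "length_um",
            "lag_s", "rate_cm_s", "max_turbidity_cm")
models <- list()
for (st in unique(resp$sample_type)) {
  d <- resp[resp$sample_type == st, ]
  for (pm in params) {
    # Grubbs screening within each condition group
    for (g in split(seq_len(nrow(d)), list(d$fibrinogen, d$activator),
                    drop = TRUE)) {
      v <- d[[pm]][g]; ok <- is.finite(v)
      if (sum(ok) >= 3) {
        gr <- grubbs_filter(v[ok])
        if (length(gr$removed)) d[[pm]][g[ok][v[ok] %in% gr$removed]] <- NA
      }
    }
    m <- multiple_regression(d, pm)
    models[[paste(st, pm)]] <- c(list(sample_type = st),
                                 unclass(m)[c("response", "beta0", "beta_fib",
                                              "beta_act", "r_squared", "n")])
  }
}

jsonlite::write_json(unname(models), "results/regression_models.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
mdf <- do.call(rbind, lapply(models, function(m)
  data.frame(response = m$response, sample_type = m$sample_type,
             beta_fib = m$beta_fib, beta_act = m$beta_act)))
signs <- sign_trend_table(mdf)
write.csv(signs, "results/sign_trends.csv", row.names = FALSE)

cat("Fitted", length(models), "multiple regressions.\n\n")
cat("Diameter models (beta_fib nm per mg/mL, beta_act nm per U/mL):\n")
for (st in c("purified", "plasma")) {
  m <- models[[paste(st, "diameter_nm")]]
  cat(sprintf("  %-9s d = %.1f %+.2f [Fg] %+.2f [Thr]  (R^2 = %.3f, n = %d)\n",
              st, m$beta0, m$beta_fib, m$beta_act, m$r_squared, m$n))
}
cat("\nSign-trend table:\n")
print(signs, row.names = FALSE)
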