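#!/usr/bin/env Rscript
# Whole-spectrum calibration of the six leaf traits: PLSR (up to 25 latent
# variables) and linear epsilon-SVR (C in {0.01, 0.1, 1, 10, 100}), both
# selected by 10-fold cross-validated RMSE on the 60% training split and
# evaluated on the held-out 40%. Writes the calibration/test results table.

source("analysis/00_common.R")

d <- study_data()
X <- d$spectra
tr <- d$train

rows <- list()
for (trait in TRAITS) {
  y <- d$traits[[trait]]
  m <- fit_plsr(X[tr, ], y[tr], max_lv = 25, cv = d$cv)
  ev <- evaluate_predictions(y[!tr], predict_plsr(m, X[!tr, ]), trait)
  rows[[paste0(trait, "_plsr")]] <- data.frame(
    trait = trait, method = "PLSR", hyperparameter = m$selected_n_lv,
    calibration_r2 = r_squared(y[tr], m$fitted),
    calibration_rmse = rmse(y[tr], m$fitted),
    test_r2 = ev$r2, test_rmse = ev$rmse, test_mape_pct = ev$mape_pct,
    rpd = ev$rpd, category = ev$category)

  ms <- suppressWarnings(fit_svr(X[tr, ], y[tr], cv = d$cv))
  evs <- evaluate_predictions(y[!tr], predict_svr(ms, X[!tr, ]), trait)
  rows[[paste0(trait, "_svr")]] <- data.frame(
    trait = trait, method = "SVR", hyperparameter = ms$C,
    calibration_r2 = r_squared(y[tr], ms$fitted),
    calibration_rmse = rmse(y[tr], ms$fitted),
    test_r2 = evs$r2, test_rmse = evs$rmse, test_mape_pct = evs$mape_pct,
    rpd = evs$rpd, category = evs$category)
  cat(sprintf(
    "%-3s PLSR nLV=%2d R2=%.3f RPD=%.2f (%s) | SVR C=%g R2=%.3f RPD=%.2f (%s)\n",
    trait, m$selected_n_lv, ev$r2, ev$rpd, ev$category,
    ms$C, evs$r2, evs$rpd, evs$category))
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(results_dir(), "calibration_results.csv"),
          row.names = FALSE)
cat("wrote results/calibration_results.csv\n")
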