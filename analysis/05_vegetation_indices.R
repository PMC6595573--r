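#!/usr/bin/env Rscript
# Vegetation-index baselines: GNDVI, RENDVI and NDWI plus the exhaustive
# two-band normalized-difference search (84,255 pairs on the 411-band
# processed grid). Band selection and the linear+quadratic index
# regressions use the training split only; metrics are test-split. Writes
# the per-trait index results table.

source("analysis/00_common.R")

d <- study_data()
X <- d$spectra
tr <- d$train

rows <- list()
for (trait in TRAITS) {
  y <- d$traits[[trait]]
  for (def in builtin_vis()) {
    vm <- fit_vi_model(compute_vi(X[tr, ], def), y[tr], def)
    ev <- evaluate_predictions(y[!tr],
                               predict_vi_model(vm, compute_vi(X[!tr, ], def)),
                               trait)
    rows[[paste(trait, def$name)]] <- data.frame(
      trait = trait, index = def$name,
      band1_nm = def$band1_nm, band2_nm = def$band2_nm,
      test_r2 = ev$r2, rpd = ev$rpd, category = ev$category)
  }
  bs <- exhaustive_band_search(X[tr, ], y[tr])
  vm <- fit_vi_model(compute_vi(X[tr, ], bs$best_definition), y[tr],
                     bs$best_definition)
  ev <- evaluate_predictions(
    y[!tr], predict_vi_model(vm, compute_vi(X[!tr, ], bs$best_definition)),
    trait)
  rows[[paste(trait, "best")]] <- data.frame(
    trait = trait, index = "best-pair",
    band1_nm = bs$best_definition$band1_nm,
    band2_nm = bs$best_definition$band2_nm,
    test_r2 = ev$r2, rpd = ev$rpd, category = ev$category)
  cat(sprintf("%-3s best pair %g/%g nm (train r %.3f) test R2 %.3f\n",
              trait, bs$best_definition$band2_nm, bs$best_definition$band1_nm,
              bs$train_correlation, ev$r2))
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(results_dir(), "vi_results.csv"), row.names = FALSE)
cat("wrote results/vi_results.csv\n")
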