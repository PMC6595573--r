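# Shared setup for the analysis scripts: one master seed drives the
# simulated study, the train/test split and the CV folds, so every script
# works on exactly the same data and split. Regenerating the dataset takes
# seconds, so no bulky intermediates are written to disk.

library(leafspec)

STUDY_SEED <- 2026

study_data <- function(seed = STUDY_SEED) {
  cfg <- synthetic_config(seed = derive_seed(seed, 1))
  ds <- generate_dataset(cfg)
  proc <- preprocess_spectra(average_replicates(ds$scans))
  ids <- rownames(proc)
  traits <- ds$traits[match(ids, ds$traits$sample_id), ]
  split <- train_test_split(ids, 0.6, derive_seed(seed, 2))
  list(config = cfg, scans = ds$scans, traits = traits, spectra = proc,
       train = ids %in% split$train,
       cv = cv_spec(10, derive_seed(seed, 3)))
}

results_dir <- function() {
  dir.create("results", showWarnings = FALSE)
  "results"
}

TRAITS <- c("CHL", "LWC", "SLA", "N", "P", "K")
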