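#!/usr/bin/env Rscript
# Preprocess the replicate-averaged spectra: trim the noisy 350-450 nm
# edge, Savitzky-Golay smooth (window 5, order 2), downsample to 5 nm.
# Writes the per-group mean processed spectra (the classic mean-reflectance
# figure as a table).

source("analysis/00_common.R")

d <- study_data()
proc <- d$spectra
cat(sprintf("processed spectra: %d samples x %d bands (%g-%g nm)\n",
            nrow(proc), ncol(proc), min(wavelengths(proc)),
            max(wavelengths(proc))))

groups <- d$traits$group
mean_by_group <- sapply(unique(groups), function(g)
  colMeans(proc[groups == g, , drop = FALSE]))
out <- data.frame(wavelength_nm = wavelengths(proc), mean_by_group,
                  check.names = FALSE)
write.csv(out, file.path(results_dir(), "mean_spectra_by_group.csv"),
          row.names = FALSE)

vis <- wavelengths(proc) <= 700
cat("mean VIS (450-700 nm) reflectance by group:",
    sprintf("%s %.3f", unique(groups),
            colMeans(mean_by_group[vis, , drop = FALSE])), "\n")
cat("wrote results/mean_spectra_by_group.csv\n")
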