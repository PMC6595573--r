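#!/usr/bin/env Rscript
# Principal component exploration of the processed spectra: how much
# spectral variance the leading components carry and how the three
# environment groups separate (partially) in the score plane.

source("analysis/00_common.R")

d <- study_data()
pc <- pca_scores(d$spectra, 2)
cat(sprintf("PC1 explains %.1f%% of spectral variance, PC2 %.1f%%\n",
            100 * pc$explained_variance[1], 100 * pc$explained_variance[2]))

scores <- data.frame(sample_id = rownames(d$spectra),
                     group = d$traits$group,
                     PC1 = pc$scores[, 1], PC2 = pc$scores[, 2])
write.csv(scores, file.path(results_dir(), "pca_scores.csv"),
          row.names = FALSE)
write.csv(data.frame(component = c("PC1", "PC2"),
                     variance_pct = 100 * pc$explained_variance),
          file.path(results_dir(), "pca_variance.csv"), row.names = FALSE)

ctr <- aggregate(cbind(PC1, PC2) ~ group, scores, mean)
print(ctr, row.names = FALSE)
cat("wrote results/pca_scores.csv, results/pca_variance.csv\n")
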