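#!/usr/bin/env Rscript
# Group-level contrasts on the cohort table: method-grid SNR comparison,
# contra-vs-ipsilateral lateralization, frequency specificity of the 2 and
# 4 Hz peaks, and cross-condition Spearman correlations (uncorrected, as
# flagged). Statistical tests are the delegated standard routines; this
# step assembles their inputs and writes the table-shaped summaries.

suppressPackageStartupMessages(library(ckcpipe))

tab <- read.csv("results/subject_table.csv")

## method x resolution x averaging SNR summary
sm <- snr_method_table(tab)
write.csv(sm$cells, "results/snr_method_cells.csv", row.names = FALSE)
cat("Marginal mean SNR (dB) by averaging strategy:\n")
print(round(sm$marginals$averaging, 2))
cat("by accelerometer summary:\n"); print(round(sm$marginals$accel_method, 2))
cat("by resolution (Hz):\n"); print(round(sm$marginals$resolution, 2))

## headline configuration for the remaining contrasts
best <- tab[tab$accel_method == "magnitude" & tab$averaging == "median" &
              tab$resolution == 0.5, ]

lat_rows <- list()
for (h in c("right", "left")) for (f in c(2, 4)) {
  lc <- lateralization_contrast(best, freq = f, hand = h)
  lat_rows[[length(lat_rows) + 1]] <- data.frame(
    hand = h, freq_hz = f, median_contra_minus_ipsi = lc$median_difference,
    shapiro_p = if (is.null(lc$shapiro)) NA else lc$shapiro$p.value,
    wilcoxon_v = unname(lc$wilcoxon$statistic),
    wilcoxon_p = lc$wilcoxon$p.value, direction = lc$direction)
}
lat <- do.call(rbind, lat_rows)
write.csv(lat, "results/lateralization.csv", row.names = FALSE)
cat("\nLateralization (contra - ipsi), Magnitude-Median @ 0.5 Hz:\n")
print(lat, digits = 3)

fs <- rbind(frequency_specificity(best, 2, c(1.5, 2.5)),
            frequency_specificity(best, 4, c(3.5, 4.5)))
write.csv(fs, "results/frequency_specificity.csv", row.names = FALSE)
cat("\nFrequency specificity (target minus neighbour):\n")
print(fs[, c("target_hz", "neighbor_hz", "mean_difference", "test_used",
             "t_p", "wilcoxon_p")], digits = 3)

cc <- condition_correlations(best)
write.csv(cc, "results/condition_correlations.csv", row.names = FALSE)
cat("\nCross-condition Spearman correlations (p uncorrected):\n")
print(cc, digits = 2)
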