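#!/usr/bin/env Rscript
# Per-state Welch spectra of the simulated cohort, the 1/f fit and the
# power-excess curves; demonstrates the beta-gamma peak downshift that a
# lower generator gamma peak produces (the SAMP8-vs-control contrast).

library(slowosc)

manifest <- read.csv(file.path("results", "manifest.csv"))
spec_dir <- file.path("results", "spectra")
dir.create(spec_dir, showWarnings = FALSE, recursive = TRUE)

# give the two strains distinguishable gamma peaks (control higher)
gamma_of <- c(SAMR1 = 50, SAMP8 = 35)

summary_rows <- NULL
for (i in seq_len(nrow(manifest))) {
  row <- manifest[i, ]
  p <- preset(row$preset, "frequency_matched", rate = row$rate,
              seed = row$seed)
  p$gamma_peak_hz <- gamma_of[[row$group]]
  sim <- synthesize_channel(p, row$duration_s)
  seg <- segment_states(compute_features(sim$rec))
  res <- lapply(c("Up", "Down"), function(st) {
    psd <- state_psd(sim$rec, 1, seg, st)
    fit <- fit_one_over_f(psd)
    ex <- power_excess(psd, fit)
    keep <- psd$freq >= 1 & psd$freq <= 100
    write.csv(data.frame(f = psd$freq[keep], psd = psd$power[keep],
                         fit = fit$fitted(psd$freq[keep]),
                         excess = ex$excess[match(psd$freq[keep], ex$freq)]),
              file.path(spec_dir, sprintf("%s_%s.csv", row$id, tolower(st))),
              row.names = FALSE)
    ex
  })
  summary_rows <- rbind(summary_rows, data.frame(
    id = row$id, group = row$group, age = row$age,
    gamma_true_hz = gamma_of[[row$group]],
    peak_hz_up = res[[1]]$peak_hz, peak_excess_up = res[[1]]$peak_excess))
  cat(sprintf("  %s (%s): Up-state excess peak %.1f Hz (true %g Hz)\n",
              row$id, row$group, res[[1]]$peak_hz, gamma_of[[row$group]]))
}
write.csv(summary_rows, file.path("results", "spectra_summary.csv"),
          row.names = FALSE)
agg <- aggregate(peak_hz_up ~ group, summary_rows, mean)
cat("mean Up-state excess peak by group:\n")
print(agg, row.names = FALSE)
cat("the SAMP8 peak sits below the control peak, the downshift signature\n")
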