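#!/usr/bin/env Rscript
# Group-level statistics over the cohort metric table: per-cell and
# pooled-area mean +/- SE, and independent-samples Student t-tests for
# the SAMP8-vs-control contrast at each age (raw p-values, no
# multiple-testing correction, mirroring the analysis convention).

library(slowosc)

metrics <- read_metrics(file.path("results", "metrics.csv"))
summary <- summarize_groups(metrics)
tests <- group_tests(metrics)

write.csv(summary, file.path("results", "summary.csv"), row.names = FALSE)
write.csv(tests, file.path("results", "tests.csv"), row.names = FALSE)

pooled <- summary[summary$area == "pooled", ]
for (mn in c("so_frequency", "down_duration", "up_duration", "cv_freq")) {
  sub <- pooled[pooled$metric_name == mn, ]
  cat(sprintf("%s:\n", mn))
  for (j in seq_len(nrow(sub)))
    cat(sprintf("  %s %s: %.3f +/- %.3f (n = %d)\n", sub$group[j],
                sub$age[j], sub$mean[j], sub$se[j], sub$n[j]))
}
cat("\ngroup contrasts (pooled areas, Student t):\n")
show <- tests[tests$metric_name %in%
              c("so_frequency", "down_duration", "cv_freq"), ]
for (j in seq_len(nrow(show)))
  cat(sprintf("  %s %s: t = %.2f, p = %.2g\n", show$age[j],
              show$metric_name[j], show$t[j], show$p[j]))
cat("\nnote: p-values are raw (no multiple-testing correction)\n")
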