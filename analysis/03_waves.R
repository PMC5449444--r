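#!/usr/bin/env Rscript
# Traveling-wave analysis on a 16-electrode array simulation: detect Up
# onsets per channel, group them into waves, cluster the lag patterns and
# estimate the weighted propagation speed, against known ground truth.

library(slowosc)

rate <- 10000
truth_speed <- 17.5   # mm/s, the control-group pooled speed at 7 months

p <- preset("SAMR1_7M", "frequency_matched", rate = rate, seed = 42)
arr <- array_params(n_channels = 16, spacing_mm = 0.1,
                    speed_mm_s = truth_speed, onset_jitter_s = 0.002)
sim <- synthesize_array(p, arr, 120)

onsets <- channel_onsets(sim$rec)
ws <- group_waves(onsets)
wc <- cluster_lags(ws, seed = 42)
sp <- propagation_speed(wc, sim$truth$positions_mm)

dir.create("results", showWarnings = FALSE)
clusters <- data.frame(
  cluster = seq_len(wc$k),
  n_waves = as.integer(round(wc$weights * nrow(ws$onset))),
  weight = wc$weights,
  speed_mm_s = sp$cluster_speeds)
write.csv(clusters, file.path("results", "waves.csv"), row.names = FALSE)
lag_tab <- data.frame(position_mm = sim$truth$positions_mm,
                      t(wc$mean_lags))
names(lag_tab)[-1] <- paste0("mean_lag_s_cluster", seq_len(wc$k))
write.csv(lag_tab, file.path("results", "wave_lags.csv"), row.names = FALSE)

cat(sprintf("grouped %d waves from 16 channels into %d lag clusters\n",
            nrow(ws$onset), wc$k))
cat(sprintf("weighted propagation speed %.2f mm/s (truth %.1f, error %+.1f%%)\n",
            sp$weighted_speed, truth_speed,
            100 * (sp$weighted_speed / truth_speed - 1)))
cat(sprintf("dominant direction: %s (lag-position slope sign %+d)\n",
            if (sp$direction_sign > 0) "anteroposterior" else "posteroanterior",
            sp$direction_sign))
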