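# construct per-channel onset lists from wave times and per-channel lags
onsets_from_waves <- function(wave_times, lag_per_channel, n_channels = 16) {
  lapply(seq_len(n_channels), function(c)
    wave_times + lag_per_channel[c])
}

test_that("group_waves recovers constructed waves and rejects partial ones", {
  # identical onsets on all 16 channels, 20 waves -> 20 waves, lags 0
  on <- onsets_from_waves(seq(1, 20), rep(0, 16))
  ws <- group_waves(on)
  expect_equal(nrow(ws$onset), 20)
  expect_true(all(abs(ws$lag) < 1e-12))
  # lags sum to zero per wave over participants
  expect_true(all(abs(rowSums(ws$lag, na.rm = TRUE)) < 1e-9))

  # an event present on only 9 channels is rejected
  on2 <- onsets_from_waves(seq(1, 15), rep(0, 16))
  for (c in 1:9) on2[[c]] <- sort(c(on2[[c]], 15.7))
  ws2 <- group_waves(on2)
  expect_equal(nrow(ws2$onset), 15)

  # 20 linear-lag waves + 5 isolated spurious onsets -> exactly 20 waves
  lag <- seq(0, 0.075, length.out = 16)
  on3 <- onsets_from_waves(seq(1, 20), lag)
  on3[[1]] <- sort(c(on3[[1]], c(1.5, 4.5, 9.5, 13.5, 17.5)))
  ws3 <- group_waves(on3)
  expect_equal(nrow(ws3$onset), 20)
  expect_equal(sum(!is.na(ws3$onset)), 20 * 16)

  expect_error(group_waves(onsets_from_waves(1:5, rep(0, 8), 8)),
               "at least 10")
})

test_that("cluster_lags separates constructed lag patterns deterministically", {
  # 3 waves with distinct patterns: k = min(5, n_waves) = 3 singletons
  la <- seq(0, 0.06, length.out = 16)
  pat <- rbind(la, -la, la * 0)
  on <- lapply(1:16, function(c) c(2, 6, 11) + pat[, c])
  ws <- group_waves(on)
  wc <- cluster_lags(ws, seed = 2)
  expect_equal(wc$k, 3)
  expect_equal(sort(as.numeric(table(wc$assignment))), c(1, 1, 1))

  # two opposite linear patterns, 50 waves each: never mixed in a cluster
  lag_f <- seq(-0.04, 0.04, length.out = 16)
  times <- seq(1, 300, length.out = 100)
  onsets <- lapply(1:16, function(c)
    sort(c(times[1:50] + lag_f[c], times[51:100] - lag_f[c])))
  ws2 <- group_waves(onsets)
  expect_equal(nrow(ws2$onset), 100)
  wc2 <- cluster_lags(ws2, seed = 3)
  truth_pattern <- ws2$lag[, 16] > 0          # sign of last-channel lag
  mix <- tapply(truth_pattern, wc2$assignment, function(v) min(mean(v), 1 - mean(v)))
  expect_true(all(mix == 0))
  # determinism
  wc2b <- cluster_lags(ws2, seed = 3)
  expect_identical(wc2$assignment, wc2b$assignment)

  # all-identical lags collapse to one effective cluster
  wc3 <- cluster_lags(group_waves(onsets_from_waves(1:20, rep(0, 16))),
                      seed = 4)
  expect_equal(wc3$k, 1)
})

test_that("propagation_speed implements the max-min lag rule with weights", {
  pos <- seq(0, 1.5, length.out = 16)
  mk_wc <- function(mean_lags, weights) {
    k <- nrow(mean_lags)
    structure(list(assignment = rep(seq_len(k), round(weights * 100)),
                   mean_lags = mean_lags,
                   sem_lags = mean_lags * 0, weights = weights, k = k),
              class = "wave_clusters")
  }
  # linear lags spanning 0.1 s over 1.5 mm -> 15 mm/s
  wc1 <- mk_wc(matrix(seq(0, 0.1, length.out = 16), 1), 1)
  expect_equal(propagation_speed(wc1, pos)$weighted_speed, 15)

  # speeds 10 and 20 mm/s with weights 0.75 / 0.25 -> 12.5 mm/s
  wc2 <- mk_wc(rbind(seq(0, 0.15, length.out = 16),
                     seq(0, 0.075, length.out = 16)), c(0.75, 0.25))
  expect_equal(propagation_speed(wc2, pos)$weighted_speed, 12.5)

  # zero-spread cluster excluded with renormalized weights + warning
  wc3 <- mk_wc(rbind(seq(0, 0.15, length.out = 16), rep(0.01, 16)),
               c(0.6, 0.4))
  expect_warning(sp3 <- propagation_speed(wc3, pos), "undefined")
  expect_equal(sp3$weighted_speed, 10)
  expect_equal(sp3$weights, 1)
})

test_that("speed is invariant to time translation and electrode reversal", {
  lag <- seq(0, 0.1, length.out = 16)
  pos <- seq(0, 1.5, length.out = 16)
  base <- group_waves(onsets_from_waves(seq(1, 30), lag))
  shifted <- group_waves(onsets_from_waves(seq(1, 30) + 123.4, lag))
  s1 <- propagation_speed(cluster_lags(base, seed = 1), pos)
  s2 <- propagation_speed(cluster_lags(shifted, seed = 1), pos)
  expect_equal(s1$weighted_speed, s2$weighted_speed, tolerance = 1e-9)

  rev_ws <- group_waves(onsets_from_waves(seq(1, 30), rev(lag)))
  s3 <- propagation_speed(cluster_lags(rev_ws, seed = 1), pos)
  expect_equal(s3$weighted_speed, s1$weighted_speed, tolerance = 1e-9)
  expect_equal(s3$direction_sign, -s1$direction_sign)
})

test_that("zero-jitter generator waves recover ground-truth speed to < 1%", {
  for (v in c(5, 50)) {
    p <- fast_params(seed = 17)
    arr <- array_params(speed_mm_s = v, onset_jitter_s = 0)
    sim <- synthesize_array(p, arr, 40)
    # onsets straight from ground truth (isolates the wave analysis)
    onsets <- lapply(1:16, function(c)
      sim$truth$cycle_table$up_start + sim$truth$lags[, c])
    ws <- group_waves(onsets)
    sp <- propagation_speed(cluster_lags(ws, seed = 18), sim$truth$positions_mm)
    expect_equal(sp$weighted_speed, v, tolerance = 0.01)
  }
})
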