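test_that("presets carry the printed pooled group means", {
  p <- preset("SAMP8_5M", "duration_matched")
  expect_equal(p$mean_down_s, 1.1)
  expect_equal(p$mean_up_s, 0.61)
  expect_equal(p$cycle_cv, 0.53)

  r1 <- preset("SAMR1_5M", "duration_matched")
  expect_equal(r1$mean_down_s, 0.71)
  expect_equal(r1$mean_up_s, 0.49)
  expect_equal(r1$cycle_cv, 0.40)

  expect_error(preset("SAMX_9M"), "unknown preset")
})

test_that("frequency-matched presets put the mean per-cycle frequency at the printed value", {
  # Monte-Carlo oracle: the expectation of 1/(up+down) must equal the
  # printed pooled frequency (the matching statistic), not 1/E[period]
  for (case in list(c("SAMR1_5M", 1.02), c("SAMP8_5M", 0.72),
                    c("SAMR1_7M", 0.91), c("SAMP8_7M", 0.77))) {
    p <- preset(case[1], "frequency_matched", seed = 99)
    d <- sample_state_durations(p, 2e5)
    f <- 1 / (d$up + d$down)
    expect_equal(mean(f), as.numeric(case[2]), tolerance = 0.01,
                 label = paste("E[1/T] for", case[1]))
    # Up:Down mean ratio preserved from the printed 5M durations
    base <- preset(sub("_7M", "_5M", case[1]), "duration_matched")
    expect_equal(p$mean_up_s / p$mean_down_s,
                 base$mean_up_s / base$mean_down_s, tolerance = 1e-6)
  }
})

test_that("duration sampling hits the requested means and frequency CV", {
  p <- generator_params(mean_up_s = 0.61, mean_down_s = 1.1,
                        cycle_cv = 0.53, seed = 11)
  d <- sample_state_durations(p, 10000)
  se <- sd(d$down) / sqrt(length(d$down))
  expect_lt(abs(mean(d$down) - 1.1), 3 * se)
  se_u <- sd(d$up) / sqrt(length(d$up))
  expect_lt(abs(mean(d$up) - 0.61), 3 * se_u)

  # empirical frequency CV within 5% of the target over >= 5000 cycles
  for (cv in c(0.3, 0.4, 0.53, 0.61)) {
    p <- generator_params(cycle_cv = cv, seed = 12)
    d <- sample_state_durations(p, 20000)
    f <- 1 / (d$up + d$down)
    expect_equal(sd(f) / mean(f), cv, tolerance = 0.05,
                 label = paste("empirical CV at target", cv))
  }
})

test_that("cycle_cv = 0 degenerates to exact constant durations", {
  p <- generator_params(mean_up_s = 0.5, mean_down_s = 0.7, cycle_cv = 0)
  d <- sample_state_durations(p, 50)
  expect_identical(d$up, rep(0.5, 50))
  expect_identical(d$down, rep(0.7, 50))
})

test_that("identical params and seed give bit-identical output", {
  p <- fast_params(seed = 5)
  a <- synthesize_channel(p, 20)
  b <- synthesize_channel(p, 20)
  expect_identical(a$rec$samples[[1]], b$rec$samples[[1]])
  expect_identical(a$truth$cycle_table, b$truth$cycle_table)

  d1 <- sample_state_durations(p, 100)
  d2 <- sample_state_durations(p, 100)
  expect_identical(d1, d2)
})

test_that("true Up samples carry more MUA-band power than Down samples", {
  # Welch oracle on truth-labelled samples, for any up_rate > down_rate
  sim <- synthesize_channel(fast_params(seed = 3), 40)
  x <- sim$rec$samples[[1]]
  band_power <- function(idx) {
    seg <- x[idx]
    sp <- Mod(fft(seg))^2 / length(seg)
    f <- (seq_along(seg) - 1) * 5000 / length(seg)
    mean(sp[f >= 200 & f <= 1500])
  }
  up_idx <- which(sim$truth$up)[1:50000]
  down_idx <- which(!sim$truth$up)[1:50000]
  expect_gt(band_power(up_idx), band_power(down_idx))

  # and the logMUA series is higher during true Up bins for every preset
  for (nm in c("SAMR1_5M", "SAMP8_5M")) {
    sim <- synthesize_channel(fast_preset(nm, seed = 4), 40)
    mua <- estimate_logmua(sim$rec)
    bin_n <- round(0.005 * 5000)
    nb <- length(mua$values)
    tu <- colMeans(matrix(sim$truth$up[1:(nb * bin_n)], nrow = bin_n)) > 0.5
    expect_gt(mean(mua$values[tu]), mean(mua$values[!tu]))
  }
})

test_that("null generator (no state contrast) yields a stationary signal", {
  p <- fast_params(up_rate_hz = 300, down_rate_hz = 300, slow_amp = 0,
                   gamma_amp = 0)
  sim <- synthesize_channel(p, 30)
  mua <- estimate_logmua(sim$rec)
  bin_n <- 25
  nb <- length(mua$values)
  tu <- colMeans(matrix(sim$truth$up[1:(nb * bin_n)], nrow = bin_n)) > 0.5
  # no separation between labelled classes
  expect_lt(abs(mean(mua$values[tu]) - mean(mua$values[!tu])), 0.05)
})

test_that("array lags follow geometry / speed arithmetic", {
  p <- fast_params(seed = 8)
  # speed 15 mm/s, spacing 0.1 mm, 16 channels: first-to-last lag 0.1 s
  arr <- array_params(n_channels = 16, spacing_mm = 0.1, speed_mm_s = 15,
                      onset_jitter_s = 0)
  sim <- synthesize_array(p, arr, 15)
  lag_span <- sim$truth$lags[, 16] - sim$truth$lags[, 1]
  expect_equal(unique(round(lag_span, 12)), 1.5 / 15)
  # zero jitter: lags exactly linear in position
  for (w in seq_len(nrow(sim$truth$lags))) {
    fit <- lm(sim$truth$lags[w, ] ~ sim$truth$positions_mm)
    expect_lt(max(abs(resid(fit))), 1e-12)
  }
  expect_error(array_params(speed_mm_s = 0), "speed")
  expect_error(array_params(speed_mm_s = -3), "speed")
})

test_that("too-short requests are refused", {
  p <- fast_params()
  expect_error(synthesize_channel(p, 5), "duration too short")
  expect_error(synthesize_array(p, array_params(), 5), "duration too short")
})
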