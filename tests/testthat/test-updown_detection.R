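test_that("so_envelope tracks slow structure and rejects fast content", {
  rate <- 1000
  z <- recording(numeric(20000), rate)
  expect_identical(so_envelope(z), numeric(20000 / 5))

  t <- seq(0, 20, length.out = 20000 + 1)[-1]
  sq <- sign(sin(2 * pi * 0.5 * t))
  x <- sq + 0.5 * sin(2 * pi * 40 * t)
  env <- so_envelope(recording(x, rate))
  sq_b <- slowosc:::bin_means(sq, 5)
  # tracks the square wave (up to detection-side sign orientation)
  expect_gt(abs(cor(env, sq_b)), 0.95)
  # 40 Hz content removed: spectral check on the output
  sp <- Mod(fft(env - mean(env)))^2
  f <- (seq_along(env) - 1) * 200 / length(env)
  p40 <- sum(sp[f >= 39 & f <= 41])
  p05 <- sum(sp[f >= 0.4 & f <= 0.6])
  expect_lt(p40, 1e-6 * p05)

  expect_error(so_envelope(recording(x, rate), cutoff_hz = 600), "Nyquist")
})

test_that("so_envelope is higher during true Up states (negative deflection input)", {
  sim <- synthesize_channel(fast_params(seed = 2), 40)
  env <- so_envelope(sim$rec)
  bin_n <- 25
  nb <- length(env)
  tu <- colMeans(matrix(sim$truth$up[1:(nb * bin_n)], nrow = bin_n)) > 0.5
  expect_gt(mean(env[tu]), mean(env[!tu]))
})

test_that("gamma variance envelope localizes band-limited power in time", {
  rate <- 1000
  expect_equal(gamma_variance_envelope(recording(numeric(5000), rate)),
               numeric(1000), tolerance = 1e-12)

  # 40 Hz tone of amplitude a on [1, 2] s: plateau ~ a^2 / 2
  a <- 2
  t <- seq(0, 3, length.out = 3000 + 1)[-1]
  x <- ifelse(t > 1 & t <= 2, a * sin(2 * pi * 40 * t), 0)
  v <- gamma_variance_envelope(recording(x, rate))
  ctr <- slowosc:::bin_centers(length(v))
  expect_equal(mean(v[ctr > 1.2 & ctr < 1.8]), a^2 / 2, tolerance = 0.05)
  expect_lt(mean(v[ctr < 0.8]), 0.01 * a^2 / 2)

  # 500 Hz tone is outside the 20-80 Hz band
  x5 <- sin(2 * pi * 500 * seq(0, 3, length.out = 6000 + 1)[-1])
  v5 <- gamma_variance_envelope(recording(x5, 2000))
  expect_lt(max(v5), 1e-4)

  expect_error(gamma_variance_envelope(recording(x, 100)), "twice")
})

test_that("PCA combination weights and orientation behave as eigenanalysis predicts", {
  set.seed(9)
  s <- rnorm(500)
  fs <- combine_features_pca(s, s, s)
  expect_equal(abs(fs$pca_weights), rep(1 / sqrt(3), 3), tolerance = 1e-10)
  expect_equal(abs(cor(fs$combined, s)), 1, tolerance = 1e-10)
  # oriented to correlate positively with the logMUA input
  expect_gt(cor(fs$combined, s), 0)

  # two state-modulated series + independent noise: noise weight smallest
  state <- rep(rep(c(0, 1), each = 50), 5)
  f1 <- state + rnorm(500, sd = 0.1)
  f2 <- 2 * state + rnorm(500, sd = 0.1)
  noise <- rnorm(500)
  fs2 <- combine_features_pca(f1, noise, f2)
  w <- abs(fs2$pca_weights)
  expect_lt(w[2], min(w[1], w[3]))

  # variance of the combined series equals the first eigenvalue of the
  # z-scored covariance (PCA identity, eigen oracle)
  z <- scale(cbind(f1, noise, f2))
  ev1 <- eigen(cov(z))$values[1]
  expect_equal(var(fs2$combined), ev1, tolerance = 1e-8)

  # degenerate feature: weight zero with a warning
  expect_warning(fs3 <- combine_features_pca(f1, rep(1, 500), f2),
                 "degenerate")
  expect_equal(fs3$pca_weights[2], 0)
})

test_that("segment_states finds exact boundaries of a clean two-level series", {
  # 40 cycles of 0.5 s Down / 0.5 s Up on the 5 ms grid
  combined <- rep(rep(c(-1, 1), each = 100), 40)
  seg <- segment_states(combined)
  expect_true(all(abs(seg$up[, 1] %% 1 - 0.5) < 1e-9))
  expect_true(all(seg$up[, 2] %% 1 < 1e-9))
  expect_equal(unname(seg$up[, 2] - seg$up[, 1]),
               rep(0.5, nrow(seg$up)))
  m <- so_metrics(seg)
  expect_equal(m$so_freq_hz, 1.0)
  expect_equal(m$cv_freq, 0)
})

test_that("stationary null signals raise 'no state alternation'", {
  set.seed(21)
  expect_error(segment_states(rnorm(8000)), "no state alternation")
  # full null-model pipeline: equal rates, no slow deflection, no gamma
  p <- fast_params(up_rate_hz = 300, down_rate_hz = 300, slow_amp = 0,
                   gamma_amp = 0, seed = 13)
  sim <- synthesize_channel(p, 30)
  fs <- compute_features(sim$rec)
  expect_error(segment_states(fs), "no state alternation")
})

test_that("detection agrees with generator ground truth", {
  p <- preset("SAMR1_5M", rate = 5000, seed = 1)
  sim <- synthesize_channel(p, 60)
  seg <- segment_states(compute_features(sim$rec))
  expect_gte(label_agreement(seg, sim$truth$up, 5000), 0.9)
})

test_that("segmentation is invariant to sign flip and affine rescaling", {
  sim <- synthesize_channel(fast_params(seed = 6), 40)
  x <- sim$rec$samples[[1]]
  seg1 <- segment_states(compute_features(sim$rec))
  rec2 <- recording(-2 * x + 5, 5000)
  seg2 <- segment_states(compute_features(rec2))
  expect_equal(seg1$cycles, seg2$cycles, tolerance = 1e-9)
})

test_that("so_metrics implements inverse-cycle frequency and frequency CV", {
  # periods 1 s and 3 s: frequencies {1, 1/3}
  seg <- manual_segmentation(down_start = c(0, 1), up_start = c(0.5, 3),
                             up_end = c(1, 4))
  m <- so_metrics(seg)
  expect_equal(m$so_freq_hz, mean(c(1, 1 / 3)), tolerance = 1e-12)
  expect_equal(m$cv_freq, sd(c(1, 1 / 3)) / mean(c(1, 1 / 3)),
               tolerance = 1e-12)
  expect_equal(m$cv_freq, 0.7071, tolerance = 1e-4)

  # printed-durations arithmetic: up 0.61, down 1.1 -> 1/1.71 Hz
  seg2 <- manual_segmentation(down_start = c(0, 1.71), up_start = c(1.1, 2.81),
                              up_end = c(1.71, 3.42))
  expect_equal(so_metrics(seg2)$so_freq_hz, 1 / 1.71, tolerance = 1e-9)

  expect_error(so_metrics(manual_segmentation(0, 0.5, 1)), "2 complete")
})

test_that("detected SO frequency decreases with generator Down duration", {
  freqs <- vapply(c(0.5, 0.9, 1.4), function(md) {
    p <- fast_params(mean_down_s = md, seed = 31)
    sim <- synthesize_channel(p, 50)
    seg <- segment_states(compute_features(sim$rec))
    so_metrics(seg)$so_freq_hz
  }, numeric(1))
  expect_true(all(diff(freqs) < 0))
})
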