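#' Generator parameters for synthetic LFP
#'
#' Parameters of the surrogate slow-oscillation model: alternating Up and
#' Down states with gamma-distributed durations, an Up-state slow LFP
#' deflection (negative, the deep-layer convention), an Up-state gamma
#' oscillation, a Poisson unit-event train driving the 200-1500 Hz
#' "spiking" band, and a 1/f background.
#'
#' @param mean_up_s,mean_down_s Mean Up/Down state durations (s).
#' @param cycle_cv Target coefficient of variation of the per-cycle
#'   frequency 1/(up+down) (dimensionless, >= 0).
#' @param up_rate_hz,down_rate_hz Poisson unit-event rates during Up and
#'   Down states (events/s).
#' @param gamma_peak_hz Centre frequency of the Up-state gamma
#'   oscillation (Hz, must be below Nyquist).
#' @param gamma_amp,slow_amp,mua_amp,noise_1f_amp Component amplitudes
#'   (arbitrary units): gamma oscillation, Up-state slow deflection,
#'   unit-event kernel, and 1/f background scale.
#' @param rate Sampling frequency (Hz). 20 kHz mirrors the acquisition
#'   convention; lower rates (>= 5 kHz, so the 1500 Hz band exists) are
#'   allowed for faster runs.
#' @param seed Integer RNG seed.
#' @return A `generator_params` list.
#' @export
generator_params <- function(mean_up_s = 0.5, mean_down_s = 0.7,
                             cycle_cv = 0.4,
                             up_rate_hz = 1500, down_rate_hz = 150,
                             gamma_peak_hz = 40, gamma_amp = 0.3,
                             slow_amp = 1, mua_amp = 0.5,
                             noise_1f_amp = 0.3,
                             rate = 20000, seed = 1L) {
  stopifnot(mean_up_s > 0, mean_down_s > 0, cycle_cv >= 0,
            up_rate_hz >= 0, down_rate_hz >= 0,
            gamma_peak_hz < rate / 2, rate > 0)
  structure(
    list(mean_up_s = mean_up_s, mean_down_s = mean_down_s,
         cycle_cv = cycle_cv, up_rate_hz = up_rate_hz,
         down_rate_hz = down_rate_hz, gamma_peak_hz = gamma_peak_hz,
         gamma_amp = gamma_amp, slow_amp = slow_amp, mua_amp = mua_amp,
         noise_1f_amp = noise_1f_amp, rate = rate, seed = as.integer(seed)),
    class = "generator_params"
  )
}

#' Array geometry and propagation parameters
#'
#' @param n_channels Number of contacts (default 16).
#' @param spacing_mm Inter-electrode distance (default 0.1 mm).
#' @param speed_mm_s Ground-truth propagation speed (mm/s).
#' @param onset_jitter_s Per-channel, per-wave Gaussian lag noise SD (s).
#' @param origin `"first_channel"` (anterior origin; onsets propagate
#'   towards increasing position) or `"last_channel"`.
#' @return An `array_params` list.
#' @export
array_params <- function(n_channels = 16L, spacing_mm = 0.1,
                         speed_mm_s = 15, onset_jitter_s = 0.002,
                         origin = c("first_channel", "last_channel")) {
  origin <- match.arg(origin)
  stopifnot(n_channels >= 2L, spacing_mm > 0)
  if (speed_mm_s <= 0) stop("speed_mm_s must be > 0", call. = FALSE)
  structure(
    list(n_channels = as.integer(n_channels), spacing_mm = spacing_mm,
         speed_mm_s = speed_mm_s, onset_jitter_s = onset_jitter_s,
         origin = origin),
    class = "array_params"
  )
}

# Pooled group means printed in the source study: SO frequency (Hz), Down
# and Up durations (s, printed at 5 months only) and cycle-frequency CV.
.preset_table <- function() {
  data.frame(
    name = c("SAMR1_5M", "SAMP8_5M", "SAMR1_7M", "SAMP8_7M"),
    so_freq_hz = c(1.02, 0.72, 0.91, 0.77),
    mean_down_s = c(0.71, 1.10, NA, NA),
    mean_up_s = c(0.49, 0.61, NA, NA),
    cycle_cv = c(0.40, 0.53, 0.48, 0.61),
    stringsAsFactors = FALSE
  )
}

# E[T^-s] for T = U + D, U ~ Gamma(k, scale thU), D ~ Gamma(k, scale thD),
# via the Laplace-transform identity
#   E[T^-s] = 1/Gamma(s) * Int_0^inf t^(s-1) (1+thU t)^-k (1+thD t)^-k dt
.inv_moment <- function(s, k, thU, thD) {
  f <- function(t) t^(s - 1) * exp(-k * (log1p(thU * t) + log1p(thD * t)))
  stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value / gamma(s)
}

# CV of the per-cycle frequency 1/T given common shape k and Up:Down mean
# ratio rho (scale-invariant, so computed with mean_down = 1)
.freq_cv_of_shape <- function(k, rho) {
  thU <- rho / k
  thD <- 1 / k
  m1 <- .inv_moment(1, k, thU, thD)
  m2 <- .inv_moment(2, k, thU, thD)
  sqrt(pmax(m2 / m1^2 - 1, 0))
}

# numeric tuning: common gamma shape k such that CV(1/(U+D)) = cv
.tune_shape <- function(cv, rho) {
  if (cv <= 0) return(Inf)
  g <- function(logk) .freq_cv_of_shape(exp(logk), rho) - cv
  lo <- log(1.05); hi <- log(5e5)
  if (g(lo) < 0)
    stop("parameter error: cycle_cv = ", cv,
         " is not attainable by the gamma duration family", call. = FALSE)
  if (g(hi) > 0) return(exp(hi))
  exp(stats::uniroot(g, c(lo, hi), tol = 1e-10)$root)
}

#' Generator presets from the study's printed pooled group means
#'
#' Each mouse-group x age cell has two variants. `duration_matched`
#' presets set the mean Up/Down durations to the printed pooled means
#' (available at 5 months; at 7 months durations are derived from the
#' printed pooled frequency keeping the group's 5-month Up:Down ratio).
#' `frequency_matched` presets scale the period distribution so that the
#' expected per-cycle frequency E[1/(up+down)] equals the printed pooled
#' SO frequency, keeping the printed Up:Down mean-duration ratio. The
#' cycle-frequency CV is set to the printed group CV in both variants.
#'
#' @param name One of `"SAMR1_5M"`, `"SAMP8_5M"`, `"SAMR1_7M"`,
#'   `"SAMP8_7M"`.
#' @param matching `"duration_matched"` or `"frequency_matched"`.
#' @param ... Further arguments passed to [generator_params()] (e.g.
#'   `rate`, `seed`).
#' @return A [generator_params()] object.
#' @export
preset <- function(name, matching = c("duration_matched", "frequency_matched"),
                   ...) {
  matching <- match.arg(matching)
  tab <- .preset_table()
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1L) stop("unknown preset name: ", name, call. = FALSE)
  # Up:Down mean ratio; 7M rows inherit their group's printed 5M ratio
  base <- if (is.na(row$mean_up_s)) {
    grp <- sub("_7M$", "_5M", row$name)
    tab[tab$name == grp, ]
  } else row
  rho <- base$mean_up_s / base$mean_down_s
  use_durations <- matching == "duration_matched" && !is.na(row$mean_up_s)
  if (use_durations) {
    mu <- row$mean_up_s
    md <- row$mean_down_s
  } else {
    # scale so that E[1/T] equals the printed pooled frequency
    k <- .tune_shape(row$cycle_cv, rho)
    m1 <- if (is.finite(k)) .inv_moment(1, k, rho / k, 1 / k) else 1 / (1 + rho)
    md <- m1 / row$so_freq_hz
    mu <- rho * md
  }
  generator_params(mean_up_s = mu, mean_down_s = md,
                   cycle_cv = row$cycle_cv, ...)
}

#' Draw Up/Down state duration sequences
#'
#' Up and Down durations are independent gamma variates with means
#' `mean_up_s` / `mean_down_s` and a common shape parameter tuned
#' numerically so that the CV of the per-cycle frequency 1/(up+down)
#' equals `cycle_cv` in expectation. `cycle_cv = 0` degenerates to exact
#' constant durations.
#'
#' @param params A [generator_params()].
#' @param n_cycles Number of cycles (>= 1).
#' @param use_seed Set `params$seed` before drawing (default `TRUE`;
#'   internal callers that manage the RNG pass `FALSE`).
#' @return A list with numeric vectors `up` and `down` (seconds).
#' @export
sample_state_durations <- function(params, n_cycles, use_seed = TRUE) {
  stopifnot(inherits(params, "generator_params"), n_cycles >= 1)
  if (use_seed) set.seed(params$seed)
  if (params$cycle_cv <= 0) {
    return(list(up = rep(params$mean_up_s, n_cycles),
                down = rep(params$mean_down_s, n_cycles)))
  }
  rho <- params$mean_up_s / params$mean_down_s
  k <- .tune_shape(params$cycle_cv, rho)
  list(up = stats::rgamma(n_cycles, shape = k, scale = params$mean_up_s / k),
       down = stats::rgamma(n_cycles, shape = k, scale = params$mean_down_s / k))
}

# raised-cosine gating envelope: 1 inside each [a, b) interval with
# half-Hann ramps of ramp_n samples at the edges (0-based sample indices)
.gate_envelope <- function(n, starts, ends, ramp_n) {
  env <- numeric(n)
  for (i in seq_along(starts)) {
    a <- starts[i]; b <- ends[i]
    if (a >= n || b <= 1) next
    a <- max(a, 0L); b <- min(b, n)
    len <- b - a
    if (len <= 0) next
    r <- min(ramp_n, len %/% 2L)
    seg <- rep(1, len)
    if (r > 0) {
      ramp <- 0.5 * (1 - cos(pi * seq_len(r) / (r + 1)))
      seg[seq_len(r)] <- ramp
      seg[len - r + seq_len(r)] <- rev(ramp)
    }
    env[(a + 1):b] <- seg
  }
  env
}

# 1/f (power exponent 1) background via spectral shaping of white noise,
# unit variance before scaling; FFT length padded to a composite size
.noise_1f <- function(n, rate) {
  m <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(m)
  W <- stats::fft(w)
  f <- seq(0, rate, length.out = m + 1)[1:m]
  f[f > rate / 2] <- rate - f[f > rate / 2]  # two-sided frequency axis
  shape <- 1 / sqrt(pmax(f, 0.1))            # amplitude ~ f^-1/2
  shape[1] <- 0                              # drop DC
  x <- Re(stats::fft(W * shape, inverse = TRUE))[1:n] / m
  x / stats::sd(x)
}

# Poisson unit-event train convolved with a 1 ms biphasic kernel
# (padded FFT convolution; stats::convolve can hit prime-length FFTs)
.mua_train <- function(n, rate, p_event) {
  ev <- stats::rbinom(n, 1L, pmin(p_event, 1)) *
    stats::rgamma(n, shape = 2, scale = 0.5)   # amplitude jitter, mean 1
  kn <- max(4L, round(0.001 * rate))
  kern <- sin(2 * pi * seq(0, kn - 1) / kn)    # one biphasic cycle, 1 ms
  m <- stats::nextn(n + kn, c(2, 3, 5))
  out <- Re(stats::fft(stats::fft(c(ev, numeric(m - n))) *
                       stats::fft(c(kern, numeric(m - kn))),
                       inverse = TRUE)) / m
  out[pmin(seq_len(n) + (kn %/% 2L), m)]
}

# shared synthesis of one channel given explicit up intervals (seconds)
.render_channel <- function(up_start, up_end, duration_s, params) {
  rate <- params$rate
  n <- round(duration_s * rate)
  a <- pmax(round(up_start * rate), 0)
  b <- pmin(round(up_end * rate), n)
  keep <- b > a
  a <- a[keep]; b <- b[keep]
  ramp_n <- max(2L, round(0.02 * rate))       # 20 ms transition ramps
  env <- .gate_envelope(n, a, b, ramp_n)
  x <- -params$slow_amp * env
  # Up-state gamma oscillation, random phase per state
  if (params$gamma_amp > 0) {
    tt <- seq_len(n) / rate
    for (i in seq_along(a)) {
      idx <- (a[i] + 1):b[i]
      ph <- stats::runif(1, 0, 2 * pi)
      x[idx] <- x[idx] + params$gamma_amp * env[idx] *
        sin(2 * pi * params$gamma_peak_hz * tt[idx] + ph)
    }
  }
  # unit events: state-dependent Poisson rate
  lab <- rep(FALSE, n)
  for (i in seq_along(a)) lab[(a[i] + 1):b[i]] <- TRUE
  p <- ifelse(lab, params$up_rate_hz, params$down_rate_hz) / rate
  x <- x + params$mua_amp * .mua_train(n, rate, p)
  x <- x + params$noise_1f_amp * .noise_1f(n, rate)
  list(x = quantize_f32(x), labels = lab)
}

# build the cycle skeleton covering duration_s; first Down starts at 0
.cycle_skeleton <- function(params, duration_s) {
  mean_cycle <- params$mean_up_s + params$mean_down_s
  n_cycles <- ceiling(duration_s / mean_cycle * 1.5) + 10L
  dur <- sample_state_durations(params, n_cycles, use_seed = FALSE)
  down_start <- cumsum(c(0, dur$up + dur$down))[seq_len(n_cycles)]
  up_start <- down_start + dur$down
  up_end <- up_start + dur$up
  keep <- up_end <= duration_s
  data.frame(down_start = down_start[keep], up_start = up_start[keep],
             up_end = up_end[keep])
}

#' Synthesize a single-channel LFP with ground truth
#'
#' @param params A [generator_params()].
#' @param duration_s Signal length in seconds; must be at least 10 mean
#'   cycles.
#' @return A list with `rec` (a [recording()], float32-quantized) and
#'   `truth` (per-sample logical `up` labels, the `cycle_table` of
#'   complete cycles, and a `params` echo).
#' @export
synthesize_channel <- function(params, duration_s) {
  stopifnot(inherits(params, "generator_params"))
  mean_cycle <- params$mean_up_s + params$mean_down_s
  if (duration_s < 10 * mean_cycle)
    stop("duration too short: need at least 10 mean cycles (",
         signif(10 * mean_cycle, 3), " s)", call. = FALSE)
  set.seed(params$seed)
  cyc <- .cycle_skeleton(params, duration_s)
  ch <- .render_channel(cyc$up_start, cyc$up_end, duration_s, params)
  rec <- recording(list(ch$x), rate = params$rate,
                   channels = list(channel_meta("sim01", "synthetic")))
  list(rec = rec,
       truth = list(up = ch$labels, cycle_table = cyc, params = params))
}

#' Synthesize a multichannel array recording with traveling waves
#'
#' All channels share one cycle skeleton; channel `c`'s Up onsets (and
#' offsets) are delayed by `position_c / speed_mm_s` plus Gaussian jitter,
#' implementing an anteroposterior traveling wave along the array.
#' Background noise, gamma phases and unit events are independent across
#' channels.
#'
#' @param params A [generator_params()].
#' @param arr An [array_params()].
#' @param duration_s Signal length in seconds.
#' @return A list with `rec` (n-channel [recording()] with strictly
#'   increasing `position_mm`) and `truth` (`cycle_table` of the reference
#'   skeleton, `lags` matrix of exact per-wave, per-channel onset lags in
#'   seconds, per-channel label list `up`, and parameter echoes).
#' @export
synthesize_array <- function(params, arr, duration_s) {
  stopifnot(inherits(params, "generator_params"), inherits(arr, "array_params"))
  mean_cycle <- params$mean_up_s + params$mean_down_s
  if (duration_s < 10 * mean_cycle)
    stop("duration too short: need at least 10 mean cycles", call. = FALSE)
  set.seed(params$seed)
  cyc <- .cycle_skeleton(params, duration_s)
  nw <- nrow(cyc)
  nc <- arr$n_channels
  pos <- (seq_len(nc) - 1L) * arr$spacing_mm
  base_lag <- if (arr$origin == "first_channel") pos / arr$speed_mm_s
              else (max(pos) - pos) / arr$speed_mm_s
  lags <- matrix(rep(base_lag, each = nw), nrow = nw) +
    matrix(stats::rnorm(nw * nc, 0, arr$onset_jitter_s), nrow = nw)
  chans <- vector("list", nc)
  labels <- vector("list", nc)
  for (c in seq_len(nc)) {
    us <- cyc$up_start + lags[, c]
    ue <- cyc$up_end + lags[, c]
    # keep shifted states disjoint (jitter can only violate this for
    # pathologically short Down states)
    if (nw > 1L) {
      for (i in 2:nw) if (us[i] < ue[i - 1] + 0.005) us[i] <- ue[i - 1] + 0.005
    }
    ch <- .render_channel(us, ue, duration_s, params)
    chans[[c]] <- ch$x
    labels[[c]] <- ch$labels
  }
  meta <- lapply(seq_len(nc), function(c)
    channel_meta(sprintf("arr%02d", c), "synthetic", position_mm = pos[c]))
  rec <- recording(chans, rate = params$rate, channels = meta)
  list(rec = rec,
       truth = list(cycle_table = cyc, lags = lags, up = labels,
                    positions_mm = pos, params = params, array = arr))
}
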