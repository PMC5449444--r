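# The three Up-state fingerprints: slow-oscillation envelope, gamma-band
# variance envelope, and logMUA. All are computed on a common 5 ms grid
# so that they can be combined by PCA.

FEATURE_BIN_S <- 0.005

# crude high-frequency activity proxy used only to orient the slow
# envelope so that Up deflections come out positive (sign-agnostic
# detection); falls back to the deep-layer convention (Up = negative
# LFP deflection) when no high band exists or correlation is negligible.
.activity_proxy <- function(x, rate, bin_n) {
  hp_lo <- min(100, 0.35 * rate)
  hf <- fft_bandpass(x, rate, lo = hp_lo, hi = Inf, transition = hp_lo * 0.2)
  bin_means(hf^2, bin_n)
}

#' Slow-oscillation envelope
#'
#' Low-pass filters the LFP (zero-phase, default cutoff 2 Hz), orients it
#' so that the Up-state deflection is positive, and resamples it onto the
#' 5 ms feature grid. Orientation is decided by correlating the slow
#' component with high-frequency signal power; if that correlation is
#' negligible the deep-layer convention (Up = negative deflection, so the
#' trace is sign-flipped) is used.
#'
#' @param rec A [recording()].
#' @param channel Channel index (default 1).
#' @param cutoff_hz Low-pass cutoff (Hz), must be below Nyquist.
#' @return Numeric series on the 5 ms grid.
#' @export
so_envelope <- function(rec, channel = 1L, cutoff_hz = 2) {
  stopifnot(inherits(rec, "recording"))
  if (rec$rate < 200) stop("rate must be >= 200 Hz", call. = FALSE)
  if (cutoff_hz >= rec$rate / 2)
    stop("cutoff at or above Nyquist", call. = FALSE)
  x <- rec$samples[[channel]]
  bin_n <- max(1L, round(FEATURE_BIN_S * rec$rate))
  # bin first, then low-pass on the 5 ms grid: equivalent to filtering at
  # the native rate for a 2 Hz corner, and numerically much better behaved
  xb <- bin_means(x, bin_n)
  grid_rate <- rec$rate / bin_n
  slow <- fft_bandpass(xb, grid_rate, lo = 0, hi = cutoff_hz,
                       transition = cutoff_hz / 2)
  if (stats::sd(slow) == 0) return(slow)
  proxy <- .activity_proxy(x, rec$rate, bin_n)
  m <- min(length(slow), length(proxy))
  r <- suppressWarnings(stats::cor(slow[1:m], proxy[1:m]))
  s <- if (is.na(r) || abs(r) < 0.05) -1 else sign(r)
  s * slow
}

#' Gamma-band variance envelope
#'
#' Band-pass filters the LFP in the gamma band (zero-phase, default
#' 20-80 Hz), takes the moving variance in 5 ms bins and smooths it with
#' a moving average (default 50 ms). Elevated values flag Up states
#' (Mukovski-style fingerprint).
#'
#' @param rec A [recording()].
#' @param channel Channel index.
#' @param band Two-element numeric, gamma band in Hz.
#' @param smooth_s Moving-average smoothing span (s).
#' @return Numeric series on the 5 ms grid.
#' @export
gamma_variance_envelope <- function(rec, channel = 1L, band = c(20, 80),
                                    smooth_s = 0.05) {
  stopifnot(inherits(rec, "recording"), length(band) == 2L, band[1] < band[2])
  if (rec$rate < 2 * band[2])
    stop("rate must be at least twice the gamma band top", call. = FALSE)
  x <- rec$samples[[channel]]
  g <- fft_bandpass(x, rec$rate, lo = band[1], hi = band[2],
                    transition = band[1] * 0.25)
  bin_n <- max(1L, round(FEATURE_BIN_S * rec$rate))
  v <- bin_means(g^2, bin_n)   # per-bin variance (band-passed, zero-mean)
  moving_average(v, round(smooth_s / FEATURE_BIN_S))
}

#' Combine the three fingerprints by PCA weighting
#'
#' Z-scores the slow-oscillation envelope, the gamma variance envelope
#' and the logMUA series, runs PCA on the three-column matrix, and takes
#' the projection on the first principal component as the combined
#' detection series, oriented to correlate positively with logMUA. A
#' constant (degenerate) feature gets weight 0 with a warning. Weights
#' are unit-norm.
#'
#' @param so_env,gamma_var Numeric series from [so_envelope()] and
#'   [gamma_variance_envelope()].
#' @param logmua A [logmua_series()] (or its numeric values) from
#'   [estimate_logmua()].
#' @return A `feature_set` list: `so_env`, `gamma_var`, `logmua` (the
#'   z-scored inputs), `pca_weights` (3 loadings, unit norm), `combined`,
#'   `bin_s`.
#' @export
combine_features_pca <- function(so_env, gamma_var, logmua) {
  if (inherits(logmua, "logmua_series")) logmua <- logmua$values
  n <- min(length(so_env), length(gamma_var), length(logmua))
  if (n < 3L) stop("series too short", call. = FALSE)
  mat <- cbind(so_env = so_env[1:n], gamma_var = gamma_var[1:n],
               logmua = logmua[1:n])
  sds <- apply(mat, 2, stats::sd)
  dead <- sds == 0
  if (all(dead)) stop("degenerate features: all series constant", call. = FALSE)
  if (any(dead))
    warning("degenerate feature(s) with zero variance: ",
            paste(colnames(mat)[dead], collapse = ", "),
            "; weight set to 0")
  z <- mat
  z[, !dead] <- scale(mat[, !dead, drop = FALSE])
  z[, dead] <- 0
  pc <- stats::prcomp(z[, !dead, drop = FALSE], center = FALSE, scale. = FALSE)
  w <- numeric(3L)
  w[!dead] <- pc$rotation[, 1L]
  combined <- as.numeric(z %*% w)
  # orient so the combined series correlates positively with logMUA
  # (or with the first live feature if logMUA itself is degenerate)
  ref <- if (!dead[3L]) z[, 3L] else z[, which(!dead)[1L]]
  if (stats::cor(combined, ref) < 0) {
    w <- -w
    combined <- -combined
  }
  structure(
    list(so_env = z[, 1L], gamma_var = z[, 2L], logmua = z[, 3L],
         pca_weights = w / sqrt(sum(w^2)), combined = combined,
         bin_s = FEATURE_BIN_S),
    class = "feature_set"
  )
}

#' Compute the full feature set of a recording channel
#'
#' Convenience wrapper running [so_envelope()],
#' [gamma_variance_envelope()] and [estimate_logmua()] and combining them
#' with [combine_features_pca()].
#'
#' @param rec A [recording()].
#' @param channel Channel index.
#' @param so_cutoff_hz,gamma_band Feature parameters.
#' @return A `feature_set`.
#' @export
compute_features <- function(rec, channel = 1L, so_cutoff_hz = 2,
                             gamma_band = c(20, 80)) {
  so <- so_envelope(rec, channel, so_cutoff_hz)
  gv <- gamma_variance_envelope(rec, channel, gamma_band)
  mua <- estimate_logmua(rec, channel)
  combine_features_pca(so, gv, mua)
}
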