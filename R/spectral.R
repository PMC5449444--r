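# Per-state Welch spectra, aperiodic (1/f) fit, and power-excess peak.

# one-sided Welch PSD over a set of [start, end) sample-index segments
.welch_segments <- function(x, rate, seg_idx, window_n, overlap = 0.5) {
  hop <- max(1L, round(window_n * (1 - overlap)))
  w <- 0.5 * (1 - cos(2 * pi * seq_len(window_n) / (window_n + 1)))  # Hann
  norm <- rate * sum(w^2)
  starts <- integer(0)
  for (i in seq_len(nrow(seg_idx))) {
    a <- seg_idx[i, 1L]; b <- seg_idx[i, 2L]
    if (b - a < window_n) next
    starts <- c(starts, seq(a, b - window_n, by = hop))
  }
  if (!length(starts)) return(NULL)
  m <- vapply(starts, function(s) x[(s + 1L):(s + window_n)] * w,
              numeric(window_n))
  sp <- stats::mvfft(m)
  nf <- window_n %/% 2L + 1L
  pow <- rowMeans(abs(sp[seq_len(nf), , drop = FALSE])^2) / norm
  pow[2:(nf - 1L)] <- 2 * pow[2:(nf - 1L)]  # one-sided doubling
  list(freq = (seq_len(nf) - 1L) * rate / window_n, power = pow,
       n_windows = length(starts))
}

#' Per-state Welch power spectral density
#'
#' Welch PSD with Hann-tapered windows of `window_n` samples and 50%
#' overlap, where windows are drawn only from within segments of the
#' requested state; segments shorter than one window are skipped and the
#' periodograms of all windows are averaged. The PSD is one-sided and
#' density-scaled (integral approximates the within-state variance).
#'
#' @param rec A [recording()].
#' @param channel Channel index.
#' @param seg A `state_segmentation` (or `NULL` with `state = "all"` to
#'   use the whole signal).
#' @param state `"Up"`, `"Down"`, or `"all"`.
#' @param window_n Window length in samples (default 5000 at the native
#'   rate).
#' @return A `state_psd` object: `freq` (Hz), `power` (a.u.^2/Hz), `df`,
#'   `state`, `n_windows`.
#' @export
state_psd <- function(rec, channel = 1L, seg = NULL,
                      state = c("Up", "Down", "all"), window_n = 5000L) {
  state <- match.arg(state)
  stopifnot(inherits(rec, "recording"))
  x <- rec$samples[[channel]]
  if (state == "all") {
    iv <- cbind(0L, length(x))
  } else {
    stopifnot(inherits(seg, "state_segmentation"))
    sec <- if (state == "Up") seg$up else seg$down
    iv <- cbind(round(sec[, 1L] * rec$rate), round(sec[, 2L] * rec$rate))
  }
  res <- .welch_segments(x, rec$rate, iv, window_n)
  if (is.null(res))
    stop("no ", state, " segment of at least ", window_n,
         " samples (", signif(window_n / rec$rate, 3), " s)", call. = FALSE)
  structure(list(freq = res$freq, power = res$power,
                 df = rec$rate / window_n, state = state,
                 n_windows = res$n_windows),
            class = "state_psd")
}

#' @export
print.state_psd <- function(x, ...) {
  cat(sprintf("<state_psd> %s: %d bins (df = %g Hz) from %d windows\n",
              x$state, length(x$freq), x$df, x$n_windows))
  invisible(x)
}

#' Fit the aperiodic 1/f decay of a power spectrum
#'
#' Linear regression of log power on log frequency over `fit_band`
#' (default 5-100 Hz), with iterative exclusion of bins more than 2
#' residual SD above the fit (two passes) so that oscillatory peaks do
#' not bias the aperiodic component. Model: `P(f) = A / f^alpha`.
#'
#' @param psd A `state_psd`, or a list with `freq` and `power`.
#' @param fit_band Two-element numeric (Hz), must exclude 0.
#' @param alpha Optional fixed exponent (e.g. 1 for a strict 1/f fit);
#'   default `NULL` estimates it.
#' @return A `one_over_f_fit`: `A`, `alpha`, `fitted(f)` function,
#'   `fit_band`, `n_used`.
#' @export
fit_one_over_f <- function(psd, fit_band = c(5, 100), alpha = NULL) {
  f <- psd$freq; p <- psd$power
  sel <- which(f >= fit_band[1] & f <= fit_band[2] & f > 0 & p > 0)
  if (length(sel) < 5L)
    stop("fewer than 5 usable bins in the fit band", call. = FALSE)
  lx <- log(f[sel]); ly <- log(p[sel])
  use <- rep(TRUE, length(sel))
  for (pass in 1:2) {
    if (is.null(alpha)) {
      co <- stats::coef(stats::lm(ly[use] ~ lx[use]))
      a0 <- co[1L]; slope <- co[2L]
    } else {
      slope <- -alpha
      a0 <- mean(ly[use] - slope * lx[use])
    }
    resid <- ly - (a0 + slope * lx)
    s <- stats::sd(resid[use])
    if (s == 0) break
    use <- resid <= 2 * s          # drop bins sticking out above the fit
    if (sum(use) < 5L) { use <- rep(TRUE, length(sel)); break }
  }
  A <- exp(unname(a0))
  alpha_hat <- -unname(slope)
  structure(list(A = A, alpha = alpha_hat,
                 fitted = function(f) A / f^alpha_hat,
                 fit_band = fit_band, n_used = sum(use)),
            class = "one_over_f_fit")
}

#' Power excess over the 1/f decay
#'
#' The power ratio between the measured PSD and the fitted aperiodic
#' decay, and the frequency of its maximum within a search band
#' (default 10-90 Hz, the beta-gamma focus). A spectrum
#' indistinguishable from its 1/f fit (relative excess range below
#' `flat_tol`) is flagged flat and the lower band edge returned.
#'
#' @param psd A `state_psd` (or compatible list).
#' @param fit A `one_over_f_fit`.
#' @param search_band Two-element numeric (Hz).
#' @param flat_tol Relative excess range below which the curve is
#'   considered flat (default 1e-3).
#' @return A `power_excess` object: `freq`, `excess`, `peak_hz`,
#'   `peak_excess`, `flat`.
#' @export
power_excess <- function(psd, fit, search_band = c(10, 90),
                         flat_tol = 1e-3) {
  stopifnot(inherits(fit, "one_over_f_fit"))
  f <- psd$freq; p <- psd$power
  keep <- f > 0
  f <- f[keep]; p <- p[keep]
  excess <- p / fit$fitted(f)
  sel <- which(f >= search_band[1] & f <= search_band[2])
  if (!length(sel)) stop("empty search band", call. = FALSE)
  ex <- excess[sel]
  flat <- (max(ex) - min(ex)) / max(ex) < flat_tol
  peak_i <- if (flat) sel[1L] else sel[which.max(ex)]
  structure(list(freq = f, excess = excess,
                 peak_hz = f[peak_i], peak_excess = excess[peak_i],
                 flat = flat),
            class = "power_excess")
}
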