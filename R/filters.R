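# Zero-phase frequency-domain filtering and time-grid helpers.
#
# Whole-trace FFT masks with raised-cosine transition edges are used
# instead of IIR designs: the analysis needs corner frequencies down to
# 2 Hz on signals sampled at 10-20 kHz, where normalized IIR corners
# (~1e-4) are numerically fragile, while an FFT mask is exactly
# zero-phase and stable at any corner.

# band-pass x between lo and hi Hz (lo = 0 => low-pass; hi = Inf =>
# high-pass); transition = one-sided raised-cosine width in Hz
fft_bandpass <- function(x, rate, lo = 0, hi = Inf, transition = NULL) {
  n0 <- length(x)
  if (is.null(transition)) transition <- max(0.5, 0.1 * max(lo, 1))
  nyq <- rate / 2
  if (lo >= nyq || (is.finite(hi) && hi > nyq))
    stop("filter band outside Nyquist range (", nyq, " Hz)", call. = FALSE)
  # pad by edge reflection to a composite FFT length (prime-length FFTs
  # in R are O(n^2)); reflection avoids wrap-around edge discontinuities
  n <- stats::nextn(n0, c(2, 3, 5))
  if (n > n0) {
    pad <- n - n0
    tail_ref <- x[n0 - (seq_len(min(pad, n0)) - 1L)]
    x <- c(x, rep(tail_ref, length.out = pad))
  }
  f <- seq(0, rate, length.out = n + 1)[1:n]
  f[f > nyq] <- rate - f[f > nyq]          # folded two-sided axis
  mask <- rep(1, n)
  if (lo > 0) {
    lo0 <- max(lo - transition, 0)
    mask <- mask * ifelse(f <= lo0, 0,
                   ifelse(f >= lo, 1,
                          0.5 * (1 - cos(pi * (f - lo0) / (lo - lo0)))))
  }
  if (is.finite(hi)) {
    hi1 <- hi + transition
    mask <- mask * ifelse(f >= hi1, 0,
                   ifelse(f <= hi, 1,
                          0.5 * (1 + cos(pi * (f - hi) / transition))))
  }
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE))[seq_len(n0)] / n
}

# mean of x over consecutive non-overlapping bins of bin_n samples;
# trailing partial bin dropped
bin_means <- function(x, bin_n) {
  nb <- length(x) %/% bin_n
  if (nb == 0L) stop("signal shorter than one bin", call. = FALSE)
  colMeans(matrix(x[seq_len(nb * bin_n)], nrow = bin_n))
}

# centered moving average with window w bins (w forced odd)
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) return(x)
  k <- rep(1 / w, w)
  y <- stats::filter(x, k, sides = 2)
  # fill edges with shrunken windows
  h <- (w - 1L) %/% 2L
  n <- length(x)
  for (i in seq_len(h)) {
    y[i] <- mean(x[1:(i + h)])
    y[n - i + 1L] <- mean(x[(n - i + 1L - h):n])
  }
  as.numeric(y)
}

# bin-centre times (s) for a 5 ms grid series of length n
bin_centers <- function(n, bin_s = 0.005) (seq_len(n) - 0.5) * bin_s
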