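# Independent oracles used across tests. These are deliberately naive
# (exhaustive loops, direct formulas) and written before the package
# implementations they check.

# exhaustive SampEn: count all template pairs with triple loops
brute_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  countm <- function(len) {
    cnt <- 0L
    for (i in 1:(nt - 1)) {
      for (j in (i + 1):nt) {
        ok <- TRUE
        for (k in 0:(len - 1)) {
          if (abs(x[i + k] - x[j + k]) > r) { ok <- FALSE; break }
        }
        if (ok) cnt <- cnt + 1L
      }
    }
    cnt
  }
  B <- countm(m)
  A <- countm(m + 1)
  if (B == 0L || A == 0L) return(NA_real_)
  -log(A / B)
}

# pooled-variance two-sample t by the textbook formula
brute_ttest <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}

# Pearson r by the direct sum formula
brute_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# small fast generator settings shared by tests: 5 kHz keeps the
# 200-1500 Hz MUA band while making 60 s runs take ~1 s
fast_params <- function(seed = 1L, ...) {
  generator_params(rate = 5000, seed = seed, ...)
}

fast_preset <- function(name, matching = "duration_matched", seed = 1L) {
  preset(name, matching, rate = 5000, seed = seed)
}

# build a state_segmentation object directly from interval vectors
# (bypasses detection; used to unit-test downstream metric functions)
manual_segmentation <- function(down_start, up_start, up_end,
                                bin_s = 0.005, n_bins = NULL) {
  cyc <- data.frame(down_start = down_start, up_start = up_start,
                    up_end = up_end)
  if (is.null(n_bins)) n_bins <- ceiling(max(up_end) / bin_s)
  structure(
    list(cycles = cyc,
         up = cbind(start = up_start, end = up_end),
         down = cbind(start = down_start, end = up_start),
         threshold = 0, bin_s = bin_s, n_bins = n_bins),
    class = "state_segmentation"
  )
}

# wrap a numeric vector as a logmua_series
manual_logmua <- function(values, bin_s = 0.005) {
  structure(list(values = values, bin_s = bin_s, band = c(200, 1500)),
            class = "logmua_series")
}
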