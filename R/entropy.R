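# Sample entropy of the logMUA series, per state.

#' Sample entropy
#'
#' SampEn(m, r, N) is the negative natural logarithm of the conditional
#' probability that two sequences similar for `m` points (Chebyshev
#' distance at most `r_abs`) remain similar at the next point,
#' self-matches excluded (Richman-Moorman convention: both template
#' lengths use the first `N - m` starting points).
#'
#' @param series Numeric vector, length at least `m + 2`.
#' @param m Template length (default 2).
#' @param r_abs Absolute similarity tolerance (> 0).
#' @return SampEn in nats, or `NA` (undefined) when no template pairs
#'   match at length `m` or `m + 1`.
#' @export
sample_entropy <- function(series, m = 2L, r_abs) {
  n <- length(series)
  stopifnot(m >= 1L, r_abs > 0)
  if (n < m + 2L) stop("series too short: need at least m + 2 points",
                       call. = FALSE)
  nt <- n - m                       # number of template starting points
  # embedding of length m and m+1 templates over the same nt starts
  emb <- function(len) {
    out <- matrix(0, nt, len)
    for (k in seq_len(len)) out[, k] <- series[(k - 1L) + seq_len(nt)]
    out
  }
  count_pairs <- function(x) {
    d <- stats::dist(x, method = "maximum")
    sum(d <= r_abs)
  }
  B <- count_pairs(emb(m))
  A <- count_pairs(emb(m + 1L))
  if (B == 0L || A == 0L) return(NA_real_)
  -log(A / B)
}

#' Per-state sample entropy of the logMUA series
#'
#' Computes SampEn within every single Up and Down state (bins assigned
#' by centre), with the tolerance set per segment as `r_factor` times the
#' segment's SD of logMUA bins, then averages the defined values over
#' homologous states. Segments with fewer than `min_bins` bins (default
#' 10, i.e. 50 ms) or with zero variance tolerance are skipped.
#'
#' @param mua A `logmua_series`.
#' @param seg A `state_segmentation`.
#' @param m Template length (default 2).
#' @param r_factor Tolerance as a fraction of the per-segment SD
#'   (default 0.25).
#' @param min_bins Minimum bins per usable segment (default 10).
#' @param r_abs Optional absolute tolerance overriding the SD scaling.
#' @return An `entropy_metrics` list: `sampen_up`, `sampen_down`, `m`,
#'   `r_factor`, `n_up_used`, `n_down_used`.
#' @export
state_sampen <- function(mua, seg, m = 2L, r_factor = 0.25, min_bins = 10L,
                         r_abs = NULL) {
  stopifnot(inherits(mua, "logmua_series"), inherits(seg, "state_segmentation"))
  v <- mua$values
  ctr <- bin_centers(length(v), mua$bin_s)
  per_class <- function(iv) {
    vals <- numeric(0)
    for (i in seq_len(nrow(iv))) {
      b <- v[ctr >= iv[i, 1L] & ctr < iv[i, 2L]]
      if (length(b) < max(min_bins, m + 2L)) next
      if (stats::sd(b) == 0) {          # constant segment: perfectly regular
        vals <- c(vals, 0)
        next
      }
      r <- if (is.null(r_abs)) r_factor * stats::sd(b) else r_abs
      if (!is.finite(r) || r <= 0) next
      se <- sample_entropy(b, m, r)
      if (!is.na(se)) vals <- c(vals, se)
    }
    vals
  }
  up <- per_class(seg$up)
  down <- per_class(seg$down)
  if (!length(up) && !length(down))
    stop("no usable segments in either state class", call. = FALSE)
  structure(list(sampen_up = if (length(up)) mean(up) else NA_real_,
                 sampen_down = if (length(down)) mean(down) else NA_real_,
                 m = m, r_factor = r_factor,
                 n_up_used = length(up), n_down_used = length(down)),
            class = "entropy_metrics")
}
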