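# logMUA: the 200-1500 Hz spectral estimate of population firing, and the
# absolute/relative firing-rate metrics built on it.

#' Estimate the logMUA series
#'
#' Multi-unit activity is estimated as the mean periodogram power of the
#' wide-band signal over 200-1500 Hz in non-overlapping 5 ms windows
#' (rectangular taper), floored at a small positive epsilon and
#' natural-log scaled.
#'
#' @param rec A [recording()].
#' @param channel Channel index.
#' @param band Two-element numeric, MUA band in Hz (default 200-1500).
#' @param bin_s Window length (s, default 0.005).
#' @return A `logmua_series`: `values` (log a.u.), `bin_s`, `band`.
#' @export
estimate_logmua <- function(rec, channel = 1L, band = c(200, 1500),
                            bin_s = 0.005) {
  stopifnot(inherits(rec, "recording"))
  if (rec$rate < 2 * band[1])
    stop("rate too low for MUA band: need >= ", 2 * band[1], " Hz",
         call. = FALSE)
  x <- rec$samples[[channel]]
  win <- round(bin_s * rec$rate)
  nb <- length(x) %/% win
  if (nb == 0L) stop("signal shorter than one window", call. = FALSE)
  m <- matrix(x[seq_len(nb * win)], nrow = win)
  sp <- stats::mvfft(m)
  f <- (seq_len(win) - 1L) * rec$rate / win
  sel <- f >= band[1] & f <= min(band[2], rec$rate / 2)
  if (!any(sel))
    stop("MUA band empty at this sampling rate", call. = FALSE)
  pow <- colMeans(abs(sp[sel, , drop = FALSE])^2) / win
  eps <- 1e-12 * stats::median(pow)
  if (eps <= 0) eps <- .Machine$double.xmin
  structure(list(values = log(pmax(pow, eps)), bin_s = bin_s, band = band),
            class = "logmua_series")
}

#' @export
print.logmua_series <- function(x, ...) {
  cat(sprintf("<logmua_series> %d bins of %g ms, band %g-%g Hz\n",
              length(x$values), 1000 * x$bin_s, x$band[1], x$band[2]))
  invisible(x)
}

#' Absolute firing rate per state
#'
#' Mean logMUA over all bins inside Up intervals (`fr_up`) and Down
#' intervals (`fr_down`); bins straddling a boundary are assigned by
#' their centre.
#'
#' @param mua A `logmua_series`.
#' @param seg A `state_segmentation`.
#' @return A list: `fr_up`, `fr_down` (log a.u.).
#' @export
state_fr <- function(mua, seg) {
  stopifnot(inherits(mua, "logmua_series"), inherits(seg, "state_segmentation"))
  v <- mua$values
  ctr <- bin_centers(length(v), mua$bin_s)
  in_up <- in_intervals(ctr, seg$up)
  in_down <- in_intervals(ctr, seg$down)
  if (!any(in_up) || !any(in_down))
    stop("empty state class in segmentation", call. = FALSE)
  list(fr_up = mean(v[in_up]), fr_down = mean(v[in_down]))
}

in_intervals <- function(t, iv) {
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(iv))) out[t >= iv[i, 1L] & t < iv[i, 2L]] <- TRUE
  out
}

#' Relative firing rate at the Down-to-Up transition
#'
#' Averages the logMUA waveform in a window around every Down-to-Up
#' transition, normalizes it to zero over the pre-transition Down
#' portion, and returns the maximum of the post-transition portion.
#' Averaging precedes the maximum (averaged-then-max, the waveform
#' convention); transitions whose window does not fit inside the series
#' are skipped.
#'
#' @param mua A `logmua_series`.
#' @param seg A `state_segmentation`.
#' @param window_s Half-window around each transition (s, default 0.5).
#' @return A list: `rel_fr` (log a.u.), `waveform`, `lag_s` (waveform
#'   time axis), `n_transitions`.
#' @export
relative_fr <- function(mua, seg, window_s = 0.5) {
  stopifnot(inherits(mua, "logmua_series"), inherits(seg, "state_segmentation"))
  v <- mua$values
  w <- round(window_s / mua$bin_s)
  onsets <- round(seg$cycles$up_start / mua$bin_s)    # bin index of up_start
  onsets <- onsets[onsets - w >= 1 & onsets + w <= length(v)]
  if (length(onsets) < 5L)
    stop("need at least 5 usable Down-to-Up transitions", call. = FALSE)
  wf <- rowMeans(vapply(onsets, function(o) v[(o - w):(o + w)],
                        numeric(2L * w + 1L)))
  lag <- seq(-w, w) * mua$bin_s
  baseline <- mean(wf[lag < 0])
  wf <- wf - baseline
  list(rel_fr = max(wf[lag >= 0]), waveform = wf, lag_s = lag,
       n_transitions = length(onsets))
}
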