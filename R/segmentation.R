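# Thresholding the combined detection series into alternating Up/Down
# states and computing slow-oscillation cycle metrics.

# Sarle's bimodality coefficient; <= 5/9 for uniform/normal-like data
.bimodality_coefficient <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) return(0)
  g1 <- mean((x - m)^3) / s^3
  g2 <- mean((x - m)^4) / s^4 - 3
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

# mean silhouette of a 1-D 2-means split (subsampled for speed)
.silhouette_1d <- function(x, cl, max_n = 2000L) {
  if (length(x) > max_n) {
    idx <- round(seq(1L, length(x), length.out = max_n))
    x <- x[idx]; cl <- cl[idx]
  }
  s <- numeric(length(x))
  for (g in 1:2) {
    own <- x[cl == g]; oth <- x[cl != g]
    if (!length(own) || !length(oth)) return(0)
    for (i in which(cl == g)) {
      a <- mean(abs(x[i] - own)) * length(own) / max(length(own) - 1L, 1L)
      b <- mean(abs(x[i] - oth))
      s[i] <- (b - a) / max(a, b)
    }
  }
  mean(s)
}

# histogram-trough threshold: deepest density valley between the two
# dominant modes; NULL when no clean bimodality
.trough_threshold <- function(x) {
  d <- stats::density(x, n = 512)
  y <- d$y
  locmax <- which(diff(sign(diff(y))) == -2) + 1L
  locmax <- locmax[y[locmax] >= 0.10 * max(y)]
  if (length(locmax) < 2L) return(NULL)
  peaks <- locmax[order(y[locmax], decreasing = TRUE)][1:2]
  lo <- min(peaks); hi <- max(peaks)
  btw <- lo:hi
  trough <- btw[which.min(y[btw])]
  if (y[trough] > 0.5 * min(y[lo], y[hi])) return(NULL)  # shallow valley
  d$x[trough]
}

#' Segment the combined series into Up and Down states
#'
#' Thresholds the PCA-combined detection series at the trough between the
#' two modes of its distribution (falling back to the 2-means class
#' boundary when the density is unimodal), then cleans the binary
#' sequence: sub-`merge_gap_s` gaps between Up runs are merged, runs
#' shorter than `min_state_s` are absorbed into their flanking state, and
#' partial states at the edges of the recording are dropped. If the
#' distribution shows no evidence of two states (unimodal density whose
#' 2-means split has silhouette < 0.2 or a bimodality coefficient at or
#' below the unimodal reference 5/9), segmentation aborts.
#'
#' @param fs A `feature_set` from [combine_features_pca()], or a numeric
#'   combined series.
#' @param min_state_s Minimum state duration (s, default 0.1).
#' @param merge_gap_s Maximum gap merged into an Up run (s, default 0.05).
#' @return A `state_segmentation`: `cycles` data frame (`down_start`,
#'   `up_start`, `up_end`, seconds; a cycle is a Down followed by its
#'   terminating Up), `up` / `down` interval matrices, `threshold`,
#'   `bin_s`, `n_bins`.
#' @export
segment_states <- function(fs, min_state_s = 0.1, merge_gap_s = 0.05) {
  x <- if (inherits(fs, "feature_set")) fs$combined else as.numeric(fs)
  bin_s <- if (inherits(fs, "feature_set")) fs$bin_s else FEATURE_BIN_S
  if (length(x) < 10 / bin_s)
    stop("combined series shorter than 10 s", call. = FALSE)
  thr <- .trough_threshold(x)
  if (is.null(thr)) {
    km <- stats::kmeans(x, centers = 2L, nstart = 5L)
    sil <- .silhouette_1d(x, km$cluster)
    bc <- .bimodality_coefficient(x)
    if (sil < 0.2 || bc <= 5 / 9)
      stop("no state alternation detected", call. = FALSE)
    thr <- mean(km$centers)
  }
  up <- x > thr
  # merge short gaps between Up runs
  r <- rle(up)
  gap_bins <- max(1L, round(merge_gap_s / bin_s))
  short_gap <- !r$values & r$lengths < gap_bins
  short_gap[1L] <- FALSE; short_gap[length(short_gap)] <- FALSE
  r$values[short_gap] <- TRUE
  up <- inverse.rle(r)
  # absorb runs shorter than min_state_s into the flanking state
  min_bins <- max(1L, round(min_state_s / bin_s))
  repeat {
    r <- rle(up)
    if (length(r$lengths) < 2L) break
    interior <- seq_along(r$lengths)
    interior <- interior[interior > 1L & interior < length(r$lengths)]
    short <- interior[r$lengths[interior] < min_bins]
    if (!length(short)) break
    i <- short[which.min(r$lengths[short])]
    r$values[i] <- !r$values[i]
    up <- inverse.rle(r)
  }
  r <- rle(up)
  if (length(r$lengths) < 4L)
    stop("no state alternation detected", call. = FALSE)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  runs <- data.frame(value = r$values, start = starts, end = ends)
  # drop partial edge states
  runs <- runs[-c(1L, nrow(runs)), , drop = FALSE]
  # cycles: Down followed by its terminating Up
  cyc <- list()
  i <- 1L
  while (i < nrow(runs)) {
    if (!runs$value[i] && runs$value[i + 1L]) {
      cyc[[length(cyc) + 1L]] <- c(down_start = runs$start[i],
                                   up_start = runs$start[i + 1L],
                                   up_end = runs$end[i + 1L])
      i <- i + 2L
    } else i <- i + 1L
  }
  if (length(cyc) < 2L)
    stop("no state alternation detected", call. = FALSE)
  cyc <- as.data.frame(do.call(rbind, cyc)) * bin_s
  ups <- runs[runs$value, , drop = FALSE]
  downs <- runs[!runs$value, , drop = FALSE]
  structure(
    list(cycles = cyc,
         up = cbind(start = ups$start, end = ups$end) * bin_s,
         down = cbind(start = downs$start, end = downs$end) * bin_s,
         threshold = thr, bin_s = bin_s, n_bins = length(x)),
    class = "state_segmentation"
  )
}

#' @export
print.state_segmentation <- function(x, ...) {
  cat(sprintf("<state_segmentation> %d cycles, %d Up / %d Down intervals\n",
              nrow(x$cycles), nrow(x$up), nrow(x$down)))
  invisible(x)
}

#' Slow-oscillation cycle metrics
#'
#' Per-cycle frequency is the inverse of the whole Up-Down cycle
#' duration; the SO frequency is its mean; the CV is the ratio of the
#' standard deviation (sample SD, n-1) of the per-cycle frequency to its
#' mean. Durations are arithmetic means over states.
#'
#' @param seg A `state_segmentation`.
#' @return A list: `so_freq_hz`, `mean_up_s`, `mean_down_s`, `cv_freq`,
#'   `n_cycles`, and the per-cycle `freq_hz` vector.
#' @export
so_metrics <- function(seg) {
  stopifnot(inherits(seg, "state_segmentation"))
  cyc <- seg$cycles
  if (nrow(cyc) < 2L) stop("need at least 2 complete cycles", call. = FALSE)
  up_d <- cyc$up_end - cyc$up_start
  down_d <- cyc$up_start - cyc$down_start
  f <- 1 / (up_d + down_d)
  list(so_freq_hz = mean(f),
       mean_up_s = mean(up_d),
       mean_down_s = mean(down_d),
       cv_freq = stats::sd(f) / mean(f),
       n_cycles = nrow(cyc),
       freq_hz = f)
}

# per-bin logical Up labels implied by a segmentation (bin-centre rule)
segmentation_labels <- function(seg, n_bins = seg$n_bins) {
  ctr <- bin_centers(n_bins, seg$bin_s)
  up <- rep(FALSE, n_bins)
  for (i in seq_len(nrow(seg$up)))
    up[ctr >= seg$up[i, 1L] & ctr < seg$up[i, 2L]] <- TRUE
  up
}

#' Sample-wise agreement between a segmentation and ground-truth labels
#'
#' Majority-votes the per-sample ground-truth Up labels onto the 5 ms
#' feature grid and returns the fraction of bins on which detection and
#' truth agree.
#'
#' @param seg A `state_segmentation`.
#' @param truth_up Logical per-sample ground-truth labels (from the
#'   generator).
#' @param rate Sampling rate of `truth_up` (Hz).
#' @return Agreement fraction in `[0, 1]`.
#' @export
label_agreement <- function(seg, truth_up, rate) {
  bin_n <- round(seg$bin_s * rate)
  lab <- segmentation_labels(seg)
  nb <- min(length(lab), length(truth_up) %/% bin_n)
  tu <- colMeans(matrix(truth_up[seq_len(nb * bin_n)], nrow = bin_n)) > 0.5
  mean(tu == lab[seq_len(nb)])
}
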