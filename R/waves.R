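# Grouping per-channel Up-state onsets into traveling waves, clustering
# the lag patterns, and estimating propagation speed.

#' Extract per-channel Up-state onset times
#'
#' Runs the detection pipeline on every channel of an array recording and
#' returns the Up-state onset times per channel.
#'
#' @param rec A multichannel [recording()].
#' @param ... Passed to [compute_features()].
#' @return A list of numeric onset-time vectors (s), one per channel.
#' @export
channel_onsets <- function(rec, ...) {
  stopifnot(inherits(rec, "recording"))
  lapply(seq_along(rec$samples), function(c) {
    seg <- segment_states(compute_features(rec, c, ...))
    seg$cycles$up_start
  })
}

#' Group per-channel onsets into waves
#'
#' Recursive grouping: starting from a window W0 (half the pooled median
#' inter-onset interval), onsets are greedily grouped so that each wave
#' holds at most one onset per channel within W of the provisional wave
#' time (the mean of its members); the window then shrinks by a fixed
#' factor and onsets are reassigned to the nearest wave until the
#' assignment is stable or W falls below `w_min`. Partial waves with
#' disjoint channel masks and compatible times are then merged
#' ("recollected") into full waves, and waves with fewer than
#' `min_channels` participants are dropped. Lags are relative to the
#' wave's mean onset time.
#'
#' @param onsets List of per-channel onset-time vectors (s).
#' @param min_channels Minimum participating channels per wave
#'   (default 10).
#' @param w0 Initial window (s); default half the pooled median
#'   inter-onset interval.
#' @param shrink Window shrink factor per iteration (default 0.75).
#' @param w_min Window floor (s, default 0.02).
#' @return A `wave_set`: `onset` and `lag` matrices (waves x channels,
#'   `NA` for non-participants), `times` (mean onset per wave),
#'   `n_channels`.
#' @export
group_waves <- function(onsets, min_channels = 10L, w0 = NULL,
                        shrink = 0.75, w_min = 0.02) {
  usable <- sum(vapply(onsets, length, integer(1)) > 0L)
  if (usable < min_channels)
    stop("need at least ", min_channels, " channels with onsets (",
         usable, " usable)", call. = FALSE)
  nc <- length(onsets)
  ev <- data.frame(
    time = unlist(onsets),
    channel = rep(seq_len(nc), vapply(onsets, length, integer(1)))
  )
  ev <- ev[order(ev$time), , drop = FALSE]
  if (is.null(w0)) {
    ioi <- unlist(lapply(onsets, function(o) diff(sort(o))))
    if (!length(ioi)) stop("no inter-onset intervals", call. = FALSE)
    w0 <- stats::median(ioi) / 2
  }
  # initial greedy pass
  wave_id <- integer(nrow(ev))
  cur_members <- integer(0)
  cur_id <- 0L
  for (i in seq_len(nrow(ev))) {
    ref <- if (length(cur_members)) mean(ev$time[cur_members]) else -Inf
    if (length(cur_members) &&
        ev$time[i] - ref <= w0 &&
        !(ev$channel[i] %in% ev$channel[cur_members])) {
      cur_members <- c(cur_members, i)
    } else {
      cur_id <- cur_id + 1L
      cur_members <- i
    }
    wave_id[i] <- cur_id
  }
  # iterative refinement with shrinking window
  W <- w0
  repeat {
    W <- W * shrink
    if (W < w_min) break
    wt <- tapply(ev$time, wave_id, mean)
    wt <- wt[!is.na(wt)]
    times <- as.numeric(wt)
    # nearest wave within W
    idx <- findInterval(ev$time, times)
    cand_lo <- pmax(idx, 1L)
    cand_hi <- pmin(idx + 1L, length(times))
    d_lo <- abs(ev$time - times[cand_lo])
    d_hi <- abs(ev$time - times[cand_hi])
    best <- ifelse(d_lo <= d_hi, cand_lo, cand_hi)
    dist <- pmin(d_lo, d_hi)
    new_id <- ifelse(dist <= W, best, 0L)
    # enforce one onset per channel per wave: keep the closest
    keyed <- paste(new_id, ev$channel)
    dup <- new_id > 0L & stats::ave(dist, keyed, FUN = min) < dist
    new_id[dup] <- 0L
    if (identical(new_id, wave_id)) break
    wave_id <- new_id
  }
  assigned <- wave_id > 0L
  ids <- sort(unique(wave_id[assigned]))
  waves <- lapply(ids, function(g) ev[wave_id == g, , drop = FALSE])
  # recollect partial waves: merge time-compatible waves with disjoint masks
  merged <- TRUE
  while (merged && length(waves) > 1L) {
    merged <- FALSE
    times <- vapply(waves, function(wv) mean(wv$time), numeric(1))
    ord <- order(times)
    waves <- waves[ord]; times <- times[ord]
    for (i in seq_len(length(waves) - 1L)) {
      a <- waves[[i]]; b <- waves[[i + 1L]]
      if (abs(mean(b$time) - mean(a$time)) <= max(W, w_min) * 2 &&
          !any(a$channel %in% b$channel)) {
        waves[[i]] <- rbind(a, b)
        waves[[i + 1L]] <- NULL
        merged <- TRUE
        break
      }
    }
  }
  waves <- Filter(function(wv) nrow(wv) >= min_channels, waves)
  if (!length(waves))
    stop("no waves with >= ", min_channels, " channels", call. = FALSE)
  onset_mat <- matrix(NA_real_, nrow = length(waves), ncol = nc)
  for (i in seq_along(waves))
    onset_mat[i, waves[[i]]$channel] <- waves[[i]]$time
  wave_times <- rowMeans(onset_mat, na.rm = TRUE)
  lag_mat <- onset_mat - wave_times
  structure(list(onset = onset_mat, lag = lag_mat, times = wave_times,
                 n_channels = nc),
            class = "wave_set")
}

#' @export
print.wave_set <- function(x, ...) {
  cat(sprintf("<wave_set> %d waves over %d channels\n",
              nrow(x$onset), x$n_channels))
  invisible(x)
}

#' Cluster wave lag patterns with k-means
#'
#' Clusters the per-wave relative-lag vectors into at most `k` groups
#' (k-means, fixed seed, 50 restarts). Missing-channel lags are imputed
#' by the running cluster mean during iteration; reported per-cluster
#' mean lags and SEMs use only observed lags.
#'
#' @param ws A `wave_set`.
#' @param k Maximum number of clusters (default 5); effective k is
#'   `min(k, n_waves, n_distinct_patterns)`.
#' @param seed RNG seed for the k-means restarts.
#' @param nstart Number of k-means restarts (default 50).
#' @return A `wave_clusters`: `assignment`, `mean_lags` (k x channels),
#'   `sem_lags`, `weights` (wave proportions, sum 1), `k`.
#' @export
cluster_lags <- function(ws, k = 5L, seed = 1L, nstart = 50L) {
  stopifnot(inherits(ws, "wave_set"))
  lag <- ws$lag
  nw <- nrow(lag)
  if (nw < 1L) stop("empty wave set", call. = FALSE)
  # impute missing lags with channel means to start
  imp <- lag
  cm <- colMeans(lag, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  for (j in seq_len(ncol(imp))) imp[is.na(imp[, j]), j] <- cm[j]
  k_eff <- min(k, nw, nrow(unique(round(imp, 12))))
  set.seed(seed)
  if (k_eff == 1L) {
    assign_vec <- rep(1L, nw)
  } else if (k_eff == nw) {
    assign_vec <- seq_len(nw)      # singleton clusters; kmeans needs k < n
  } else {
    for (it in 1:3) {
      km <- stats::kmeans(imp, centers = k_eff, nstart = nstart,
                          iter.max = 100L)
      assign_vec <- km$cluster
      # re-impute missing entries from the assigned cluster's mean
      for (g in seq_len(k_eff)) {
        rows <- which(assign_vec == g)
        gm <- colMeans(lag[rows, , drop = FALSE], na.rm = TRUE)
        gm[is.nan(gm)] <- cm[is.nan(gm)]
        for (j in seq_len(ncol(imp))) {
          miss <- rows[is.na(lag[rows, j])]
          imp[miss, j] <- gm[j]
        }
      }
    }
  }
  mean_lags <- matrix(NA_real_, k_eff, ncol(lag))
  sem_lags <- matrix(NA_real_, k_eff, ncol(lag))
  for (g in seq_len(k_eff)) {
    rows <- lag[assign_vec == g, , drop = FALSE]
    mean_lags[g, ] <- colMeans(rows, na.rm = TRUE)
    nn <- colSums(!is.na(rows))
    sem_lags[g, ] <- apply(rows, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(nn, 1))
  }
  mean_lags[is.nan(mean_lags)] <- NA_real_
  structure(list(assignment = assign_vec, mean_lags = mean_lags,
                 sem_lags = sem_lags,
                 weights = as.numeric(table(factor(assign_vec,
                                                   seq_len(k_eff)))) / nw,
                 k = k_eff),
            class = "wave_clusters")
}

#' Weighted propagation speed from clustered lags
#'
#' Per cluster, the speed is the distance between the electrodes showing
#' the maximum and minimum average time lags divided by their lag
#' difference; the recording-level speed is the mean over clusters
#' weighted by the proportion of waves each contains. Clusters with zero
#' lag spread (or fewer than two electrodes with defined mean lags) have
#' undefined speed; they are excluded and the weights renormalized, with
#' a warning.
#'
#' @param wc A `wave_clusters`.
#' @param positions_mm Electrode positions along the array axis (mm).
#' @return A list: `weighted_speed` (mm/s), `cluster_speeds`, `weights`
#'   (renormalized over defined clusters), `direction_sign` (sign of the
#'   lag-vs-position regression slope of the heaviest cluster;
#'   informational: positive = propagation towards increasing position).
#' @export
propagation_speed <- function(wc, positions_mm) {
  stopifnot(inherits(wc, "wave_clusters"))
  if (length(positions_mm) != ncol(wc$mean_lags))
    stop("geometry does not match the number of channels", call. = FALSE)
  speeds <- rep(NA_real_, wc$k)
  for (g in seq_len(wc$k)) {
    ml <- wc$mean_lags[g, ]
    ok <- !is.na(ml)
    if (sum(ok) < 2L) next
    imax <- which.max(ifelse(ok, ml, -Inf))
    imin <- which.min(ifelse(ok, ml, Inf))
    spread <- ml[imax] - ml[imin]
    if (spread <= 0) next
    speeds[g] <- abs(positions_mm[imax] - positions_mm[imin]) / spread
  }
  ok <- !is.na(speeds)
  if (!any(ok)) stop("no cluster with defined propagation speed", call. = FALSE)
  if (!all(ok))
    warning(sum(!ok), " cluster(s) with undefined speed excluded; ",
            "weights renormalized")
  w <- wc$weights[ok] / sum(wc$weights[ok])
  heavy <- which.max(wc$weights * ok)
  ml <- wc$mean_lags[heavy, ]
  okh <- !is.na(ml)
  slope <- stats::coef(stats::lm(ml[okh] ~ positions_mm[okh]))[2L]
  list(weighted_speed = sum(w * speeds[ok]),
       cluster_speeds = speeds,
       weights = w,
       direction_sign = sign(unname(slope)))
}
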