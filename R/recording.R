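#' Channel metadata
#'
#' Describes one extracellular channel: a free-text label, the cortical
#' area it was recorded from, the hemisphere, and (for linear-array
#' recordings) the position of the contact along the array axis.
#'
#' @param label Character label, e.g. `"ch01"`.
#' @param area One of `"PrL"`, `"M1"`, `"S1"`, `"V1"`, `"synthetic"`.
#' @param hemisphere One of `"left"`, `"right"`, `"n/a"`.
#' @param position_mm Position along the array axis in millimetres, or
#'   `NA` for single-electrode recordings.
#' @return A `channel_meta` list.
#' @export
channel_meta <- function(label, area = "synthetic", hemisphere = "n/a",
                         position_mm = NA_real_) {
  area <- match.arg(area, c("PrL", "M1", "S1", "V1", "synthetic"))
  hemisphere <- match.arg(hemisphere, c("left", "right", "n/a"))
  stopifnot(is.character(label), length(label) == 1L)
  structure(
    list(label = label, area = area, hemisphere = hemisphere,
         position_mm = as.numeric(position_mm)),
    class = "channel_meta"
  )
}

#' Multichannel extracellular recording
#'
#' Container for a sampled LFP signal: a list of equal-length numeric
#' channels, the sampling rate, and per-channel metadata. All times in
#' the package are seconds, sample indices are 0-based and intervals
#' half-open `[start, end)`. Amplitudes are nominally microvolts; for
#' synthetic signals the scale is arbitrary and flagged as such.
#'
#' @param samples A numeric vector (single channel) or a list of
#'   equal-length numeric vectors, one per channel.
#' @param rate Sampling frequency in Hz (> 0).
#' @param channels A list of [channel_meta()] objects, one per channel.
#'   Defaults to anonymous synthetic channels.
#' @param arbitrary_units Logical; `TRUE` for synthetic signals whose
#'   amplitude scale is not calibrated.
#' @return A `recording` object with fields `samples`, `rate`,
#'   `channels`, `duration` (seconds) and `arbitrary_units`.
#' @export
recording <- function(samples, rate, channels = NULL, arbitrary_units = TRUE) {
  if (is.numeric(samples)) samples <- list(samples)
  stopifnot(is.list(samples), length(samples) >= 1L)
  n <- unique(vapply(samples, length, integer(1)))
  if (length(n) != 1L)
    stop("integrity error: channels differ in length", call. = FALSE)
  if (n == 0L)
    stop("zero-length channels are not allowed", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar (Hz)", call. = FALSE)
  if (is.null(channels)) {
    channels <- lapply(seq_along(samples), function(i)
      channel_meta(sprintf("ch%02d", i)))
  }
  if (length(channels) != length(samples))
    stop("integrity error: metadata for ", length(channels),
         " channels but payload holds ", length(samples), call. = FALSE)
  pos <- vapply(channels, function(ch) ch$position_mm, numeric(1))
  if (any(!is.na(pos))) {
    if (any(is.na(pos)))
      stop("position_mm must be present for all channels of an array recording",
           call. = FALSE)
    if (any(diff(pos) <= 0))
      stop("channel positions must be strictly increasing", call. = FALSE)
  }
  structure(
    list(samples = samples, rate = rate, channels = channels,
         duration = n / rate, arbitrary_units = isTRUE(arbitrary_units)),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s), %.6g s at %g Hz (%d samples)\n",
              length(x$samples), x$duration, x$rate,
              length(x$samples[[1]])))
  areas <- unique(vapply(x$channels, function(ch) ch$area, character(1)))
  cat("  areas:", paste(areas, collapse = ", "),
      if (x$arbitrary_units) " [arbitrary units]" else " [uV]", "\n")
  invisible(x)
}

n_samples <- function(rec) length(rec$samples[[1]])

#' Registry of metric names used in metric tables
#' @return Character vector of valid `metric_name` values.
#' @export
metric_registry <- function() {
  c("so_frequency", "up_duration", "down_duration", "cv_freq",
    "fr_up", "fr_down", "rel_fr",
    "sampen_up", "sampen_down",
    "peak_hz", "peak_excess", "alpha_1f",
    "wave_speed", "n_waves", "label_agreement")
}

#' Build a metric table
#'
#' Long-format table of per-recording metrics with cohort labels.
#'
#' @param recording_id,group,age,area,metric_name,value,se Column vectors
#'   (recycled to a common length). `metric_name` must be drawn from
#'   [metric_registry()]; `value` must be finite.
#' @return A `data.frame` with class `metric_table`.
#' @export
metric_table <- function(recording_id, group, age, area, metric_name, value,
                         se = NA_real_) {
  df <- data.frame(recording_id = as.character(recording_id),
                   group = as.character(group),
                   age = as.character(age),
                   area = as.character(area),
                   metric_name = as.character(metric_name),
                   value = as.numeric(value),
                   se = as.numeric(se),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$metric_name), metric_registry())
  if (length(bad))
    stop("registry error: unknown metric_name(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$value)))
    stop("metric values must be finite", call. = FALSE)
  class(df) <- c("metric_table", "data.frame")
  df
}
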