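#' Write a recording to disk
#'
#' The on-disk format is a raw little-endian float32 payload with
#' channel-interleaved samples (`<path>.f32`) plus a JSON sidecar
#' (`<path>.json`) declaring the sampling rate, dtype, layout and the
#' per-channel metadata. Samples are stored as float32; recordings
#' produced by the synthetic generator are already float32-quantized, so
#' write/read round-trips are bit-exact for them.
#'
#' @param rec A [recording()].
#' @param path Base path without extension; `.f32` and `.json` are added.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  n <- n_samples(rec)
  if (n == 0L) stop("refusing to write empty-channel recording", call. = FALSE)
  payload <- sub("\\.f32$", "", path)
  sidecar <- paste0(payload, ".json")
  payload <- paste0(payload, ".f32")
  mat <- do.call(rbind, rec$samples)       # channels x samples
  con <- file(payload, "wb")
  on.exit(close(con), add = TRUE)
  # interleaved: sample-major, channel-minor
  writeBin(as.vector(mat), con, size = 4L, endian = "little")
  meta <- list(
    format = "slowosc-lfp-v1",
    dtype = "float32_le",
    layout = "interleaved_channel_minor",
    rate = rec$rate,
    n_channels = length(rec$samples),
    n_samples = n,
    duration_s = rec$duration,
    arbitrary_units = rec$arbitrary_units,
    units = "uV",
    channels = lapply(rec$channels, function(ch)
      list(label = ch$label, area = ch$area, hemisphere = ch$hemisphere,
           position_mm = if (is.na(ch$position_mm)) NULL else ch$position_mm))
  )
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path Base path (with or without the `.f32` extension).
#' @return A [recording()].
#' @export
read_recording <- function(path) {
  base <- sub("\\.f32$", "", path)
  sidecar <- paste0(base, ".json")
  payload <- paste0(base, ".f32")
  if (!file.exists(sidecar))
    stop("format error: missing sidecar ", sidecar, call. = FALSE)
  if (!file.exists(payload))
    stop("format error: missing payload ", payload, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = FALSE)
  for (k in c("rate", "n_channels", "n_samples", "dtype"))
    if (is.null(meta[[k]]))
      stop("format error: sidecar lacks '", k, "'", call. = FALSE)
  if (!identical(meta$dtype, "float32_le"))
    stop("format error: unsupported dtype ", meta$dtype, call. = FALSE)
  nch <- as.integer(meta$n_channels)
  ns <- as.integer(meta$n_samples)
  sz <- file.info(payload)$size
  if (sz != 4 * nch * ns)
    stop("integrity error: payload holds ", sz %/% (4L * ns),
         " channel(s), sidecar declares ", nch, call. = FALSE)
  con <- file(payload, "rb")
  on.exit(close(con), add = TRUE)
  raw <- readBin(con, what = "numeric", n = nch * ns, size = 4L,
                 endian = "little")
  mat <- matrix(raw, nrow = nch, ncol = ns)
  channels <- lapply(meta$channels, function(ch)
    channel_meta(ch$label, ch$area, ch$hemisphere,
                 if (is.null(ch$position_mm)) NA_real_ else ch$position_mm))
  recording(lapply(seq_len(nch), function(i) mat[i, ]),
            rate = as.numeric(meta$rate), channels = channels,
            arbitrary_units = isTRUE(meta$arbitrary_units))
}

#' Write a metric table as CSV
#'
#' RFC-4180 CSV with a fixed header and full-precision floats.
#'
#' @param table A [metric_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(table, path) {
  stopifnot(inherits(table, "metric_table"))
  if (nrow(table) == 0L) stop("empty metric table", call. = FALSE)
  df <- as.data.frame(table)
  df$value <- sprintf("%.17g", df$value)
  df$se <- ifelse(is.na(df$se), "", sprintf("%.17g", df$se))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a metric table CSV written by [write_metrics()]
#' @param path CSV path.
#' @return A [metric_table()].
#' @export
read_metrics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(se = "character"))
  df$se[df$se == ""] <- NA_character_
  metric_table(df$recording_id, df$group, df$age, df$area, df$metric_name,
               df$value, as.numeric(df$se))
}

# quantize a double vector through float32 (used by the generator so that
# in-memory and written/re-read signals are bit-identical)
quantize_f32 <- function(x) {
  readBin(writeBin(x, raw(), size = 4L, endian = "little"),
          what = "numeric", n = length(x), size = 4L, endian = "little")
}
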