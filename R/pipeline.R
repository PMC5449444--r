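# End-to-end orchestration: per-recording analysis, cohort pipeline from
# a YAML config, and group summaries.

#' Analyze one recording channel end to end
#'
#' Runs the detection pipeline (features, PCA combination, state
#' segmentation) and computes the slow-oscillation, firing-rate, sample
#' entropy and Up-state spectral-peak metrics.
#'
#' @param rec A [recording()].
#' @param channel Channel index.
#' @param so_cutoff_hz,gamma_band Detection feature parameters.
#' @param min_state_s,merge_gap_s Segmentation parameters.
#' @param psd_window_n Welch window length in samples; `NULL` skips the
#'   spectral block (useful for short recordings).
#' @return A list: `seg`, `metrics` (named numeric vector using
#'   [metric_registry()] names), `features`, `mua`, and (when computed)
#'   `psd_up`, `fit`, `excess`.
#' @export
analyze_recording <- function(rec, channel = 1L, so_cutoff_hz = 2,
                              gamma_band = c(20, 80), min_state_s = 0.1,
                              merge_gap_s = 0.05, psd_window_n = 5000L) {
  fs <- compute_features(rec, channel, so_cutoff_hz, gamma_band)
  seg <- segment_states(fs, min_state_s, merge_gap_s)
  mua <- estimate_logmua(rec, channel)
  som <- so_metrics(seg)
  fr <- state_fr(mua, seg)
  rel <- tryCatch(relative_fr(mua, seg)$rel_fr, error = function(e) NA_real_)
  ent <- state_sampen(mua, seg)
  metrics <- c(so_frequency = som$so_freq_hz,
               up_duration = som$mean_up_s,
               down_duration = som$mean_down_s,
               cv_freq = som$cv_freq,
               fr_up = fr$fr_up, fr_down = fr$fr_down, rel_fr = rel,
               sampen_up = ent$sampen_up, sampen_down = ent$sampen_down)
  out <- list(seg = seg, features = fs, mua = mua, metrics = metrics)
  if (!is.null(psd_window_n)) {
    spectral <- tryCatch({
      psd_up <- state_psd(rec, channel, seg, "Up", psd_window_n)
      fit <- fit_one_over_f(psd_up)
      ex <- power_excess(psd_up, fit)
      list(psd_up = psd_up, fit = fit, excess = ex,
           metrics = c(peak_hz = ex$peak_hz, peak_excess = ex$peak_excess,
                       alpha_1f = fit$alpha))
    }, error = function(e) NULL)
    if (!is.null(spectral)) {
      out$psd_up <- spectral$psd_up
      out$fit <- spectral$fit
      out$excess <- spectral$excess
      out$metrics <- c(out$metrics, spectral$metrics)
    }
  }
  out
}

#' Run the cohort pipeline from a config
#'
#' The config (a YAML file path or an equivalent list) declares
#' recordings to analyze, each either a file path (core format) or a
#' simulation spec, with `group` / `age` / `area` labels:
#'
#' ```yaml
#' recordings:
#'   - id: r1a
#'     group: SAMR1
#'     age: 5M
#'     area: M1
#'     preset: SAMR1_5M          # or `path: some/file` for a recording
#'     matching: frequency_matched
#'     duration_s: 120
#'     seed: 11
#'     rate: 10000
#' ```
#'
#' Per-recording failures are recorded and excluded from summaries.
#'
#' @param config Path to a YAML file or a list.
#' @param psd_window_n Welch window (samples); `NULL` to skip spectra.
#' @return A list: `metrics` (a [metric_table()]), `summary` (per
#'   group/age/area/metric n, mean, se), `tests` (pooled-area group
#'   contrasts per age and metric), `errors` (named character).
#' @export
run_pipeline <- function(config, psd_window_n = 5000L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  specs <- config$recordings
  if (!length(specs)) stop("config lists no recordings", call. = FALSE)
  rows <- list()
  errors <- character(0)
  for (sp in specs) {
    res <- tryCatch({
      rec <- if (!is.null(sp$path)) {
        read_recording(sp$path)
      } else {
        pr <- preset(sp$preset,
                     matching = if (is.null(sp$matching)) "duration_matched"
                                else sp$matching,
                     rate = if (is.null(sp$rate)) 10000 else sp$rate,
                     seed = if (is.null(sp$seed)) 1L else sp$seed)
        synthesize_channel(pr, if (is.null(sp$duration_s)) 120
                               else sp$duration_s)$rec
      }
      ana <- analyze_recording(rec, psd_window_n = psd_window_n)
      m <- ana$metrics[!is.na(ana$metrics)]
      metric_table(sp$id, sp$group, sp$age, sp$area, names(m), m)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[sp$id] <- conditionMessage(res)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows)) stop("all recordings failed: ",
                          paste(errors, collapse = "; "), call. = FALSE)
  metrics <- do.call(rbind, rows)
  class(metrics) <- c("metric_table", "data.frame")
  list(metrics = metrics,
       summary = summarize_groups(metrics),
       tests = group_tests(metrics),
       errors = errors)
}

#' Per-group summary of a metric table
#'
#' Mean and standard error per (group, age, area, metric), plus
#' pooled-area rows (`area = "pooled"`) where every per-recording area
#' value enters as one observation.
#'
#' @param metrics A [metric_table()].
#' @return A data frame with columns `group`, `age`, `area`,
#'   `metric_name`, `n`, `mean`, `se`.
#' @export
summarize_groups <- function(metrics) {
  stopifnot(inherits(metrics, "metric_table"))
  df <- as.data.frame(metrics)
  pooled <- df
  pooled$area <- "pooled"
  both <- rbind(df, pooled)
  agg <- stats::aggregate(value ~ group + age + area + metric_name, both,
                          function(v) c(n = length(v), mean = mean(v),
                                        se = stats::sd(v) / sqrt(length(v))))
  out <- cbind(agg[, c("group", "age", "area", "metric_name")],
               as.data.frame(agg$value))
  out[order(out$metric_name, out$age, out$area, out$group), ]
}

#' Pooled-area group contrasts
#'
#' For every age and metric with exactly two groups of n >= 2, runs the
#' independent-samples Student t-test on the pooled-area observations.
#' No multiple-testing correction is applied (raw p-values).
#'
#' @param metrics A [metric_table()].
#' @return A data frame: `age`, `metric_name`, `group_a`, `group_b`,
#'   `n_a`, `n_b`, `t`, `p`.
#' @export
group_tests <- function(metrics) {
  df <- as.data.frame(metrics)
  out <- list()
  for (age in unique(df$age)) {
    for (mn in unique(df$metric_name)) {
      sub <- df[df$age == age & df$metric_name == mn, ]
      gs <- sort(unique(sub$group))
      if (length(gs) != 2L) next
      a <- sub$value[sub$group == gs[1L]]
      b <- sub$value[sub$group == gs[2L]]
      if (length(a) < 2L || length(b) < 2L) next
      tt <- ttest_independent(a, b)
      out[[length(out) + 1L]] <- data.frame(
        age = age, metric_name = mn, group_a = gs[1L], group_b = gs[2L],
        n_a = length(a), n_b = length(b), t = tt$t, p = tt$p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}
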