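## Component features from TRFs: grand averages, windowed mean amplitudes,
## and individual peak latencies transferred from the grand-average peak via
## dynamic time warping (DTW).  Windows: N1 90-140 ms, P2 190-250 ms, late
## component 300-600 ms (open-class words) / 500-800 ms (closed-class words).

#' Component analysis windows and polarities
#' @return Data frame: `component`, `lo_ms`, `hi_ms`, `polarity`.
#' @export
component_windows <- function() {
  data.frame(component = c("N1", "P2", "late_open", "late_closed"),
             lo_ms = c(90, 190, 300, 500),
             hi_ms = c(140, 250, 600, 800),
             polarity = c("negative", "positive", "negative", "negative"),
             stringsAsFactors = FALSE)
}

#' Grand-average TRF waveform
#'
#' Pointwise mean across participants of one feature/channel kernel.
#'
#' @param trfsets List of [trf_set()] (one per participant).
#' @param feature,channel Kernel to average.
#' @return Numeric lag series.
#' @export
grand_average <- function(trfsets, feature, channel) {
  if (!length(trfsets)) stop("no TRF sets given", call. = FALSE)
  rowMeans(vapply(trfsets, trf_series, numeric(trfsets[[1]]$lag_axis$n_lags),
                  feature = feature, channel = channel))
}

#' Mean amplitude within a latency window
#'
#' Arithmetic mean of the samples whose lag lies in `[lo, hi]` (inclusive).
#'
#' @param series Lag series.
#' @param lag_axis Its [lag_axis()].
#' @param window_ms Length-2 window in ms.
#' @return Scalar mean amplitude.
#' @export
window_amplitude <- function(series, lag_axis, window_ms) {
  idx <- lag_axis$lags_ms >= window_ms[1] & lag_axis$lags_ms <= window_ms[2]
  if (!any(idx)) stop("window contains no samples", call. = FALSE)
  mean(series[idx])
}

#' Peak latency of a grand-average waveform
#'
#' The extremum of the component's polarity inside its window (minimum for
#' negative components, maximum for positive); ties resolve to the earlier
#' lag.  If the extremum's sign contradicts the polarity (e.g. the series is
#' positive throughout a negative component's window) there is no peak and
#' `NA` is returned -- such features are dropped/missing downstream.
#'
#' @param series Grand-average lag series.
#' @param lag_axis Its [lag_axis()].
#' @param window_ms Component window.
#' @param polarity `"negative"` or `"positive"`.
#' @return Peak latency in ms, or `NA_real_` when no peak of the required
#'   polarity exists.
#' @export
find_grand_peak <- function(series, lag_axis, window_ms, polarity) {
  idx <- which(lag_axis$lags_ms >= window_ms[1] &
                 lag_axis$lags_ms <= window_ms[2])
  if (!length(idx)) stop("window outside the lag axis", call. = FALSE)
  vals <- series[idx]
  k <- if (polarity == "negative") which.min(vals) else which.max(vals)
  v <- vals[k]
  ok <- if (polarity == "negative") v < 0 else v > 0
  if (!ok) return(NA_real_)
  lag_axis$lags_ms[idx[k]]
}

#' Dynamic time warping between two series
#'
#' Monotone, continuous warping path from `(1, 1)` to `(n, m)` minimizing
#' the summed absolute amplitude difference, with steps
#' `{(1,0), (0,1), (1,1)}`.
#'
#' @param a,b Numeric series (non-empty).
#' @param normalize Z-normalize both series before warping (default FALSE
#'   here; the latency mapper normalizes).
#' @return List: `cost` (total path cost), `path` (two-column matrix of
#'   aligned indices).
#' @export
dtw_path <- function(a, b, normalize = FALSE) {
  if (!length(a) || !length(b)) stop("series must be non-empty",
                                     call. = FALSE)
  if (normalize) { a <- znorm(a); b <- znorm(b) }
  .dtw_core(as.numeric(a), as.numeric(b))
}

znorm <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) x - mean(x) else (x - mean(x)) / s
}

#' Transfer a grand-average peak latency onto an individual TRF
#'
#' Both series are restricted to non-negative lags (latency features live
#' there) and z-normalized, then aligned by DTW.  The individual samples
#' matched to the grand-peak sample are collected and their median index
#' (lower median, i.e. ties resolve earlier) is converted back to ms.
#'
#' @param individual Individual lag series.
#' @param grand Grand-average lag series on the same axis.
#' @param grand_peak_ms Peak latency of `grand` (from [find_grand_peak()]).
#' @param lag_axis Shared [lag_axis()].
#' @param normalize Z-normalize before DTW (default TRUE).
#' @param min_lag_ms Lower lag bound of the warped region.
#' @return Individual peak latency in ms (`NA` if `grand_peak_ms` is `NA`).
#' @export
map_peak_latency <- function(individual, grand, grand_peak_ms, lag_axis,
                             normalize = TRUE, min_lag_ms = 0) {
  if (is.na(grand_peak_ms)) return(NA_real_)
  keep <- which(lag_axis$lags_ms >= min_lag_ms)
  gi <- match(TRUE, lag_axis$lags_ms[keep] == grand_peak_ms)
  if (is.na(gi)) stop("grand_peak_ms is not on the lag axis", call. = FALSE)
  a <- individual[keep]; g <- grand[keep]
  if (normalize) { a <- znorm(a); g <- znorm(g) }
  res <- .dtw_core(as.numeric(g), as.numeric(a))   # rows follow the grand axis
  matched <- res$path[res$path[, 1] == gi, 2]
  j <- lower_median(matched)
  lag_axis$lags_ms[keep[j]]
}

# lower median: for even counts take the smaller middle value
lower_median <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

#' Pairwise position contrasts
#'
#' Differences beginning-middle, beginning-end and middle-end of a
#' per-position feature value (amplitude or latency); a missing position
#' yields a missing contrast.
#'
#' @param beginning,middle,end Scalar feature values.
#' @return Named numeric vector of the three contrasts.
#' @export
position_contrasts <- function(beginning, middle, end) {
  c(beginning_minus_middle = beginning - middle,
    beginning_minus_end = beginning - end,
    middle_minus_end = middle - end)
}
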