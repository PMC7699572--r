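## Respiratory-cycle summarization: each per-frame metric series is reduced
## to a "true" minimum (average of all breath valleys), mean (average of all
## frames) and maximum (average of all breath peaks), the surrogate measures
## of the airway's temporal dynamics.

#' Detect respiratory peaks and valleys in a metric time-series
#'
#' Local maxima (peaks) and minima (valleys) of the optionally smoothed
#' series whose topographic prominence is at least `min_prominence` times the
#' series range. Endpoints are excluded — a truncated first or last breath
#' would bias the averages. If no qualifying peak (valley) is found the
#' single global maximum (minimum) index is used as fallback, so at least one
#' of each is always returned; for a constant series both fall back to index
#' 1.
#'
#' @param series numeric vector, length >= 3.
#' @param min_prominence prominence threshold as a fraction of the series
#'   range (default 0.1).
#' @param smooth moving-average window in frames (default 1 = none; extrema
#'   are indexed on the raw series either way).
#' @return list with integer vectors `peaks` and `valleys` (1-based frame
#'   indices into the raw series).
#' @examples
#' s <- 100 + 20 * sin(2 * pi * (0:74) / 15)
#' ex <- detectExtrema(s)
#' length(ex$peaks)  # 5 breathing cycles -> 5 peaks
#' @export
detectExtrema <- function(series, min_prominence = 0.1, smooth = 1L) {
  n <- length(series)
  if (n < 3L) stop("series must have at least 3 frames")
  s <- if (smooth > 1L) movingAverage(series, as.integer(smooth)) else series
  rng <- diff(range(s))
  thr <- min_prominence * rng
  interior <- function(pk) {
    ## drop runs touching the series ends; plateau index = run start
    keep <- pk$start > 1L & pk$end < n
    idx <- pk$start[keep & pk$prominence >= thr]
    as.integer(idx)
  }
  peaks <- interior(profilePeaks(s))
  valleys <- interior(profilePeaks(-s))
  if (length(peaks) == 0L) peaks <- which.max(s)
  if (length(valleys) == 0L) valleys <- which.min(s)
  list(peaks = as.integer(peaks), valleys = as.integer(valleys))
}

#' Summarize a metrics table as true minimum / mean / maximum per measure
#'
#' For each measure column the series is reduced to `t_min` (mean of the
#' series at its valley indices), `t_mean` (mean of all frames) and `t_max`
#' (mean at its peak indices). Extrema are detected independently per
#' measure. The ordering t_min <= t_mean <= t_max is enforced: if averaging
#' noisy extrema ever violates it on a side, that side falls back to the
#' global extremum.
#'
#' @param metrics data.frame from [sequenceMetrics()] (or any data.frame with
#'   the columns named in `measures`).
#' @param min_prominence,smooth passed to [detectExtrema()].
#' @param measures named character vector mapping output measure labels to
#'   metric columns.
#' @return data.frame: measure, t_min, t_mean, t_max, n_peaks, n_valleys.
#' @examples
#' tab <- data.frame(frame = 1:75, time_ms = (0:74) * 350,
#'                   area_mm2 = 100 + 20 * sin(2 * pi * (0:74) / 15),
#'                   ap_mm = 10, tx_mm = 12)
#' summarizeTemporal(tab)
#' @export
summarizeTemporal <- function(metrics, min_prominence = 0.1, smooth = 1L,
                              measures = c(area = "area_mm2", ap = "ap_mm",
                                           tx = "tx_mm")) {
  rows <- lapply(names(measures), function(mname) {
    s <- metrics[[measures[[mname]]]]
    if (is.null(s)) stop("metrics table has no column ", measures[[mname]])
    ex <- detectExtrema(s, min_prominence = min_prominence, smooth = smooth)
    t_min <- mean(s[ex$valleys])
    t_max <- mean(s[ex$peaks])
    t_mean <- mean(s)
    if (t_min > t_mean) { ex$valleys <- which.min(s); t_min <- min(s) }
    if (t_max < t_mean) { ex$peaks <- which.max(s); t_max <- max(s) }
    data.frame(measure = mname, t_min = t_min, t_mean = t_mean,
               t_max = t_max, n_peaks = length(ex$peaks),
               n_valleys = length(ex$valleys))
  })
  do.call(rbind, rows)
}
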