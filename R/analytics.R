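# Scenario-level indicator statistics: temperature stability, alert response
# times, excursion summaries.

#' Summary statistics with a Student-t confidence interval
#'
#' Mean, sample standard deviation (n - 1 denominator) and a two-sided
#' Student-t interval `mean +/- t_{n-1,(1+level)/2} sd / sqrt(n)`. Student-t
#' rather than normal because scenario replicate counts are small.
#'
#' @param values Numeric vector (length >= 1; >= 2 for an interval).
#' @param level Confidence level in (0, 1), default 0.95; `NULL` skips the
#'   interval.
#' @return List `n`, `mean`, `sd`, `ci_low`, `ci_high` (the last two `NA`
#'   when no interval is requested).
#' @export
#' @examples
#' summarize_indicator(c(4, 5, 6))
summarize_indicator <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 1) stop("need at least one value")
  m <- mean(values)
  if (is.null(level)) {
    return(list(n = n, mean = m, sd = if (n > 1) stats::sd(values) else NA_real_,
                ci_low = NA_real_, ci_high = NA_real_))
  }
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (n < 2) stop("a confidence interval needs n >= 2")
  s <- stats::sd(values)
  half <- stats::qt((1 + level) / 2, df = n - 1) * s / sqrt(n)
  list(n = n, mean = m, sd = s, ci_low = m - half, ci_high = m + half)
}

#' Alert response times from the true temperature trace
#'
#' Response time is anchored to the TRUE threshold crossing, not the reported
#' sample: for each true excursion (maximal run of trace points outside the
#' `[alert_low, alert_high]` band) the response is the delivery time of its
#' onset alert minus the first out-of-band instant, so sensing latency (up to
#' the inter-window gap plus the window length) and any buffering delay both
#' appear in the measurement.
#'
#' @param trace Data frame `unit_id`, `time_min`, `temp_c` of true
#'   (instantaneous) temperatures, sorted by time within unit.
#' @param alerts Delivered temperature-alert data frame with `source`,
#'   `created_at`, `delivered_at` (minutes).
#' @param thresholds A [threshold_config()].
#' @return Numeric vector of response times in minutes, one per true
#'   excursion that has an onset alert. An alert that matches no true
#'   excursion raises a consistency error.
#' @export
alert_response_times <- function(trace, alerts, thresholds = threshold_config()) {
  res <- numeric(0)
  temp_alerts <- alerts[alerts$kind %in% c("temp_low", "temp_high"), ,
                        drop = FALSE]
  for (uid in unique(trace$unit_id)) {
    tr <- trace[trace$unit_id == uid, , drop = FALSE]
    tr <- tr[order(tr$time_min), , drop = FALSE]
    out <- tr$temp_c < thresholds$alert_low | tr$temp_c > thresholds$alert_high
    onset <- which(out & !c(FALSE, out[-length(out)]))
    starts <- tr$time_min[onset]
    al <- temp_alerts[temp_alerts$source == uid, , drop = FALSE]
    al <- al[order(al$created_at), , drop = FALSE]
    if (nrow(al) > 0 && length(starts) == 0) {
      stop("alert with no matching true excursion for unit ", uid)
    }
    if (length(starts) == 0) next
    bounds <- c(starts, Inf)
    used <- logical(length(starts))
    for (k in seq_len(nrow(al))) {
      i <- findInterval(al$created_at[k], bounds)
      if (i < 1) stop("alert precedes any true excursion for unit ", uid)
      if (!used[i]) {
        res <- c(res, al$delivered_at[k] - starts[i])
        used[i] <- TRUE
      }
    }
  }
  res
}

#' Per-unit excursion summary table
#'
#' @param episodes Episode data frame from [detect_excursions()].
#' @return Data frame `unit_id`, `episodes`, `total_min`, `max_peak_deviation`
#'   (degree-C beyond the violated threshold); zero rows when there are no
#'   episodes.
#' @export
excursion_summary <- function(episodes) {
  if (is.null(episodes) || nrow(episodes) == 0L) {
    return(data.frame(unit_id = character(0), episodes = integer(0),
                      total_min = numeric(0), max_peak_deviation = numeric(0),
                      stringsAsFactors = FALSE))
  }
  ids <- unique(episodes$unit_id)
  do.call(rbind, lapply(ids, function(uid) {
    e <- episodes[episodes$unit_id == uid, , drop = FALSE]
    data.frame(unit_id = uid, episodes = nrow(e),
               total_min = sum(e$duration_min),
               max_peak_deviation = max(e$peak_deviation),
               stringsAsFactors = FALSE)
  }))
}
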