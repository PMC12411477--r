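# Thermal dynamics of vaccine storage units, sensing windows, alert
# classification, excursion detection and malfunction injection.

#' Alert threshold configuration
#'
#' Vaccines are stored in a nominal 2-8 degree-C band; alerts fire when a
#' reported temperature falls below `alert_low` (3 degree-C) or rises above
#' `alert_high` (7 degree-C). Both comparisons are strict: 3.0 and 7.0 are
#' normal.
#'
#' @param nominal_low,nominal_high Nominal storage band, degree-C.
#' @param alert_low,alert_high Alert thresholds, degree-C.
#' @return A `threshold_config` list.
#' @export
threshold_config <- function(nominal_low = 2, nominal_high = 8,
                             alert_low = 3, alert_high = 7) {
  if (!(nominal_low < alert_low && alert_low < alert_high &&
        alert_high < nominal_high)) {
    stop("thresholds must satisfy nominal_low < alert_low < alert_high < nominal_high")
  }
  structure(list(nominal_low = nominal_low, nominal_high = nominal_high,
                 alert_low = alert_low, alert_high = alert_high),
            class = "threshold_config")
}

#' A vaccine storage unit
#'
#' An ice-lined refrigerator (ILR) or thermal box with mean-reverting
#' (Ornstein-Uhlenbeck) temperature dynamics: the temperature relaxes toward
#' the setpoint at rate `theta_per_h` with volatility `sigma_c`, or toward
#' ambient while the unit is in the `failed` regime.
#'
#' @param id Unit identifier.
#' @param kind `"ILR"` or `"thermal_box"`.
#' @param setpoint_c Setpoint mu, degree-C.
#' @param theta_per_h Mean-reversion rate, 1/hour (must be > 0).
#' @param sigma_c Volatility, degree-C (>= 0).
#' @param ambient_c Ambient temperature the unit drifts to when failed.
#' @param temp_c Initial temperature (defaults to the setpoint).
#' @param regime `"normal"` or `"failed"`.
#' @return An `equipment_unit` list.
#' @export
equipment_unit <- function(id, kind = c("ILR", "thermal_box"), setpoint_c = 5,
                           theta_per_h = 0.5, sigma_c = 0.15, ambient_c = 25,
                           temp_c = setpoint_c, regime = "normal") {
  kind <- match.arg(kind)
  if (!is.numeric(theta_per_h) || theta_per_h <= 0) {
    stop("theta_per_h must be > 0")
  }
  if (sigma_c < 0) stop("sigma_c must be >= 0")
  structure(list(id = id, kind = kind, setpoint_c = setpoint_c,
                 theta_per_h = theta_per_h, sigma_c = sigma_c,
                 ambient_c = ambient_c, temp_c = temp_c,
                 regime = match.arg(regime, c("normal", "failed"))),
            class = "equipment_unit")
}

#' Advance a unit's temperature by one time step
#'
#' Exact discretization of the Ornstein-Uhlenbeck process
#' `T' = target + (T - target) exp(-theta dt) +
#'  sigma sqrt((1 - exp(-2 theta dt)) / (2 theta)) eps`,
#' with `eps ~ N(0, 1)` and target equal to the setpoint (normal regime) or
#' ambient (failed regime). Exactness means the step size never biases the
#' stationary distribution, whose mean is the target and whose standard
#' deviation is `sigma / sqrt(2 theta)`.
#'
#' @param unit An [equipment_unit()].
#' @param dt_h Step length in hours (> 0).
#' @param stream An [rng_stream()] supplying the Gaussian innovation; `NULL`
#'   for the deterministic (`sigma = 0`) skeleton.
#' @return The new temperature in degree-C.
#' @export
step_temperature <- function(unit, dt_h, stream = NULL) {
  stopifnot(inherits(unit, "equipment_unit"))
  if (!is.numeric(dt_h) || dt_h <= 0) stop("dt_h must be > 0")
  theta <- unit$theta_per_h
  if (theta <= 0) stop("theta_per_h must be > 0")
  target <- if (identical(unit$regime, "failed")) unit$ambient_c else unit$setpoint_c
  decay <- exp(-theta * dt_h)
  sd_step <- unit$sigma_c * sqrt((1 - exp(-2 * theta * dt_h)) / (2 * theta))
  eps <- if (sd_step > 0) {
    if (is.null(stream)) stop("a stochastic step (sigma > 0) needs an rng stream")
    rng_rnorm(stream, 1L)
  } else 0
  target + (unit$temp_c - target) * decay + sd_step * eps
}

#' Reported value of a sensing window
#'
#' Temperatures are sensed once per hour for a 5-minute window; the record the
#' system stores is the arithmetic mean of the readings inside the window.
#'
#' @param readings Numeric vector of in-window readings (degree-C).
#' @return The window mean, or `NA_real_` (a missing-record gap marker) for an
#'   empty window.
#' @export
sample_window <- function(readings) {
  if (length(readings) == 0L) return(NA_real_)
  if (!all(is.finite(readings))) stop("non-finite reading in window")
  mean(readings)
}

#' Classify a reported temperature against the alert thresholds
#'
#' @param value Reported temperature, degree-C (vectorised).
#' @param thresholds A [threshold_config()].
#' @return `"low_alert"` if value < alert_low, `"high_alert"` if
#'   value > alert_high, else `"normal"`. Boundaries are strict.
#' @export
#' @examples
#' classify_reading(c(2.8, 5, 7.1))
classify_reading <- function(value, thresholds = threshold_config()) {
  if (!all(is.finite(value))) stop("non-finite temperature value")
  ifelse(value < thresholds$alert_low, "low_alert",
         ifelse(value > thresholds$alert_high, "high_alert", "normal"))
}

#' Build a temperature record table
#'
#' @param unit_id Unit identifier.
#' @param window_start Window start, minutes since simulation start.
#' @param value_c Reported window mean, degree-C.
#' @param duration_min Window length, minutes.
#' @param thresholds A [threshold_config()].
#' @return Data frame with columns `unit_id`, `window_start`, `duration_min`,
#'   `value_c`, `status`.
#' @export
temperature_record <- function(unit_id, window_start, value_c,
                               duration_min = 5, thresholds = threshold_config()) {
  if (any(duration_min <= 0)) stop("window duration must be > 0")
  data.frame(unit_id = unit_id, window_start = window_start,
             duration_min = duration_min, value_c = value_c,
             status = classify_reading(value_c, thresholds),
             stringsAsFactors = FALSE)
}

#' Detect excursion episodes in a record sequence
#'
#' An episode is a maximal run of records sharing the same non-normal status.
#' Missing windows (buffer gaps) do not terminate an episode: a run bridges a
#' time gap shorter than `bridge_windows` missing windows; a longer gap splits
#' it. The episode starts at its first non-normal window start and ends at the
#' first subsequent record's window start (or, for a run closing the sequence
#' or hitting a long gap, at its last record's window end).
#'
#' @param records Records for a single unit, sorted by `window_start`, as
#'   produced by [temperature_record()].
#' @param cadence_min Sensing cadence, minutes (default hourly).
#' @param bridge_windows Maximum number of consecutive missing windows an
#'   episode may bridge is `bridge_windows - 1` (default 2: one missing window
#'   bridges, two split).
#' @return Data frame with columns `unit_id`, `start`, `end`, `direction`,
#'   `peak_deviation`, `duration_min`, `n_windows`.
#' @export
detect_excursions <- function(records, cadence_min = 60, bridge_windows = 2) {
  empty <- data.frame(unit_id = character(0), start = numeric(0),
                      end = numeric(0), direction = character(0),
                      peak_deviation = numeric(0), duration_min = numeric(0),
                      n_windows = integer(0), stringsAsFactors = FALSE)
  if (nrow(records) == 0L) return(empty)
  if (length(unique(records$unit_id)) > 1L) {
    stop("detect_excursions expects records from a single unit")
  }
  if (is.unsorted(records$window_start, strictly = TRUE)) {
    stop("records must be sorted by window_start")
  }
  st <- records$status
  ts <- records$window_start
  dur <- records$duration_min
  n <- nrow(records)
  # new episode when status changes or the time gap spans >= bridge_windows
  # missing windows
  new_run <- c(TRUE, st[-1] != st[-n] | diff(ts) > bridge_windows * cadence_min)
  run_id <- cumsum(new_run)
  out <- list()
  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    if (st[idx[1]] == "normal") next
    last <- idx[length(idx)]
    nxt <- last + 1L
    end <- if (nxt <= n && ts[nxt] - ts[last] <= bridge_windows * cadence_min) {
      ts[nxt]
    } else {
      ts[last] + dur[last]
    }
    direction <- if (st[idx[1]] == "low_alert") "low" else "high"
    thr <- attr(records, "thresholds")
    lo <- if (is.null(thr)) 3 else thr$alert_low
    hi <- if (is.null(thr)) 7 else thr$alert_high
    peak <- if (direction == "low") max(lo - records$value_c[idx]) else
      max(records$value_c[idx] - hi)
    out[[length(out) + 1L]] <- data.frame(
      unit_id = records$unit_id[idx[1]], start = ts[idx[1]], end = end,
      direction = direction, peak_deviation = peak,
      duration_min = end - ts[idx[1]], n_windows = length(idx),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Register an equipment failure episode
#'
#' While failed, a unit's drift target becomes the ambient temperature, so an
#' ILR left failed for long enough will warm past the 7 degree-C alert
#' threshold. Failure intervals on the same unit must not overlap.
#'
#' @param failures Existing failure registry (data frame with `unit_id`,
#'   `start`, `duration_min`), or `NULL`.
#' @param unit_id Unit to fail.
#' @param start Failure onset, minutes since simulation start.
#' @param duration_min Failure length, minutes (> 0). The unit is failed on
#'   `[start, start + duration_min)` and reverts to normal afterwards.
#' @return The updated failure registry.
#' @export
inject_failure <- function(failures, unit_id, start, duration_min) {
  if (!is.numeric(duration_min) || duration_min <= 0) {
    stop("failure duration must be > 0")
  }
  new <- data.frame(unit_id = unit_id, start = start,
                    duration_min = duration_min, stringsAsFactors = FALSE)
  if (is.null(failures) || nrow(failures) == 0L) return(new)
  same <- failures[failures$unit_id == unit_id, , drop = FALSE]
  if (nrow(same) > 0L) {
    overlap <- start < same$start + same$duration_min &
      same$start < start + duration_min
    if (any(overlap)) stop("overlapping failure on unit ", unit_id)
  }
  rbind(failures, new)
}
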