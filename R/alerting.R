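# Alert construction (standardized message templates), role-based routing
# and per-episode deduplication.

#' Temperature alert message
#'
#' Direction-specific standardized text, with the thresholds interpolated:
#' `"Alert: Temperature below 3°C. Please verify storage conditions."` /
#' `"Alert: Temperature above 7°C. Please verify storage conditions."`.
#'
#' @param direction `"low"` or `"high"`.
#' @param thresholds A [threshold_config()].
#' @return Message string.
#' @export
format_temperature_alert <- function(direction = c("low", "high"),
                                     thresholds = threshold_config()) {
  direction <- match.arg(direction)
  if (direction == "low") {
    sprintf("Alert: Temperature below %s°C. Please verify storage conditions.",
            format(thresholds$alert_low))
  } else {
    sprintf("Alert: Temperature above %s°C. Please verify storage conditions.",
            format(thresholds$alert_high))
  }
}

#' Vaccination reminder message
#'
#' `"Vaccination Alert: {name} must receive the {vaccine} vaccine within {X}
#' days!"`; negative days remaining produce the overdue variant
#' `"Vaccination Alert: {name} is overdue for the {vaccine} vaccine!"`.
#'
#' @param patient_name Patient display name.
#' @param vaccine Vaccine name.
#' @param days_remaining Whole days until the due date (may be negative).
#' @return Message string.
#' @export
#' @examples
#' format_vaccination_alert("Alice", "BCG", 15)
format_vaccination_alert <- function(patient_name, vaccine, days_remaining) {
  if (days_remaining < 0) {
    sprintf("Vaccination Alert: %s is overdue for the %s vaccine!",
            patient_name, vaccine)
  } else {
    sprintf("Vaccination Alert: %s must receive the %s vaccine within %d days!",
            patient_name, vaccine, as.integer(days_remaining))
  }
}

#' Route an alert to recipient roles
#'
#' Temperature alerts go to the three staff roles (immunisation team, unit
#' manager, local health authority). Vaccination reminders go to the local
#' team (immunisation team and unit manager) plus the patient, or the legal
#' guardian when the patient is a minor.
#'
#' @param kind `"temp_low"`, `"temp_high"` or `"vaccination_reminder"`.
#' @param minor For reminders: is the patient a minor?
#' @return Character vector of roles.
#' @export
route_alert <- function(kind = c("temp_low", "temp_high", "vaccination_reminder"),
                        minor = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("temp_low", "temp_high")) {
    return(c("immunisation_team", "unit_manager", "local_authority"))
  }
  if (is.null(minor)) stop("reminder routing needs the minor flag")
  c("immunisation_team", "unit_manager", if (minor) "guardian" else "patient")
}

#' Construct an alert record
#'
#' @param kind Alert kind.
#' @param message Message string (see [format_temperature_alert()] and
#'   [format_vaccination_alert()]).
#' @param recipients Character vector of roles.
#' @param created_at Creation time (minutes since simulation start).
#' @param source Unit id or patient id.
#' @param channel Delivery-intent tag (metadata only), default
#'   `"SMS;WhatsApp"`.
#' @return A one-row data frame alert record (`delivered_at` is `NA` until
#'   the telemetry layer delivers it).
#' @export
make_alert <- function(kind, message, recipients, created_at, source,
                       channel = "SMS;WhatsApp") {
  data.frame(kind = kind, message = message,
             recipients = paste(recipients, collapse = ";"),
             created_at = created_at, delivered_at = NA_real_,
             source = source, channel = channel, stringsAsFactors = FALSE)
}

#' Deduplicate temperature alerts per excursion episode
#'
#' Scans a classified record stream and emits exactly one alert at each
#' excursion onset: an alert fires when a record is non-normal and the unit
#' was previously normal (or the status direction changed, or the same-status
#' run was broken by a gap of `bridge_windows` or more missing windows). No
#' further alert is emitted until the status returns to normal, after which a
#' fresh episode re-arms the unit.
#'
#' This is an independent stateful scan; on any gap-free stream its emitted
#' alerts are in bijection with the episodes found by [detect_excursions()].
#'
#' @param records Classified record data frame (`unit_id`, `window_start`,
#'   `value_c`, `status`), ordered by `window_start` within each unit.
#' @param thresholds A [threshold_config()].
#' @param cadence_min Sensing cadence, minutes.
#' @param bridge_windows Gap-bridging span (same meaning as in
#'   [detect_excursions()]).
#' @return Alert data frame (one row per episode onset) as built by
#'   [make_alert()], with creation time at the onset record's window start.
#' @export
dedup_temperature_alerts <- function(records, thresholds = threshold_config(),
                                     cadence_min = 60, bridge_windows = 2) {
  out <- list()
  for (uid in unique(records$unit_id)) {
    rec <- records[records$unit_id == uid, , drop = FALSE]
    if (is.unsorted(rec$window_start, strictly = TRUE)) {
      stop("records must be ordered by window_start within each unit")
    }
    last_status <- "normal"
    last_time <- -Inf
    for (i in seq_len(nrow(rec))) {
      st <- rec$status[i]
      gap_broken <- rec$window_start[i] - last_time > bridge_windows * cadence_min
      if (st != "normal" && (st != last_status || gap_broken)) {
        dir <- if (st == "low_alert") "low" else "high"
        kind <- paste0("temp_", dir)
        out[[length(out) + 1L]] <- make_alert(
          kind = kind,
          message = format_temperature_alert(dir, thresholds),
          recipients = route_alert(kind),
          created_at = rec$window_start[i],
          source = uid)
      }
      last_status <- st
      last_time <- rec$window_start[i]
    }
  }
  if (length(out) == 0L) {
    return(data.frame(kind = character(0), message = character(0),
                      recipients = character(0), created_at = numeric(0),
                      delivered_at = numeric(0), source = character(0),
                      channel = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
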