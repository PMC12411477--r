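# Scenario runner: couples the thermal, telemetry and immunisation processes
# on the discrete-event engine and emits the output bundle.

.min_to_iso <- function(t_min, start) {
  ifelse(is.na(t_min), NA_character_,
         format(start + round(t_min * 60), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
}

#' Run a scenario
#'
#' Executes a full scenario on the discrete-event engine: per-unit hourly
#' sensing windows (Ornstein-Uhlenbeck thermal dynamics, 30-second readings,
#' window-mean records), threshold classification, per-episode alert
#' deduplication, equipment-failure regime switches, store-and-forward
#' telemetry over the outage schedule, vaccination reminder ladders, dose
#' administration against the stock ledger, and end-of-horizon coverage and
#' indicator summaries. Everything is deterministic under the configured
#' seed: all randomness flows through named streams (one per component), and
#' event ties are broken by (time, priority, insertion order).
#'
#' @param config A `scenario_config` (see [default_config()],
#'   [scenario_preset()], [load_config()]).
#' @param out_dir Optional output directory; when given, the bundle is also
#'   written as CSV/JSON/JSONL files (see [write_bundle()]).
#' @return A `scenario_bundle` list: `temperature_log`, `trace`, `alerts`,
#'   `deliveries`, `dropped`, `vaccination_log`, `population`, `coverage`,
#'   `summary`, `events`, `config`.
#' @export
run_scenario <- function(config = scenario_preset("stable"), out_dir = NULL) {
  config <- validate_config(config)
  start <- as.POSIXct(paste0(config$start_date, " 00:00:00"), tz = "UTC")
  start_day <- as.Date(config$start_date)
  horizon_min <- config$horizon_days * 1440
  th <- threshold_config(config$thresholds$nominal_low,
                         config$thresholds$nominal_high,
                         config$thresholds$alert_low,
                         config$thresholds$alert_high)
  period <- config$cadence$period_min
  win <- config$cadence$window_min
  step_min <- config$cadence$intra_step_min
  link <- link_schedule(lapply(config$network$outages,
                               function(o) c(o$start_min, o$end_min)))
  buffer <- fifo_buffer(config$buffer$capacity)

  # mutable scenario state
  S <- new.env(parent = emptyenv())
  S$units <- list()
  for (e in config$equipment) {
    S$units[[e$id]] <- list(
      unit = equipment_unit(e$id, e$kind, e$setpoint_c, e$theta_per_h,
                            e$sigma_c, e$ambient_c),
      last_t = 0, last_status = "normal", last_status_t = -Inf,
      stream = rng_stream(config$seed, paste0("thermal/", e$id)))
  }
  S$records <- list()
  S$trace <- list()
  S$deliveries <- list()
  S$doses <- NULL
  S$stock <- NULL

  # advance a unit's thermal state to time to_t, tracing intermediate points
  # every gap_step_min so true threshold crossings between sensing windows
  # are localized for the response-time indicator
  gap_step_min <- 5
  advance_unit <- function(uid, to_t) {
    us <- S$units[[uid]]
    while (to_t > us$last_t) {
      t_next <- min(to_t, us$last_t + gap_step_min)
      us$unit$temp_c <- step_temperature(us$unit, (t_next - us$last_t) / 60,
                                         us$stream)
      us$last_t <- t_next
      S$trace[[length(S$trace) + 1L]] <-
        list(unit_id = uid, time_min = t_next, temp_c = us$unit$temp_c)
    }
    S$units[[uid]] <- us
    invisible(NULL)
  }

  env <- sim_env()

  # sensing windows: floor(H) per unit over H simulated hours
  n_win <- floor(horizon_min / period)
  for (uid in names(S$units)) {
    for (k in seq_len(n_win) - 1L) {
      sim_schedule(env, k * period, priority = 5L, type = "window", unit = uid)
    }
  }
  # failure regime switches fire before windows at the same instant
  failures <- NULL
  for (f in config$failures) {
    failures <- inject_failure(failures, f$unit_id, f$start_min, f$duration_min)
  }
  if (!is.null(failures)) {
    for (i in seq_len(nrow(failures))) {
      sim_schedule(env, failures$start[i], priority = 0L, type = "regime",
                   unit = failures$unit_id[i], regime = "failed")
      t_end <- failures$start[i] + failures$duration_min[i]
      if (t_end <= horizon_min) {
        sim_schedule(env, t_end, priority = 0L, type = "regime",
                     unit = failures$unit_id[i], regime = "normal")
      }
    }
  }
  # buffer flush at each reconnection, before any same-time transmission
  for (i in seq_len(nrow(link))) {
    if (link$end[i] <= horizon_min) {
      sim_schedule(env, link$end[i], priority = 1L, type = "reconnect")
    }
  }

  # population side: reminders and adherence-driven dose administration
  if (isTRUE(config$population$enabled)) {
    pop_stream <- rng_stream(config$seed, "population")
    adh_stream <- rng_stream(config$seed, "adherence")
    S$population <- generate_population(config$strata, start_day, pop_stream)
    antigens <- unique(config$schedule$antigen)
    S$stock <- do.call(vaccine_stock, as.list(stats::setNames(
      rep(config$population$stock_per_antigen, length(antigens)), antigens)))
    policy <- reminder_policy(config$reminder$under_1, config$reminder$over_1)
    end_day <- start_day + config$horizon_days
    for (i in seq_len(nrow(S$population))) {
      p <- S$population[i, ]
      pend <- pending_vaccines(p, config$schedule, NULL, start_day)
      for (j in seq_len(nrow(pend))) {
        entry <- pend[j, ]
        rem <- reminder_schedule(p, entry, policy, start_day)
        for (r in seq_len(nrow(rem))) {
          d <- rem$alert_date[r]
          if (d >= start_day && d < end_day) {
            sim_schedule(env, as.numeric(d - start_day) * 1440, priority = 4L,
                         type = "reminder", patient = p$id, name = p$name,
                         birth = as.character(p$birth_date),
                         antigen = entry$antigen,
                         lead_days = rem$lead_days[r])
          }
        }
        if (entry$due_date >= start_day && entry$due_date < end_day &&
            rng_runif(adh_stream, 1L) < config$population$adherence) {
          sim_schedule(env, as.numeric(entry$due_date - start_day) * 1440 + 600,
                       priority = 3L, type = "dose", patient = p$id,
                       antigen = entry$antigen, dose_index = entry$dose_index,
                       date = as.character(entry$due_date))
        }
      }
    }
  } else {
    S$population <- generate_population(NULL, start_day, NULL)
  }

  deliver <- function(msgs) {
    for (m in msgs) S$deliveries[[length(S$deliveries) + 1L]] <- m
  }

  handler <- function(env, ev) {
    t <- ev$t
    switch(ev$type,
      regime = {
        advance_unit(ev$unit, t)
        us <- S$units[[ev$unit]]
        us$unit$regime <- ev$regime
        S$units[[ev$unit]] <- us
      },
      window = {
        uid <- ev$unit
        advance_unit(uid, t)
        readings <- S$units[[uid]]$unit$temp_c
        n_step <- round(win / step_min)
        for (s in seq_len(n_step)) {
          advance_unit(uid, t + s * step_min)
          readings <- c(readings, S$units[[uid]]$unit$temp_c)
        }
        value <- sample_window(readings)
        status <- classify_reading(value, th)
        S$records[[length(S$records) + 1L]] <-
          list(unit_id = uid, window_start = t, duration_min = win,
               value_c = value, status = status)
        us <- S$units[[uid]]
        onset <- status != "normal" &&
          (status != us$last_status || t - us$last_status_t > 2 * period)
        us$last_status <- status
        us$last_status_t <- t
        S$units[[uid]] <- us
        sim_schedule(env, t + win, priority = 6L, type = "transmit",
                     msg = list(type = "temperature_record", unit_id = uid,
                                window_start = t, value_c = value,
                                status = status, created_at = t + win))
        if (onset) {
          dir <- if (status == "low_alert") "low" else "high"
          kind <- paste0("temp_", dir)
          sim_schedule(env, t + win, priority = 6L, type = "transmit",
                       msg = list(type = "alert", kind = kind,
                                  message = format_temperature_alert(dir, th),
                                  recipients = paste(route_alert(kind),
                                                     collapse = ";"),
                                  source = uid, created_at = t + win))
        }
      },
      transmit = deliver(transmit(ev$msg, t, link, buffer)),
      reconnect = deliver(flush_on_reconnect(buffer, t)),
      reminder = {
        minor <- age_years(as.Date(ev$birth), start_day + t / 1440) < 18
        kind <- "vaccination_reminder"
        msg <- list(type = "alert", kind = kind,
                    message = format_vaccination_alert(ev$name, ev$antigen,
                                                       ev$lead_days),
                    recipients = paste(route_alert(kind, minor = minor),
                                       collapse = ";"),
                    source = ev$patient, created_at = t)
        deliver(transmit(msg, t, link, buffer))
      },
      dose = {
        res <- tryCatch(
          record_dose(S$doses, S$stock, ev$patient, ev$antigen,
                      ev$dose_index, as.Date(ev$date)),
          error = function(e) NULL)
        if (!is.null(res)) {
          S$doses <- res$doses
          S$stock <- res$stock
        }
      })
    invisible(NULL)
  }

  sim_run(env, horizon_min, handler)

  # assemble the bundle ------------------------------------------------------
  rec_df <- if (length(S$records)) {
    do.call(rbind, lapply(S$records, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  } else {
    data.frame(unit_id = character(0), window_start = numeric(0),
               duration_min = numeric(0), value_c = numeric(0),
               status = character(0))
  }
  trace_df <- do.call(rbind, lapply(S$trace, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  dlv <- S$deliveries
  dlv_df <- if (length(dlv)) {
    do.call(rbind, lapply(dlv, function(m) data.frame(
      type = m$type,
      kind = if (is.null(m$kind)) NA_character_ else m$kind,
      source = if (is.null(m$source)) m$unit_id else m$source,
      created_at = m$created_at, delivered_at = m$delivered_at,
      stringsAsFactors = FALSE)))
  } else {
    data.frame(type = character(0), kind = character(0), source = character(0),
               created_at = numeric(0), delivered_at = numeric(0))
  }
  alerts_df <- if (length(dlv)) {
    al <- Filter(function(m) identical(m$type, "alert"), dlv)
    if (length(al)) do.call(rbind, lapply(al, function(m) data.frame(
      created_at = m$created_at, delivered_at = m$delivered_at,
      kind = m$kind, source = m$source, recipients = m$recipients,
      message = m$message, stringsAsFactors = FALSE))) else NULL
  } else NULL
  if (is.null(alerts_df)) {
    alerts_df <- data.frame(created_at = numeric(0), delivered_at = numeric(0),
                            kind = character(0), source = character(0),
                            recipients = character(0), message = character(0),
                            stringsAsFactors = FALSE)
  }

  end_day <- start_day + config$horizon_days
  coverage <- if (isTRUE(config$population$enabled) &&
                  nrow(S$population) > 0) {
    compute_coverage(S$population, config$schedule, S$doses, end_day)
  } else NULL

  # indicator summaries: per-unit stability (SD of reported values, fraction
  # of windows inside the alert band) and alert response times
  indicators <- list()
  for (uid in names(S$units)) {
    v <- rec_df$value_c[rec_df$unit_id == uid]
    if (length(v) >= 2) {
      indicators[[paste0("temperature/", uid)]] <- c(
        summarize_indicator(v),
        list(frac_in_band = mean(v >= th$alert_low & v <= th$alert_high)))
    }
  }
  temp_alerts <- alerts_df[alerts_df$kind %in% c("temp_low", "temp_high"), ,
                           drop = FALSE]
  rts <- alert_response_times(trace_df, temp_alerts, th)
  indicators[["alert_response_min"]] <- if (length(rts) >= 2) {
    summarize_indicator(rts)
  } else if (length(rts) == 1) {
    summarize_indicator(rts, level = NULL)
  } else NULL

  bundle <- structure(list(
    temperature_log = rec_df,
    trace = trace_df,
    alerts = alerts_df,
    deliveries = dlv_df,
    dropped = buffer$dropped,
    offered = buffer$offered,
    vaccination_log = S$doses,
    population = S$population,
    stock = S$stock,
    coverage = coverage,
    response_times = rts,
    summary = indicators,
    events = sim_event_log(env),
    start = start,
    config = config
  ), class = "scenario_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Write a scenario bundle to disk
#'
#' Emits `temperature_log.csv`, `alerts.csv`, `deliveries.jsonl`,
#' `vaccination_log.csv`, `population.csv`, `coverage.json` and
#' `summary.json` (all timestamps ISO-8601 UTC) into `out_dir`.
#'
#' @param bundle A `scenario_bundle` from [run_scenario()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  start <- bundle$start
  tl <- bundle$temperature_log
  tl$window_start <- .min_to_iso(tl$window_start, start)
  utils::write.csv(tl, file.path(out_dir, "temperature_log.csv"),
                   row.names = FALSE)
  al <- bundle$alerts
  al$created_at <- .min_to_iso(al$created_at, start)
  al$delivered_at <- .min_to_iso(al$delivered_at, start)
  utils::write.csv(al, file.path(out_dir, "alerts.csv"), row.names = FALSE)
  dl <- bundle$deliveries
  lines <- vapply(seq_len(nrow(dl)), function(i) {
    jsonlite::toJSON(list(type = dl$type[i], kind = dl$kind[i],
                          source = dl$source[i],
                          created_at = .min_to_iso(dl$created_at[i], start),
                          delivered_at = .min_to_iso(dl$delivered_at[i], start)),
                     auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  writeLines(lines, file.path(out_dir, "deliveries.jsonl"))
  vl <- bundle$vaccination_log
  if (is.null(vl)) {
    vl <- data.frame(patient_id = character(0), antigen = character(0),
                     dose_index = integer(0), date = character(0))
  }
  utils::write.csv(vl, file.path(out_dir, "vaccination_log.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$population, file.path(out_dir, "population.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$coverage)) {
    cov <- bundle$coverage
    nested <- list()
    for (i in seq_len(nrow(cov$by_entry))) {
      r <- cov$by_entry[i, ]
      key <- sprintf("%s/dose%d", r$antigen, r$dose_index)
      nested[[key]][[r$stratum]] <- list(
        eligible = r$eligible, vaccinated = r$vaccinated,
        coverage = r$coverage)
    }
    jsonlite::write_json(list(by_entry = nested, up_to_date = cov$up_to_date),
                         file.path(out_dir, "coverage.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  }
  jsonlite::write_json(
    c(bundle$summary, list(dropped = bundle$dropped, offered = bundle$offered)),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(out_dir)
}
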