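# Scenario configuration: defaults, YAML/JSON loading, validation and the
# preset library mirroring the three study conditions (stable operation,
# equipment malfunction, network outage).

#' Default scenario configuration
#'
#' Seven simulated days of one ILR sensed hourly for 5 minutes (readings
#' every 30 s inside the window), alert thresholds 3/7 degree-C inside the
#' nominal 2-8 degree-C band, the seven-stratum 100-patient population, the
#' illustrative schedule, reminder ladders 7/15/30 (under 1 year) and
#' 30/60/90 days (over 1 year), and an ample store-and-forward buffer.
#'
#' @return A `scenario_config` list.
#' @export
default_config <- function() {
  structure(list(
    horizon_days = 7,
    seed = 42L,
    start_date = "2025-01-01",
    thresholds = list(nominal_low = 2, nominal_high = 8,
                      alert_low = 3, alert_high = 7),
    cadence = list(period_min = 60, window_min = 5, intra_step_min = 0.5),
    equipment = list(list(id = "ILR-1", kind = "ILR", setpoint_c = 5,
                          theta_per_h = 0.5, sigma_c = 0.15, ambient_c = 25)),
    failures = list(),
    network = list(outages = list()),
    buffer = list(capacity = 10000L),
    population = list(enabled = TRUE, adherence = 0.9,
                      stock_per_antigen = 200L),
    strata = default_strata(),
    schedule = default_schedule(),
    reminder = list(under_1 = c(7, 15, 30), over_1 = c(30, 60, 90)),
    out_dir = NULL
  ), class = "scenario_config")
}

#' Scenario presets
#'
#' Named presets matching the three study conditions. Each differs from
#' `"stable"` only in the keys it claims to change:
#' * `"stable"`: the defaults; temperatures stay inside the alert band with
#'   overwhelming probability.
#' * `"malfunction"`: a 48-hour failure of unit `ILR-1` starting on day 2;
#'   the unit drifts toward the 25 degree-C ambient and crosses the
#'   7 degree-C threshold.
#' * `"network_outage"`: a 6-hour outage starting on day 2; records are
#'   buffered FIFO and flushed on reconnection with no drops under the
#'   default (ample) capacity.
#'
#' @param name Preset name.
#' @return A `scenario_config` list.
#' @export
scenario_preset <- function(name = c("stable", "malfunction", "network_outage")) {
  name <- match.arg(name)
  cfg <- default_config()
  if (name == "malfunction") {
    cfg$failures <- list(list(unit_id = "ILR-1", start_min = 1440,
                              duration_min = 2880))
  } else if (name == "network_outage") {
    cfg$network$outages <- list(list(start_min = 1440, end_min = 1800))
  }
  cfg$preset <- name
  cfg
}

#' List available presets
#' @return Character vector of preset names.
#' @export
list_presets <- function() c("stable", "malfunction", "network_outage")

.as_row_df <- function(x) {
  # YAML/JSON deliver a list of row-records; fold back into a data frame
  if (is.data.frame(x)) return(x)
  do.call(rbind, lapply(x, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Load and validate a scenario configuration file
#'
#' Reads YAML or JSON, overlays the values on [default_config()] (so a
#' minimal file such as `{horizon_days: 7}` inherits the 3/7 degree-C
#' thresholds, the hourly/5-minute cadence and the reference strata), and
#' validates the result. Unknown top-level keys produce a warning; schema
#' violations name the offending key.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `scenario_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- default_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown)) {
    warning("unknown configuration keys ignored: ",
            paste(unknown, collapse = ", "))
  }
  raw <- raw[intersect(names(raw), names(cfg))]
  if (!is.null(raw$strata)) raw$strata <- .as_row_df(raw$strata)
  if (!is.null(raw$schedule)) raw$schedule <- .as_row_df(raw$schedule)
  named_map <- function(x) {
    is.list(x) && !is.data.frame(x) && length(x) > 0 &&
      !is.null(names(x)) && all(nzchar(names(x)))
  }
  for (nm in names(raw)) {
    cfg[[nm]] <- if (named_map(cfg[[nm]]) && named_map(raw[[nm]])) {
      utils::modifyList(cfg[[nm]], raw[[nm]])
    } else {
      raw[[nm]]
    }
  }
  validate_config(cfg)
}

#' Validate a scenario configuration
#' @param cfg A `scenario_config` list.
#' @return The config, invisibly usable, after checks; stops with the
#'   offending key on violation.
#' @export
validate_config <- function(cfg) {
  if (!is.numeric(cfg$horizon_days) || cfg$horizon_days <= 0) {
    stop("horizon_days: must be > 0")
  }
  th <- cfg$thresholds
  threshold_config(th$nominal_low, th$nominal_high, th$alert_low, th$alert_high)
  if (length(cfg$equipment) == 0L) stop("equipment: at least one unit required")
  ids <- vapply(cfg$equipment, function(e) e$id, character(1))
  if (anyDuplicated(ids)) stop("equipment: duplicate unit ids")
  for (f in cfg$failures) {
    if (!f$unit_id %in% ids) stop("failures: unknown unit_id ", f$unit_id)
    if (f$duration_min <= 0) stop("failures: duration_min must be > 0")
  }
  link_schedule(lapply(cfg$network$outages,
                       function(o) c(o$start_min, o$end_min)))
  if (cfg$buffer$capacity < 1) stop("buffer: capacity must be >= 1")
  if (cfg$cadence$period_min <= 0 || cfg$cadence$window_min <= 0 ||
      cfg$cadence$window_min > cfg$cadence$period_min) {
    stop("cadence: need 0 < window_min <= period_min")
  }
  structure(cfg, class = "scenario_config")
}

#' Write fixture files
#'
#' `kind = "schedule"` writes the illustrative schedule CSV (BCG dose 1 at
#' due-age 30 days, Hepatitis B at birth and 60 days, adult tetanus
#' booster); `kind = "population"` realizes the seven reference strata as
#' 100 synthetic patients. Identical seeds yield identical files.
#'
#' @param kind `"schedule"` or `"population"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed (population only).
#' @param as_of Reference date for ages (population only).
#' @return The written file path, invisibly.
#' @export
generate_fixtures <- function(kind = c("schedule", "population"),
                              out_dir = ".", seed = 42L,
                              as_of = "2025-01-01") {
  kind <- match.arg(kind)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (kind == "schedule") {
    path <- file.path(out_dir, "schedule.csv")
    utils::write.csv(default_schedule(), path, row.names = FALSE)
  } else {
    path <- file.path(out_dir, "population.csv")
    pop <- generate_population(default_strata(), as_of,
                               rng_stream(seed, "population"))
    utils::write.csv(pop, path, row.names = FALSE)
  }
  invisible(path)
}
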