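# Shared test fixtures, built in code.

# a record table for one unit from a vector of statuses on the hourly grid,
# with values chosen to realize each status
records_from_statuses <- function(statuses, unit_id = "U1", cadence = 60,
                                  times = (seq_along(statuses) - 1) * cadence) {
  vals <- c(normal = 5, low_alert = 2.5, high_alert = 7.5)[statuses]
  temperature_record(unit_id, times, unname(vals))
}

random_status_stream <- function(n, p_excursion = 0.3) {
  sample(c("normal", "low_alert", "high_alert"), n, replace = TRUE,
         prob = c(1 - p_excursion, p_excursion / 2, p_excursion / 2))
}

# brute-force episode counter: independent oracle for the episode/alert
# bijection -- counts starts of maximal runs of identical non-normal status
count_episodes_bruteforce <- function(statuses) {
  n <- 0L
  prev <- "normal"
  for (s in statuses) {
    if (s != "normal" && s != prev) n <- n + 1L
    prev <- s
  }
  n
}

tiny_patient <- function(birth = "2024-12-01", id = "P001", name = "Alice") {
  data.frame(id = id, name = name, birth_date = as.Date(birth),
             stratum = "under_1", stringsAsFactors = FALSE)
}
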