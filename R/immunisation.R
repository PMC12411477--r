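# Stratified synthetic population, Cochran sample sizing, vaccination
# schedule engine: due dates, pending doses, reminder ladders, dose
# administration and coverage.

DAYS_PER_YEAR <- 365.25

#' Minimal sample size (Cochran, with finite-population correction)
#'
#' `n0 = z^2 p (1 - p) / e^2` with `z` the two-sided normal quantile for the
#' confidence level, corrected for a finite population of size `N` as
#' `n = ceil(n0 / (1 + (n0 - 1) / N))`. The default `p = 0.5` is the
#' maximum-variance (most conservative) choice.
#'
#' @param N Population size (`>= 1`; `Inf` drops the correction).
#' @param confidence Confidence level in (0, 1), default 0.95.
#' @param margin Margin of error in (0, 1], default 0.10.
#' @param p Anticipated proportion in \[0, 1\], default 0.5.
#' @return Minimal integer sample size.
#' @export
#' @examples
#' cochran_min_sample(3527)  # 94
cochran_min_sample <- function(N, confidence = 0.95, margin = 0.10, p = 0.5) {
  if (!is.numeric(N) || N < 1) stop("N must be >= 1")
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  if (margin <= 0 || margin > 1) stop("margin must be in (0, 1]")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  z <- stats::qnorm((1 + confidence) / 2)
  n0 <- z^2 * p * (1 - p) / margin^2
  if (is.infinite(N)) return(as.integer(ceiling(n0)))
  as.integer(ceiling(n0 / (1 + (n0 - 1) / N)))
}

#' Allocate a total sample across strata (largest-remainder rounding)
#'
#' Proportional allocation `n * w_i / sum(w)` rounded so the counts sum
#' exactly to `n`: floors first, then one extra unit per largest fractional
#' remainder, ties broken by stratum order.
#'
#' @param weights Non-negative stratum weights (sum > 0).
#' @param n Total sample size (>= 0).
#' @return Integer vector of per-stratum counts summing to `n`.
#' @export
allocate_strata <- function(weights, n) {
  if (any(weights < 0)) stop("weights must be >= 0")
  if (sum(weights) <= 0) stop("weights must not all be zero")
  if (n < 0) stop("n must be >= 0")
  exact <- n * weights / sum(weights)
  base <- floor(exact)
  short <- as.integer(round(n - sum(base)))
  if (short > 0) {
    frac <- exact - base
    extra <- order(-frac, seq_along(frac))[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' The seven-stratum reference population design
#'
#' Age strata (years, right-open) and drawn sample counts: under 1 (3),
#' 1-6 (7), 7-9 (3), 10-19 (8), 20-39 (23), 40-59 (28), 60+ (28); 100 in
#' total, drawn from a source population of 3,527 individuals.
#'
#' @return Data frame with columns `label`, `age_low`, `age_high`, `count`.
#' @export
default_strata <- function() {
  data.frame(
    label = c("under_1", "1-6", "7-9", "10-19", "20-39", "40-59", "60+"),
    age_low = c(0, 1, 7, 10, 20, 40, 60),
    age_high = c(1, 7, 10, 20, 40, 60, 90),
    count = c(3L, 7L, 3L, 8L, 23L, 28L, 28L),
    stringsAsFactors = FALSE
  )
}

.name_pool <- c(
  "Alice", "John", "Maria", "Jose", "Ana", "Pedro", "Luiza", "Carlos",
  "Beatriz", "Rafael", "Camila", "Lucas", "Julia", "Gabriel", "Laura",
  "Mateus", "Sofia", "Thiago", "Helena", "Bruno", "Clara", "Diego",
  "Isabela", "Felipe", "Marina", "Gustavo", "Alicia", "Renato", "Paula",
  "Vitor", "Carolina", "Andre", "Fernanda", "Rodrigo", "Patricia", "Sergio",
  "Adriana", "Marcelo", "Vanessa", "Eduardo")

#' Generate a synthetic stratified population
#'
#' Draws `count` patients per stratum with birth dates uniform over the ages
#' admissible for the stratum at `as_of` (age in `[age_low, age_high)`
#' years). Deterministic under the stream's seed.
#'
#' @param strata Data frame as from [default_strata()] (ranges must not
#'   overlap; counts >= 0).
#' @param as_of Reference `Date` at which ages are evaluated.
#' @param stream An [rng_stream()].
#' @return Data frame with columns `id`, `name`, `birth_date` (`Date`),
#'   `stratum`.
#' @export
generate_population <- function(strata, as_of, stream) {
  as_of <- as.Date(as_of)
  if (is.null(strata) || nrow(strata) == 0L) {
    return(data.frame(id = character(0), name = character(0),
                      birth_date = as.Date(character(0)),
                      stratum = character(0), stringsAsFactors = FALSE))
  }
  if (any(strata$count < 0)) stop("stratum counts must be >= 0")
  o <- order(strata$age_low)
  if (any(strata$age_high[o][-nrow(strata)] > strata$age_low[o][-1])) {
    stop("stratum age ranges must not overlap")
  }
  rows <- list()
  k <- 0L
  for (s in seq_len(nrow(strata))) {
    cnt <- strata$count[s]
    if (cnt == 0L) next
    lo_d <- ceiling(strata$age_low[s] * DAYS_PER_YEAR)
    hi_d <- ceiling(strata$age_high[s] * DAYS_PER_YEAR) - 1
    u <- rng_runif(stream, cnt)
    age_days <- lo_d + floor(u * (hi_d - lo_d + 1))
    nm <- .name_pool[1L + floor(rng_runif(stream, cnt) * length(.name_pool))]
    rows[[s]] <- data.frame(
      id = sprintf("P%03d", k + seq_len(cnt)),
      name = nm,
      birth_date = as_of - age_days,
      stratum = strata$label[s],
      stringsAsFactors = FALSE)
    k <- k + cnt
  }
  do.call(rbind, rows)
}

#' Age in whole years at a date
#' @param birth_date,at `Date`s.
#' @return Numeric age in years (`days / 365.25`).
#' @export
age_years <- function(birth_date, at) {
  as.numeric(as.Date(at) - as.Date(birth_date)) / DAYS_PER_YEAR
}

#' Default illustrative vaccination schedule
#'
#' BCG dose 1 due 30 days after birth, Hepatitis B doses at birth and 60
#' days, and an adult tetanus booster. Columns: `antigen`, `dose_index`,
#' `due_age_days`, `type`.
#'
#' @return Data frame schedule.
#' @export
default_schedule <- function() {
  data.frame(
    antigen = c("Hepatitis B", "BCG", "Hepatitis B", "tetanus"),
    dose_index = c(1L, 1L, 2L, 1L),
    due_age_days = c(0L, 30L, 60L, 3650L),
    type = c("routine", "routine", "routine", "routine"),
    stringsAsFactors = FALSE
  )
}

#' Due date of a schedule entry for a patient
#'
#' @param birth_date Patient birth `Date`.
#' @param due_age_days Due age in days since birth (>= 0).
#' @return `Date` = birth date + due-age days.
#' @export
due_date <- function(birth_date, due_age_days) {
  if (any(due_age_days < 0)) stop("due_age_days must be >= 0")
  as.Date(birth_date) + due_age_days
}

#' Pending vaccine doses for a patient
#'
#' Schedule entries with no matching administered dose, with their due date
#' and signed days remaining (negative = overdue).
#'
#' @param patient One-row data frame or list with `id` and `birth_date`.
#' @param schedule Schedule data frame ([default_schedule()] layout).
#' @param doses Vaccination log data frame (`patient_id`, `antigen`,
#'   `dose_index`, `date`), possibly empty or `NULL`.
#' @param as_of Evaluation `Date`.
#' @return Data frame `antigen`, `dose_index`, `due_age_days`, `due_date`,
#'   `days_remaining`.
#' @export
pending_vaccines <- function(patient, schedule, doses = NULL, as_of) {
  as_of <- as.Date(as_of)
  birth <- as.Date(patient$birth_date)
  if (is.null(doses) || nrow(doses) == 0L) {
    got <- character(0)
  } else {
    mine <- doses[doses$patient_id == patient$id, , drop = FALSE]
    got <- paste(mine$antigen, mine$dose_index)
  }
  key <- paste(schedule$antigen, schedule$dose_index)
  pend <- schedule[!(key %in% got), , drop = FALSE]
  dd <- due_date(birth, pend$due_age_days)
  out <- data.frame(antigen = pend$antigen, dose_index = pend$dose_index,
                    due_age_days = pend$due_age_days, due_date = dd,
                    days_remaining = as.numeric(dd - as_of),
                    stringsAsFactors = FALSE)
  out[order(out$due_date, out$antigen, out$dose_index), , drop = FALSE]
}

#' Reminder ladder policy
#'
#' Advance-notice leads before a due date: 7/15/30 days for patients under
#' 1 year old, 30/60/90 days for patients over 1 year old (age evaluated at
#' each alert's emission date).
#'
#' @param under_1,over_1 Positive lead vectors, days.
#' @return A `reminder_policy` list.
#' @export
reminder_policy <- function(under_1 = c(7, 15, 30), over_1 = c(30, 60, 90)) {
  if (any(under_1 <= 0) || any(over_1 <= 0)) stop("leads must be positive")
  structure(list(under_1 = sort(under_1), over_1 = sort(over_1)),
            class = "reminder_policy")
}

#' Reminder dates for one pending schedule entry
#'
#' One alert per policy lead whose emission date (`due - lead`) falls on or
#' after `enrollment`; each lead's ladder membership is judged by the
#' patient's age class at that emission date. If every lead date has already
#' passed, a single immediate alert is emitted at `enrollment` (its
#' `lead_days` is the signed days then remaining, negative when overdue).
#'
#' @param patient One-row data frame or list with `birth_date`.
#' @param entry One schedule entry (list or one-row data frame with
#'   `due_age_days`).
#' @param policy A [reminder_policy()].
#' @param enrollment Enrollment `Date`.
#' @return Data frame `alert_date`, `lead_days`, sorted by date.
#' @export
reminder_schedule <- function(patient, entry, policy = reminder_policy(),
                              enrollment) {
  enrollment <- as.Date(enrollment)
  birth <- as.Date(patient$birth_date)
  due <- due_date(birth, entry$due_age_days)
  leads <- sort(unique(c(policy$under_1, policy$over_1)), decreasing = TRUE)
  keep <- numeric(0)
  for (L in leads) {
    emit <- due - L
    if (emit < enrollment) next
    cls <- if (age_years(birth, emit) < 1) "under_1" else "over_1"
    if (L %in% policy[[cls]]) keep <- c(keep, L)
  }
  if (length(keep) == 0L) {
    return(data.frame(alert_date = enrollment,
                      lead_days = as.numeric(due - enrollment)))
  }
  data.frame(alert_date = due - keep, lead_days = keep)
}

#' Create a vaccine stock ledger
#' @param ... Named dose counts per antigen, e.g. `BCG = 10`.
#' @return Named numeric vector of class `vaccine_stock`.
#' @export
vaccine_stock <- function(...) {
  x <- c(...)
  if (any(x < 0)) stop("stock counts must be >= 0")
  structure(x, class = "vaccine_stock")
}

#' Record an administered dose
#'
#' Appends the dose to the vaccination log and decrements the stock ledger.
#' The dose index must be the next expected one for the patient/antigen, and
#' the antigen must be in stock.
#'
#' @param doses Vaccination log data frame (`patient_id`, `antigen`,
#'   `dose_index`, `date`), possibly empty or `NULL`.
#' @param stock A [vaccine_stock()].
#' @param patient_id,antigen,dose_index,date Dose being administered.
#' @return `list(doses = updated log, stock = updated ledger)`.
#' @export
record_dose <- function(doses, stock, patient_id, antigen, dose_index, date) {
  if (is.null(doses)) {
    doses <- data.frame(patient_id = character(0), antigen = character(0),
                        dose_index = integer(0), date = as.Date(character(0)),
                        stringsAsFactors = FALSE)
  }
  have <- stock[antigen]
  if (is.na(have) || have < 1) stop("stock depleted for antigen ", antigen)
  prev <- doses[doses$patient_id == patient_id & doses$antigen == antigen, ,
                drop = FALSE]
  expected <- if (nrow(prev) == 0L) 1L else max(prev$dose_index) + 1L
  if (dose_index != expected) {
    stop(sprintf("out-of-order dose for %s/%s: got %d, expected %d",
                 patient_id, antigen, dose_index, expected))
  }
  stock[antigen] <- have - 1
  doses <- rbind(doses, data.frame(patient_id = patient_id, antigen = antigen,
                                   dose_index = as.integer(dose_index),
                                   date = as.Date(date),
                                   stringsAsFactors = FALSE))
  list(doses = doses, stock = stock)
}

#' Vaccination coverage report
#'
#' For every schedule entry and stratum: the fraction of patients already
#' past the entry's due age at `as_of` (the eligible denominator) who have
#' the dose recorded. Strata with no eligible patients report `NA` coverage
#' (serialized as `null`), not 0, so newborns are never counted as missed.
#' Also reports the overall up-to-date fraction: patients with no overdue
#' pending entry.
#'
#' @param patients Population data frame ([generate_population()] layout).
#' @param schedule Schedule data frame.
#' @param doses Vaccination log data frame (possibly empty or `NULL`).
#' @param as_of Evaluation `Date`.
#' @return List with `by_entry` (data frame `antigen`, `dose_index`,
#'   `stratum`, `eligible`, `vaccinated`, `coverage`) and `up_to_date`
#'   (fraction of patients with no overdue entry).
#' @export
compute_coverage <- function(patients, schedule, doses = NULL, as_of) {
  as_of <- as.Date(as_of)
  if (is.null(doses)) {
    doses <- data.frame(patient_id = character(0), antigen = character(0),
                        dose_index = integer(0), stringsAsFactors = FALSE)
  }
  age_days <- as.numeric(as_of - as.Date(patients$birth_date))
  strata <- unique(patients$stratum)
  rows <- list()
  for (e in seq_len(nrow(schedule))) {
    ant <- schedule$antigen[e]
    di <- schedule$dose_index[e]
    has <- patients$id %in% doses$patient_id[doses$antigen == ant &
                                               doses$dose_index == di]
    eligible <- age_days >= schedule$due_age_days[e]
    for (s in strata) {
      in_s <- patients$stratum == s
      n_elig <- sum(eligible & in_s)
      n_vac <- sum(eligible & in_s & has)
      rows[[length(rows) + 1L]] <- data.frame(
        antigen = ant, dose_index = di, stratum = s,
        eligible = n_elig, vaccinated = n_vac,
        coverage = if (n_elig > 0) n_vac / n_elig else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  by_entry <- if (length(rows)) do.call(rbind, rows) else
    data.frame(antigen = character(0), dose_index = integer(0),
               stratum = character(0), eligible = integer(0),
               vaccinated = integer(0), coverage = numeric(0))
  overdue <- vapply(seq_len(nrow(patients)), function(i) {
    p <- patients[i, ]
    pend <- pending_vaccines(p, schedule, doses, as_of)
    any(pend$days_remaining < 0)
  }, logical(1))
  list(by_entry = by_entry,
       up_to_date = if (nrow(patients) > 0) mean(!overdue) else NA_real_)
}
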