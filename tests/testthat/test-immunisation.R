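test_that("Cochran sizing with finite-population correction matches the closed form", {
  # z = qnorm(0.975), n0 = z^2 * 0.25 / 0.01 = 96.04; FPC at N=3527 -> 93.52
  expect_equal(cochran_min_sample(3527, 0.95, 0.10, 0.5), 94L)
  expect_equal(cochran_min_sample(Inf, 0.95, 0.10, 0.5), 97L)
  expect_equal(cochran_min_sample(1000, 0.95, 0.10, 0), 0L)
  expect_error(cochran_min_sample(0), "N")
  expect_error(cochran_min_sample(100, confidence = 1.2), "confidence")

  # monotonicity: non-increasing in margin; FPC result <= no-FPC result
  margins <- c(0.02, 0.05, 0.10, 0.20)
  n_by_margin <- vapply(margins, function(e)
    cochran_min_sample(5000, margin = e), integer(1))
  expect_true(all(diff(n_by_margin) <= 0))
  for (N in c(50, 500, 5000)) {
    expect_lte(cochran_min_sample(N), cochran_min_sample(Inf))
  }
})

test_that("largest-remainder allocation sums to n with in-order tie-breaks", {
  expect_equal(allocate_strata(c(.03, .07, .03, .08, .23, .28, .28), 100),
               c(3L, 7L, 3L, 8L, 23L, 28L, 28L))
  expect_equal(allocate_strata(rep(1 / 3, 3), 10), c(4L, 3L, 3L))
  expect_equal(allocate_strata(c(1, 2, 3), 0), c(0L, 0L, 0L))
  expect_error(allocate_strata(c(0, 0), 5), "zero")

  set.seed(5)
  for (i in 1:50) {
    w <- runif(sample(2:8, 1))
    n <- sample(0:200, 1)
    expect_equal(sum(allocate_strata(w, n)), n)
  }
})

test_that("synthetic population realizes the stratum design deterministically", {
  as_of <- as.Date("2025-01-01")
  pop <- generate_population(default_strata(), as_of, rng_stream(42, "population"))
  expect_equal(nrow(pop), 100)
  expect_equal(as.vector(table(factor(pop$stratum,
                                      levels = default_strata()$label))),
               default_strata()$count)
  age <- age_years(pop$birth_date, as_of)
  expect_equal(sum(age < 1), 3)
  # every age lies inside its stratum's [low, high) range
  st <- default_strata()
  for (i in seq_len(nrow(st))) {
    a <- age[pop$stratum == st$label[i]]
    expect_true(all(a >= st$age_low[i] & a < st$age_high[i]))
  }

  pop2 <- generate_population(default_strata(), as_of, rng_stream(42, "population"))
  expect_identical(pop, pop2)
  expect_equal(nrow(generate_population(NULL, as_of, NULL)), 0)
})

test_that("due dates use calendar arithmetic", {
  expect_equal(due_date(as.Date("2024-01-01"), 30), as.Date("2024-01-31"))
  expect_equal(due_date(as.Date("2024-01-01"), 0), as.Date("2024-01-01"))
  expect_equal(due_date(as.Date("2024-02-15"), 60), as.Date("2024-04-15"))
  expect_error(due_date(as.Date("2024-01-01"), -1), "due_age")
})

test_that("pending doses and the signed days-remaining convention", {
  p <- tiny_patient(birth = "2024-12-01")
  sched <- data.frame(antigen = "BCG", dose_index = 1L, due_age_days = 30L,
                      type = "routine", stringsAsFactors = FALSE)
  pend <- pending_vaccines(p, sched, NULL, as_of = "2024-12-01")
  expect_equal(nrow(pend), 1)
  expect_equal(pend$days_remaining, 30)

  # 10 days past due -> -10
  pend2 <- pending_vaccines(p, sched, NULL, as_of = "2025-01-10")
  expect_equal(pend2$days_remaining, -10)

  # administered dose removes the entry
  doses <- data.frame(patient_id = "P001", antigen = "BCG", dose_index = 1L,
                      date = as.Date("2024-12-20"), stringsAsFactors = FALSE)
  expect_equal(nrow(pending_vaccines(p, sched, doses, "2025-01-10")), 0)
})

test_that("reminder ladders: leads by age class, skipped past leads, overdue rule", {
  # infant, due 30 days after enrollment -> alerts at due-30, due-15, due-7
  p <- tiny_patient(birth = "2025-01-01")
  entry <- list(due_age_days = 30)
  rem <- reminder_schedule(p, entry, reminder_policy(), enrollment = "2025-01-01")
  due <- as.Date("2025-01-31")
  expect_equal(rem$alert_date, due - c(30, 15, 7))
  expect_equal(rem$lead_days, c(30, 15, 7))

  # adult, due in 60 days -> leads 60 and 30; the 90-day lead has passed
  adult <- tiny_patient(birth = "1990-01-01")
  entry_a <- list(due_age_days = as.numeric(as.Date("2025-03-02") -
                                              as.Date("1990-01-01")))
  rem_a <- reminder_schedule(adult, entry_a, reminder_policy(),
                             enrollment = "2025-01-01")
  expect_equal(rem_a$lead_days, c(60, 30))

  # due tomorrow, infant: all leads past -> one immediate alert at enrollment
  p2 <- tiny_patient(birth = "2024-12-03")
  rem2 <- reminder_schedule(p2, list(due_age_days = 30), reminder_policy(),
                            enrollment = "2025-01-01")
  expect_equal(nrow(rem2), 1)
  expect_equal(rem2$alert_date, as.Date("2025-01-01"))
  expect_equal(rem2$lead_days, 1)

  # overdue entry: single alert with negative days remaining
  rem3 <- reminder_schedule(p2, list(due_age_days = 10), reminder_policy(),
                            enrollment = "2025-01-01")
  expect_equal(rem3$lead_days, -19)

  # reminder count <= number of leads; equals leads inside [enrollment, due]
  set.seed(3)
  for (i in 1:40) {
    birth <- as.Date("2025-01-01") - sample(0:30000, 1)
    da <- sample(0:200, 1)
    pr <- tiny_patient(birth = as.character(birth))
    r <- reminder_schedule(pr, list(due_age_days = da), reminder_policy(),
                           enrollment = "2025-01-01")
    expect_lte(nrow(r), 3)
    expect_true(all(r$alert_date >= as.Date("2025-01-01")))
    expect_true(all(r$alert_date <= birth + da | nrow(r) == 1))
  }
})

test_that("dose recording enforces stock and dose order, conserving stock", {
  stock <- vaccine_stock(BCG = 2, tetanus = 0)
  res <- record_dose(NULL, stock, "P001", "BCG", 1L, "2025-01-05")
  expect_equal(unname(res$stock["BCG"]), 1)
  expect_equal(nrow(res$doses), 1)
  expect_error(record_dose(res$doses, res$stock, "P002", "tetanus", 1L,
                           "2025-01-05"), "stock")
  expect_error(record_dose(res$doses, res$stock, "P001", "BCG", 3L,
                           "2025-01-06"), "out-of-order")
  res2 <- record_dose(res$doses, res$stock, "P001", "BCG", 2L, "2025-02-05")
  expect_equal(unname(res2$stock["BCG"]), 0)
  # conservation: initial - administered = remaining >= 0
  expect_equal(2 - nrow(res2$doses[res2$doses$antigen == "BCG", ]),
               unname(res2$stock["BCG"]))
})

test_that("coverage: eligible denominators, null for empty ones, monotone in doses", {
  patients <- data.frame(
    id = c("P1", "P2", "P3", "P4"),
    name = c("a", "b", "c", "d"),
    birth_date = as.Date(c("2024-10-01", "2024-10-15", "2024-11-01",
                           "2024-12-25")),
    stratum = "under_1", stringsAsFactors = FALSE)
  sched <- data.frame(antigen = "BCG", dose_index = 1L, due_age_days = 30L,
                      type = "routine", stringsAsFactors = FALSE)
  doses <- data.frame(patient_id = c("P1", "P2"), antigen = "BCG",
                      dose_index = 1L, date = as.Date("2024-11-20"),
                      stringsAsFactors = FALSE)
  # as of 2025-01-01: P1..P3 are past due-age (eligible), P4 is 7 days old
  cov <- compute_coverage(patients, sched, doses, "2025-01-01")
  row <- cov$by_entry
  expect_equal(row$eligible, 3)
  expect_equal(row$vaccinated, 2)
  expect_equal(row$coverage, 2 / 3, tolerance = 1e-12)
  expect_equal(cov$up_to_date, 3 / 4)  # P3 overdue; P4 not yet due

  # nobody eligible yet -> NA, not zero
  cov0 <- compute_coverage(patients[4, ], sched, NULL, "2024-12-26")
  expect_true(is.na(cov0$by_entry$coverage))

  # monotone non-decreasing as doses accrue
  doses2 <- rbind(doses, data.frame(patient_id = "P3", antigen = "BCG",
                                    dose_index = 1L,
                                    date = as.Date("2024-12-30")))
  cov2 <- compute_coverage(patients, sched, doses2, "2025-01-01")
  expect_gte(cov2$by_entry$coverage, cov$by_entry$coverage)
  expect_equal(cov2$by_entry$coverage, 1)
  expect_equal(cov2$up_to_date, 1)
})
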