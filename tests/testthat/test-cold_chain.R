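test_that("deterministic OU step follows the exact-discretization closed form", {
  u <- equipment_unit("a", setpoint_c = 5, theta_per_h = log(2), sigma_c = 0,
                      temp_c = 7)
  expect_equal(step_temperature(u, 1), 6.0)

  # setpoint is a fixed point
  u$temp_c <- 5
  expect_equal(step_temperature(u, 1), 5.0)

  # with sigma = 0 under the normal regime, |T - mu| is non-increasing
  u$temp_c <- 9
  gaps <- numeric(20)
  for (i in 1:20) {
    u$temp_c <- step_temperature(u, 0.3)
    gaps[i] <- abs(u$temp_c - 5)
  }
  expect_true(all(diff(gaps) <= 0))

  expect_error(equipment_unit("a", theta_per_h = 0), "theta")
  expect_error(step_temperature(u, 0), "dt")
})

test_that("failed regime drifts toward ambient and crosses the high threshold,
           then relaxes back", {
  u <- equipment_unit("a", setpoint_c = 5, theta_per_h = 0.5, sigma_c = 0,
                      ambient_c = 25, regime = "failed")
  temps <- numeric(48)
  for (h in 1:48) {
    u$temp_c <- step_temperature(u, 1)
    temps[h] <- u$temp_c
  }
  expect_true(any(temps > 7))
  expect_lt(min(which(temps > 7)), 2)  # theta=0.5/h crosses within ~13 min
  expect_equal(temps[48], 25, tolerance = 1e-6)

  u$regime <- "normal"
  for (h in 1:48) u$temp_c <- step_temperature(u, 1)
  expect_equal(u$temp_c, 5, tolerance = 1e-6)
})

test_that("window sampling reports the arithmetic mean and flags empty windows", {
  expect_equal(sample_window(c(4.9, 5.0, 5.1)), 5.0)
  expect_equal(sample_window(2.8), 2.8)
  expect_equal(sample_window(c(6.9, 7.3)), 7.1)
  expect_true(is.na(sample_window(numeric(0))))
  expect_error(sample_window(c(5, NaN)), "non-finite")
})

test_that("classification matches the strict 3/7 boundaries, including the
           worked-example readings", {
  expect_equal(classify_reading(2.8), "low_alert")
  expect_equal(classify_reading(7.1), "high_alert")
  expect_equal(classify_reading(5.0), "normal")
  # boundaries are strict: exactly 3 and 7 are normal
  expect_equal(classify_reading(c(3, 7)), c("normal", "normal"))
  expect_error(classify_reading(NA_real_), "non-finite")

  # oracle equivalence: brute-force sweep 0.0..10.0 by 0.1
  v <- round(seq(0, 10, by = 0.1), 1)
  oracle <- ifelse(v < 3, "low_alert", ifelse(v > 7, "high_alert", "normal"))
  expect_identical(classify_reading(v), oracle)

  # custom thresholds propagate
  th <- threshold_config(alert_low = 2.5, alert_high = 7.5)
  expect_equal(classify_reading(2.6, th), "normal")
  expect_error(threshold_config(alert_low = 8), "thresholds")
})

test_that("excursion episodes are maximal runs of identical non-normal status", {
  r <- records_from_statuses(c("normal", "normal", "low_alert", "low_alert",
                               "normal"))
  ep <- detect_excursions(r)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$direction, "low")
  expect_equal(ep$start, 120)
  expect_equal(ep$end, 240)  # first subsequent normal window start
  expect_equal(ep$n_windows, 2)

  expect_equal(nrow(detect_excursions(records_from_statuses(rep("normal", 5)))), 0)

  # a status change splits runs
  ep2 <- detect_excursions(records_from_statuses(c("low_alert", "normal",
                                                   "high_alert")))
  expect_equal(ep2$direction, c("low", "high"))
  # trailing episode ends at its last record's window end
  expect_equal(ep2$end[2], 120 + 5)

  expect_error(detect_excursions(r[c(2, 1, 3, 4, 5), ]), "sorted")
})

test_that("episodes bridge a single missing window but split on longer gaps", {
  # windows at 0, 60, 180 (one missing), same low status: one episode
  r <- temperature_record("U1", c(0, 60, 180), c(2.5, 2.4, 2.6))
  expect_equal(nrow(detect_excursions(r)), 1)
  # gap of two missing windows (0 -> 240): split
  r2 <- temperature_record("U1", c(0, 240), c(2.5, 2.6))
  expect_equal(nrow(detect_excursions(r2)), 2)
})

test_that("episode records and normal gaps reconstruct the record sequence", {
  set.seed(11)
  for (rep in 1:20) {
    st <- random_status_stream(40)
    r <- records_from_statuses(st)
    ep <- detect_excursions(r)
    inside <- rep(FALSE, nrow(r))
    for (i in seq_len(nrow(ep))) {
      idx <- r$window_start >= ep$start[i] & r$window_start < ep$end[i]
      # every record inside an episode carries the matching non-normal status
      expect_true(all(r$status[idx] ==
                        paste0(ep$direction[i], "_alert")))
      inside <- inside | idx
    }
    # everything outside all episodes is normal
    expect_true(all(r$status[!inside] == "normal"))
  }
})

test_that("failure registration enforces positive duration and no overlap", {
  f <- inject_failure(NULL, "U1", 100, 60)
  expect_equal(nrow(f), 1)
  f <- inject_failure(f, "U1", 200, 60)       # disjoint, same unit
  f <- inject_failure(f, "U2", 120, 60)       # overlap on another unit is fine
  expect_equal(nrow(f), 3)
  expect_error(inject_failure(f, "U1", 150, 60), "overlap")
  expect_error(inject_failure(f, "U1", 500, 0), "duration")
})

test_that("stationary moments of the stochastic OU step match theory", {
  u <- equipment_unit("a", setpoint_c = 5, theta_per_h = 0.5, sigma_c = 0.15)
  s <- rng_stream(1, "thermal")
  n <- 20000L
  x <- numeric(n)
  for (i in seq_len(n)) {
    u$temp_c <- step_temperature(u, 1, s)
    x[i] <- u$temp_c
  }
  phi <- exp(-0.5)
  s_st <- 0.15 / sqrt(2 * 0.5)
  se_mean <- s_st / sqrt(n) * sqrt((1 + phi) / (1 - phi))
  n_eff <- n * (1 - phi) / (1 + phi)
  se_sd <- s_st / sqrt(2 * n_eff)
  expect_lt(abs(mean(x) - 5), 3 * se_mean)
  expect_lt(abs(sd(x) - s_st), 3 * se_sd)
})
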