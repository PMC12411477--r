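msg <- function(id, at) list(id = id, created_at = at)

test_that("link-up transmissions deliver immediately with delivered_at = at", {
  link <- link_schedule()
  buf <- fifo_buffer(10)
  out <- transmit(msg("r1", 100), 100, link, buf)
  expect_length(out, 1)
  expect_equal(out[[1]]$delivered_at, 100)
  expect_equal(out[[1]]$created_at, 100)
  expect_equal(buffer_size(buf), 0)
})

test_that("outages buffer FIFO; overflow drops the oldest and counts it", {
  link <- link_schedule(list(c(0, 1000)))
  expect_false(link_up(link, 500))
  expect_true(link_up(link, 1000))  # right-open interval

  buf <- fifo_buffer(2)
  expect_length(transmit(msg("r1", 10), 10, link, buf), 0)
  transmit(msg("r2", 20), 20, link, buf)
  expect_equal(vapply(buf$queue, `[[`, character(1), "id"), c("r1", "r2"))
  transmit(msg("r3", 30), 30, link, buf)
  expect_equal(vapply(buf$queue, `[[`, character(1), "id"), c("r2", "r3"))
  expect_equal(buf$dropped, 1)
})

test_that("flush on reconnect delivers in order, stamping delivery not creation", {
  link <- link_schedule(list(c(600, 720)))  # outage 10:00-12:00
  buf <- fifo_buffer(10)
  transmit(msg("r1", 605), 605, link, buf)  # created 10:05 during outage
  transmit(msg("r2", 665), 665, link, buf)
  out <- flush_on_reconnect(buf, 720)
  expect_equal(vapply(out, `[[`, character(1), "id"), c("r1", "r2"))
  expect_equal(vapply(out, `[[`, numeric(1), "delivered_at"), c(720, 720))
  expect_equal(vapply(out, `[[`, numeric(1), "created_at"), c(605, 665))
  expect_equal(buffer_size(buf), 0)
  expect_length(flush_on_reconnect(buf, 721), 0)
})

test_that("conservation and FIFO order hold under randomized outage schedules", {
  set.seed(23)
  for (rep in 1:40) {
    # random disjoint outages over a 0..2000 min horizon
    k <- sample(0:4, 1)
    bounds <- sort(sample(seq(0, 2000, by = 10), 2 * k))
    outages <- if (k > 0) lapply(seq_len(k), function(i)
      c(bounds[2 * i - 1], bounds[2 * i])) else NULL
    # drop zero-length intervals
    outages <- Filter(function(o) o[2] > o[1], outages)
    link <- link_schedule(outages)
    cap <- sample(c(2, 5, 1000), 1)
    buf <- fifo_buffer(cap)
    delivered <- list()
    times <- sort(sample(0:2000, 60))
    for (i in seq_along(times)) {
      delivered <- c(delivered,
                     transmit(msg(paste0("m", i), times[i]), times[i], link, buf))
      # reconnect flush at each outage end passed since the last send
      if (i < length(times)) {
        ends <- link$end[link$end > times[i] & link$end <= times[i + 1]]
        for (e in ends) delivered <- c(delivered, flush_on_reconnect(buf, e))
      }
    }
    # conservation at the end of the run
    expect_equal(buf$offered,
                 buf$delivered + buffer_size(buf) + buf$dropped)
    expect_equal(length(delivered) + buffer_size(buf) + buf$dropped, 60)
    # delivered ids form an in-order subsequence of the generated sequence
    ids <- as.integer(sub("m", "", vapply(delivered, `[[`, character(1), "id")))
    expect_true(all(diff(ids) > 0))
    # delivery never precedes creation
    expect_true(all(vapply(delivered, function(m)
      m$delivered_at >= m$created_at, logical(1))))
    # ample capacity means no drops
    if (cap == 1000) expect_equal(buf$dropped, 0)
  }
})
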