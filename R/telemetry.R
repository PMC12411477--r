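# Store-and-forward link between sensing and the twin: outage windows,
# bounded FIFO buffer, ordered flush, delivery timestamps.

#' Network link schedule
#'
#' @param outages List of `c(start, end)` pairs or a two-column data frame /
#'   matrix of right-open outage intervals (minutes); must be disjoint and
#'   sorted.
#' @return A `link_schedule` data frame with columns `start`, `end`.
#' @export
link_schedule <- function(outages = NULL) {
  if (is.null(outages) || length(outages) == 0L) {
    out <- data.frame(start = numeric(0), end = numeric(0))
  } else if (is.data.frame(outages)) {
    out <- outages[, c("start", "end")]
  } else if (is.matrix(outages)) {
    out <- data.frame(start = outages[, 1], end = outages[, 2])
  } else {
    out <- data.frame(start = vapply(outages, `[`, numeric(1), 1),
                      end = vapply(outages, `[`, numeric(1), 2))
  }
  if (nrow(out) > 0) {
    if (any(out$end <= out$start)) stop("outage intervals must have end > start")
    o <- order(out$start)
    out <- out[o, , drop = FALSE]
    if (nrow(out) > 1 && any(out$start[-1] < out$end[-nrow(out)])) {
      stop("outage intervals must be disjoint")
    }
  }
  structure(out, class = c("link_schedule", "data.frame"))
}

#' Is the link up at a given time?
#' @param link A [link_schedule()].
#' @param at Time, minutes.
#' @return Logical.
#' @export
link_up <- function(link, at) {
  !any(at >= link$start & at < link$end)
}

#' Bounded FIFO store-and-forward buffer
#'
#' Mutable (environment-backed) queue preserving arrival order. On overflow
#' the oldest buffered record is dropped — the freshest state is what the
#' twin needs — and the drop is counted. Conservation counters (`offered`,
#' `delivered`, `dropped`) are maintained so that at every instant
#' `offered == delivered + buffered + dropped`.
#'
#' @param capacity Maximum number of buffered records (>= 1).
#' @return A `fifo_buffer` environment.
#' @export
fifo_buffer <- function(capacity = 10000L) {
  stopifnot(capacity >= 1)
  b <- new.env(parent = emptyenv())
  b$capacity <- as.integer(capacity)
  b$queue <- list()
  b$offered <- 0L
  b$delivered <- 0L
  b$dropped <- 0L
  class(b) <- "fifo_buffer"
  b
}

#' Buffer occupancy
#' @param buffer A [fifo_buffer()].
#' @return Number of records currently buffered.
#' @export
buffer_size <- function(buffer) length(buffer$queue)

#' Transmit a record over the monitored link
#'
#' If the link is up the record is delivered immediately
#' (`delivered_at = at`), after first flushing anything still buffered (in
#' FIFO order) so delivery order is never inverted. If the link is down the
#' record is enqueued; when the queue is full the oldest buffered record is
#' dropped and counted.
#'
#' @param record A list or one-row data frame with a `created_at` field;
#'   original timestamps are never modified.
#' @param at Transmission attempt time, minutes.
#' @param link A [link_schedule()].
#' @param buffer A [fifo_buffer()] (mutated in place).
#' @return List of records delivered by this call (possibly empty), each with
#'   `delivered_at` set to `at`.
#' @export
transmit <- function(record, at, link, buffer) {
  buffer$offered <- buffer$offered + 1L
  if (link_up(link, at)) {
    delivered <- flush_on_reconnect(buffer, at)
    record$delivered_at <- at
    buffer$delivered <- buffer$delivered + 1L
    c(delivered, list(record))
  } else {
    if (length(buffer$queue) >= buffer$capacity) {
      buffer$queue <- buffer$queue[-1L]
      buffer$dropped <- buffer$dropped + 1L
    }
    buffer$queue[[length(buffer$queue) + 1L]] <- record
    list()
  }
}

#' Flush the buffer on reconnection
#'
#' Delivers every buffered record in FIFO order with `delivered_at = at`,
#' leaving original creation timestamps untouched, and empties the buffer.
#'
#' @param buffer A [fifo_buffer()] (mutated in place).
#' @param at Reconnection time, minutes.
#' @return List of delivered records.
#' @export
flush_on_reconnect <- function(buffer, at) {
  out <- lapply(buffer$queue, function(r) {
    r$delivered_at <- at
    r
  })
  buffer$delivered <- buffer$delivered + length(out)
  buffer$queue <- list()
  out
}
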