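# Minimal deterministic discrete-event engine: simulation clock, event queue,
# named seeded RNG streams. Time unit is minutes (real-valued).

#' Create a discrete-event simulation environment
#'
#' The environment holds a clock (minutes since simulation start), a pending
#' event queue and a log of dispatched events. Events are dispatched in strict
#' `(time, priority, seq)` order, where `seq` is the insertion counter, so a
#' given scenario replays identically.
#'
#' @return An environment of class `sim_env`.
#' @export
#' @examples
#' env <- sim_env()
#' sim_schedule(env, 10, type = "b")
#' sim_schedule(env, 5, type = "a")
#' log <- sim_run(env, until = 100)
#' log$type  # "a" then "b"
sim_env <- function() {
  env <- new.env(parent = emptyenv())
  env$now <- 0
  env$seq <- 0L
  env$time <- numeric(0)
  env$priority <- integer(0)
  env$eseq <- integer(0)
  env$payload <- list()
  env$log <- list()
  class(env) <- "sim_env"
  env
}

#' Current simulation clock
#' @param env A `sim_env`.
#' @return Clock time in minutes.
#' @export
sim_now <- function(env) env$now

#' Schedule an event
#'
#' @param env A `sim_env`.
#' @param time Event time in minutes; must not lie before the current clock.
#' @param priority Small integer; lower fires first among events at the same
#'   time (default 5).
#' @param type Character tag describing the event.
#' @param ... Further payload fields, stored as a list.
#' @return The insertion sequence number, invisibly.
#' @export
sim_schedule <- function(env, time, priority = 5L, type = "event", ...) {
  stopifnot(inherits(env, "sim_env"))
  if (!is.numeric(time) || length(time) != 1L || !is.finite(time)) {
    stop("event time must be a single finite number")
  }
  if (time < env$now) {
    stop(sprintf("cannot schedule in the past: t=%g < clock %g", time, env$now))
  }
  env$seq <- env$seq + 1L
  env$time <- c(env$time, time)
  env$priority <- c(env$priority, as.integer(priority))
  env$eseq <- c(env$eseq, env$seq)
  env$payload <- c(env$payload, list(list(type = type, ...)))
  invisible(env$seq)
}

#' Run the simulation
#'
#' Dispatches every pending event with `time <= until`, each exactly once, in
#' `(time, priority, seq)` order, then advances the clock to `until`. The
#' optional `handler` is called as `handler(env, event)` for each dispatched
#' event and may schedule further events (at or after the event's time).
#'
#' @param env A `sim_env`.
#' @param until Stop time in minutes (`>= 0` and `>=` current clock).
#' @param handler Optional callback `function(env, event)`.
#' @return A data frame event log with columns `t`, `priority`, `seq`, `type`.
#'   The full payloads are kept in `env$log`.
#' @export
sim_run <- function(env, until, handler = NULL) {
  stopifnot(inherits(env, "sim_env"), until >= 0, until >= env$now)
  repeat {
    if (length(env$time) == 0L) break
    i <- order(env$time, env$priority, env$eseq)[1L]
    if (env$time[i] > until) break
    ev <- env$payload[[i]]
    ev$t <- env$time[i]
    ev$priority <- env$priority[i]
    ev$seq <- env$eseq[i]
    env$time <- env$time[-i]
    env$priority <- env$priority[-i]
    env$eseq <- env$eseq[-i]
    env$payload <- env$payload[-i]
    env$now <- ev$t
    env$log[[length(env$log) + 1L]] <- ev
    if (!is.null(handler)) handler(env, ev)
  }
  env$now <- until
  sim_event_log(env)
}

#' Event log as a data frame
#' @param env A `sim_env`.
#' @return Data frame with one row per dispatched event.
#' @export
sim_event_log <- function(env) {
  if (length(env$log) == 0L) {
    return(data.frame(t = numeric(0), priority = integer(0),
                      seq = integer(0), type = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    t = vapply(env$log, function(e) e$t, numeric(1)),
    priority = vapply(env$log, function(e) e$priority, integer(1)),
    seq = vapply(env$log, function(e) e$seq, integer(1)),
    type = vapply(env$log, function(e) e$type, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Serialize the event log as JSON lines
#'
#' One `{"t": minutes, "type": ..., "payload": ...}` object per line.
#'
#' @param env A `sim_env`.
#' @param path Optional file path; if `NULL` the lines are returned.
#' @return Character vector of JSONL lines (invisibly when written to file).
#' @export
sim_log_jsonl <- function(env, path = NULL) {
  lines <- vapply(env$log, function(e) {
    payload <- e[setdiff(names(e), c("t", "type", "priority", "seq"))]
    jsonlite::toJSON(list(t = e$t, type = e$type, payload = payload),
                     auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# --- named RNG streams -------------------------------------------------------

# One independent stream per stochastic component (thermal, failures, network,
# population, ...) so that adding a component never perturbs another
# component's draw sequence. Each stream owns a private .Random.seed state
# derived deterministically from (seed, label); draws swap that state in and
# out of the global RNG, restoring whatever was there before.

.stream_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 7919 + h * 104729 + 1) %% 2147483647)
}

#' Create a named RNG stream
#'
#' Identical `(seed, label)` pairs yield identical draw sequences, independent
#' of any other stream and of the global RNG state.
#'
#' @param seed Integer master seed.
#' @param label Stream label, e.g. `"thermal"`.
#' @return An object of class `rng_stream`.
#' @export
#' @examples
#' s <- rng_stream(42, "thermal")
#' rng_rnorm(s, 3)
rng_stream <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  st <- new.env(parent = emptyenv())
  st$seed <- seed
  st$label <- label
  old <- .save_global_seed()
  set.seed(.stream_seed(seed, label))
  st$state <- get(".Random.seed", envir = globalenv())
  .restore_global_seed(old)
  class(st) <- "rng_stream"
  st
}

.save_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_global_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Draw from a stream
#'
#' Evaluates `expr` with the stream's private RNG state installed, then saves
#' the advanced state back into the stream and restores the previous global
#' state.
#'
#' @param stream An `rng_stream`.
#' @param expr An expression performing RNG draws (e.g. `rnorm(1)`).
#' @return The value of `expr`.
#' @export
rng_draw <- function(stream, expr) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- .save_global_seed()
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    .restore_global_seed(old)
  })
  expr
}

#' @rdname rng_draw
#' @param n Number of deviates.
#' @export
rng_rnorm <- function(stream, n = 1L) rng_draw(stream, stats::rnorm(n))

#' @rdname rng_draw
#' @export
rng_runif <- function(stream, n = 1L) rng_draw(stream, stats::runif(n))
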