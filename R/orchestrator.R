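#' In-process instrument endpoints
#'
#' The architecture's instrument servers are abstracted to an in-process
#' request/response contract: an endpoint owns a mutable state (an R
#' environment) and a set of named operations; every invocation returns a
#' status (`"ok"`/`"error"`/`"unavailable"`), a payload, and is logged by the
#' experiment loop. Unavailable endpoints reject immediately rather than
#' hanging — the property an unattended overnight loop depends on.
#'
#' Operations are functions `function(state, params)` returning the payload
#' (they may modify `state`, an environment). An optional operation named
#' `"tick"` is invoked by [run_experiment()] every loop tick with
#' `params = list(dt = tick)` to advance a virtual instrument's physics.
#'
#' @param name endpoint name.
#' @param operations named list of operation functions.
#' @param state environment holding the instrument's mutable state (one is
#'   created if omitted).
#' @param available logical availability flag.
#' @return An `instrument_endpoint` object (itself an environment, so
#'   availability can be toggled and state evolves in place).
#' @export
instrument_endpoint <- function(name, operations, state = new.env(parent = emptyenv()),
                                available = TRUE) {
  stopifnot(is.character(name), is.list(operations))
  ep <- new.env(parent = emptyenv())
  ep$name <- name
  ep$operations <- operations
  ep$state <- state
  ep$available <- available
  ep$invocations <- 0L
  class(ep) <- "instrument_endpoint"
  ep
}

#' Invoke an operation on an endpoint
#'
#' @param endpoint an [instrument_endpoint()].
#' @param operation operation name.
#' @param params named list of parameters.
#' @return List with `status`, `payload` (NULL on failure) and `message`.
#' @export
invoke <- function(endpoint, operation, params = list()) {
  if (!isTRUE(endpoint$available)) {
    return(list(status = "unavailable", payload = NULL,
                message = sprintf("endpoint '%s' is unavailable", endpoint$name)))
  }
  op <- endpoint$operations[[operation]]
  if (is.null(op)) {
    return(list(status = "error", payload = NULL,
                message = sprintf("unknown operation '%s' on '%s'",
                                  operation, endpoint$name)))
  }
  endpoint$invocations <- endpoint$invocations + 1L
  res <- tryCatch(list(status = "ok", payload = op(endpoint$state, params),
                       message = ""),
                  error = function(e) list(status = "error", payload = NULL,
                                           message = conditionMessage(e)))
  res
}

#' Reactive experiment events
#'
#' An event is "if *this* happens, do *this*": a side-effect-free condition
#' over the experiment context plus an action executed when it holds.
#' Schedules: `"on-data"` events are condition-checked every tick;
#' `"periodic"` events additionally require an interval to have completed
#' (they fire at interval completions, never at t = 0; ties between events
#' are broken by registration order); `"one-shot"` events disable themselves
#' after their first firing.
#'
#' The context passed to `condition(ctx)` and `action(ctx)` has fields `t`
#' (current time, h), `experiment` (for [invoke_logged()] calls), `data`
#' (shared mutable environment for cross-event state), and `seed`.
#'
#' @param name unique event name.
#' @param condition function(ctx) -> logical; must be side-effect-free.
#' @param action function(ctx); instrument calls inside should go through
#'   [invoke_logged()] so they are logged.
#' @param schedule `"on-data"`, `"periodic"` or `"one-shot"`.
#' @param interval_h firing interval for periodic events, h.
#' @param enabled initial enabled flag.
#' @return An `experiment_event` object.
#' @export
experiment_event <- function(name, condition = function(ctx) TRUE, action,
                             schedule = c("on-data", "periodic", "one-shot"),
                             interval_h = NULL, enabled = TRUE) {
  schedule <- match.arg(schedule)
  if (schedule == "periodic" && (is.null(interval_h) || interval_h <= 0))
    stop("periodic events need a positive interval_h", call. = FALSE)
  structure(list(name = name, condition = condition, action = action,
                 schedule = schedule, interval_h = interval_h,
                 enabled = enabled),
            class = "experiment_event")
}

#' Create an experiment
#'
#' @param instruments named list of [instrument_endpoint()]s.
#' @param seed integer seed governing all in-loop randomness.
#' @return An `experiment` environment with an empty event registry and log.
#' @export
new_experiment <- function(instruments = list(), seed = 1L) {
  ex <- new.env(parent = emptyenv())
  ex$instruments <- instruments
  ex$events <- list()
  ex$log <- list()
  ex$seq <- 0L
  ex$t <- 0
  ex$seed <- as.integer(seed)
  ex$data <- new.env(parent = emptyenv())
  class(ex) <- "experiment"
  ex
}

# append one log record (total order: time, then sequence number)
log_record <- function(ex, source, operation, params, outcome, payload = NULL) {
  ex$seq <- ex$seq + 1L
  digest <- if (is.null(payload)) "" else
    paste0("n", length(unlist(payload, use.names = FALSE)), ":",
           format(sum(as.numeric(unlist(payload, use.names = FALSE))[
             is.finite(as.numeric(unlist(payload, use.names = FALSE)))]),
             digits = 12))
  ex$log[[ex$seq]] <- list(seq = ex$seq, t = ex$t, source = source,
                           operation = operation, params = params,
                           outcome = outcome, digest = digest)
  invisible(ex)
}

#' Register an event with an experiment
#'
#' @param experiment an [new_experiment()].
#' @param event an [experiment_event()]; its name must be unique.
#' @return A handle list with `enable()` / `disable()` functions.
#' @export
register_event <- function(experiment, event) {
  stopifnot(inherits(event, "experiment_event"))
  if (event$name %in% names(experiment$events))
    stop("duplicate event name: ", event$name, call. = FALSE)
  rec <- new.env(parent = emptyenv())
  rec$event <- event
  rec$enabled <- event$enabled
  rec$fired <- 0L
  rec$next_fire <- if (event$schedule == "periodic") event$interval_h else NULL
  experiment$events[[event$name]] <- rec
  list(name = event$name,
       enable = function() rec$enabled <- TRUE,
       disable = function() rec$enabled <- FALSE,
       fired = function() rec$fired)
}

#' Logged instrument invocation
#'
#' The way event actions call instruments: performs [invoke()] and appends
#' exactly one log record for the invocation.
#'
#' @param ctx the event context (or an `experiment`).
#' @param instrument instrument name.
#' @param operation operation name.
#' @param params named list.
#' @return The [invoke()] response.
#' @export
invoke_logged <- function(ctx, instrument, operation, params = list()) {
  ex <- if (inherits(ctx, "experiment")) ctx else ctx$experiment
  ep <- ex$instruments[[instrument]]
  if (is.null(ep)) {
    res <- list(status = "error", payload = NULL,
                message = paste("unknown instrument:", instrument))
  } else {
    res <- invoke(ep, operation, params)
  }
  log_record(ex, paste0("instrument/", instrument), operation, params,
             res$status, res$payload)
  res
}

#' Run the experiment loop
#'
#' Discrete-time loop: each tick advances every virtual instrument that
#' exposes a `"tick"` operation, then evaluates event conditions on the fresh
#' state and executes fired actions in registration order, logging every
#' instrument invocation and event firing. An action error aborts that action
#' chain, is logged, and the loop continues (fail-safe for unattended runs).
#' The run is deterministic given the experiment seed.
#'
#' @param experiment an [new_experiment()] with events registered.
#' @param duration_h total simulated duration, h.
#' @param tick_h loop tick, h.
#' @return The experiment (invisibly); inspect `experiment$log`, or export
#'   with [write_experiment_log()].
#' @export
run_experiment <- function(experiment, duration_h, tick_h) {
  stopifnot(inherits(experiment, "experiment"))
  old_rng <- save_rng()
  on.exit(restore_rng(old_rng), add = TRUE)
  set.seed(experiment$seed)
  n_ticks <- round(duration_h / tick_h)
  for (k in seq_len(n_ticks)) {
    experiment$t <- k * tick_h
    for (nm in names(experiment$instruments)) {
      ep <- experiment$instruments[[nm]]
      if ("tick" %in% names(ep$operations)) {
        res <- invoke(ep, "tick", list(dt = tick_h))
        log_record(experiment, paste0("instrument/", nm), "tick",
                   list(dt = tick_h), res$status, res$payload)
      }
    }
    for (nm in names(experiment$events)) {
      rec <- experiment$events[[nm]]
      if (!isTRUE(rec$enabled)) next
      ev <- rec$event
      due <- TRUE
      if (ev$schedule == "periodic") {
        due <- experiment$t >= rec$next_fire - 1e-9
      }
      if (!due) next
      ctx <- list(t = experiment$t, experiment = experiment,
                  data = experiment$data, seed = experiment$seed)
      fire <- tryCatch(isTRUE(ev$condition(ctx)), error = function(e) FALSE)
      if (!fire) next
      rec$fired <- rec$fired + 1L
      if (ev$schedule == "periodic")
        rec$next_fire <- rec$next_fire + ev$interval_h
      if (ev$schedule == "one-shot") rec$enabled <- FALSE
      out <- tryCatch({ ev$action(ctx); "ok" },
                      error = function(e) paste("error:", conditionMessage(e)))
      log_record(experiment, paste0("event/", ev$name), "fire", list(),
                 out)
    }
  }
  invisible(experiment)
}

#' Export / import the experiment log as JSON lines
#'
#' One record per line, append-only friendly; timestamps are simulated hours.
#'
#' @param experiment an experiment after [run_experiment()].
#' @param path output file.
#' @export
write_experiment_log <- function(experiment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in experiment$log) {
    # digits = I(17): decimal round-trip-exact doubles, so file-driven replay
    # reproduces states bit-for-bit
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = I(17),
                                null = "null"), con)
  }
  invisible(path)
}

#' @rdname write_experiment_log
#' @export
read_experiment_log <- function(path) {
  lapply(readLines(path), function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}

#' Replay a logged run against fresh instruments
#'
#' Re-executes the logged instrument invocations, in order, against freshly
#' initialized endpoints. Because instruments are deterministic given their
#' operation sequence and parameters, replay reproduces the original final
#' instrument state bit-for-bit — the log is a complete record of the run.
#'
#' @param log a log (list of records, as `experiment$log` or from
#'   [read_experiment_log()]).
#' @param instruments named list of freshly initialized endpoints matching
#'   the original run.
#' @return The instruments after replay (inspect their `$state`).
#' @export
replay_log <- function(log, instruments) {
  for (r in log) {
    src <- r$source
    if (!startsWith(src, "instrument/")) next
    nm <- sub("^instrument/", "", src)
    ep <- instruments[[nm]]
    if (is.null(ep)) stop("replay: unknown instrument ", nm, call. = FALSE)
    invoke(ep, r$operation, as.list(r$params))
  }
  invisible(instruments)
}

#' Count instrument invocations recorded in a log
#'
#' @param log the experiment log.
#' @export
count_log_invocations <- function(log) {
  sum(vapply(log, function(r) startsWith(r$source, "instrument/"), logical(1)))
}

#' Format a human-readable status notification
#'
#' Deterministic one-message status digest of the kind pushed to remote chat
#' channels during long experiments (message formatting only; no delivery).
#'
#' @param state_digest list with optional fields `t` (h), `reactors` (named
#'   list: each with `od` and optionally `target`, `measured`), `last_event`.
#' @return A single character string.
#' @export
format_notification <- function(state_digest = list()) {
  lines <- "[reacloop] experiment status"
  if (!is.null(state_digest$t))
    lines <- c(lines, sprintf("t = %s h", fmt3(state_digest$t)))
  for (nm in names(state_digest$reactors)) {
    r <- state_digest$reactors[[nm]]
    parts <- sprintf("%s: OD %s", nm, fmt3(r$od))
    if (!is.null(r$target))
      parts <- paste0(parts, sprintf(", target %s RPU", fmt3(r$target)))
    if (!is.null(r$measured))
      parts <- paste0(parts, sprintf(", measured %s RPU", fmt3(r$measured)))
    lines <- c(lines, parts)
  }
  if (!is.null(state_digest$last_event))
    lines <- c(lines, sprintf("last event: %s", state_digest$last_event))
  paste(lines, collapse = "\n")
}
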