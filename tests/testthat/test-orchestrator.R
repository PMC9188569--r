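# Orchestrator: endpoints, events, logging, replay, notifications.

# a trivial counter instrument whose state is fully determined by its
# operation sequence
make_counter <- function() {
  st <- new.env(parent = emptyenv())
  st$value <- 0
  st$ticks <- 0L
  instrument_endpoint("counter", list(
    tick = function(state, p) { state$ticks <- state$ticks + 1L; state$ticks },
    add = function(state, p) { state$value <- state$value + p$x; state$value },
    fail = function(state, p) stop("instrument fault"),
    get = function(state, p) state$value
  ), state = st)
}

test_that("endpoints answer every invocation with a status", {
  ep <- make_counter()
  expect_equal(invoke(ep, "add", list(x = 2))$status, "ok")
  expect_equal(invoke(ep, "add", list(x = 3))$payload, 5)
  expect_equal(invoke(ep, "nope")$status, "error")
  expect_equal(invoke(ep, "fail")$status, "error")
  ep$available <- FALSE
  expect_equal(invoke(ep, "add", list(x = 1))$status, "unavailable")
  ep$available <- TRUE
  expect_equal(invoke(ep, "get")$payload, 5)   # failed calls changed nothing
})

test_that("event scheduling follows the documented firing conventions", {
  # always-false condition never fires
  ex <- new_experiment(list(counter = make_counter()))
  never <- register_event(ex, experiment_event(
    "never", condition = function(ctx) FALSE,
    action = function(ctx) invoke_logged(ctx, "counter", "add", list(x = 1))))
  # periodic 1-h event over 10 h at 1-min ticks: exactly 10 firings, not 11
  hourly <- register_event(ex, experiment_event(
    "hourly", action = function(ctx)
      invoke_logged(ctx, "counter", "add", list(x = 1)),
    schedule = "periodic", interval_h = 1))
  # one-shot fires once
  once <- register_event(ex, experiment_event(
    "once", condition = function(ctx) ctx$t >= 2,
    action = function(ctx) NULL, schedule = "one-shot"))
  run_experiment(ex, duration_h = 10, tick_h = 1 / 60)
  expect_equal(never$fired(), 0L)
  expect_equal(hourly$fired(), 10L)
  expect_equal(once$fired(), 1L)
  expect_equal(ex$instruments$counter$state$value, 10)

  # on-data: fires exactly once per data arrival flagged by another event
  ex2 <- new_experiment(list(counter = make_counter()))
  register_event(ex2, experiment_event(
    "arrival", action = function(ctx) ctx$data$fresh <- TRUE,
    schedule = "periodic", interval_h = 1))
  got <- register_event(ex2, experiment_event(
    "consume", condition = function(ctx) isTRUE(ctx$data$fresh),
    action = function(ctx) ctx$data$fresh <- FALSE))
  run_experiment(ex2, duration_h = 10, tick_h = 0.25)
  expect_equal(got$fired(), 10L)

  expect_error(register_event(ex, experiment_event("never",
                                                   action = function(ctx) NULL)),
               "duplicate")
  expect_error(experiment_event("p", action = function(ctx) NULL,
                                schedule = "periodic"), "interval")
})

test_that("the log is complete and action errors do not stop the loop", {
  ex <- new_experiment(list(counter = make_counter()))
  register_event(ex, experiment_event(
    "work", action = function(ctx) {
      invoke_logged(ctx, "counter", "add", list(x = 1))
      if (ctx$t >= 3) stop("late failure")
      invoke_logged(ctx, "counter", "add", list(x = 10))
    }, schedule = "periodic", interval_h = 1))
  run_experiment(ex, duration_h = 5, tick_h = 0.5)

  # invocation count equals instrument-record count (ticks included)
  expect_equal(count_log_invocations(ex$log),
               ex$instruments$counter$invocations)
  # the loop survived the failing actions and kept firing
  fires <- Filter(function(r) r$source == "event/work", ex$log)
  expect_length(fires, 5L)
  expect_match(fires[[4]]$outcome, "error")
  # the aborted chains (t = 3, 4, 5) skipped their second invocation
  expect_equal(ex$instruments$counter$state$value, 2 * 11 + 3 * 1)
})

test_that("replaying the log reproduces final state bit for bit", {
  ex <- new_experiment(list(counter = make_counter()))
  register_event(ex, experiment_event(
    "work", action = function(ctx)
      invoke_logged(ctx, "counter", "add", list(x = exp(ctx$t / 3))),
    schedule = "periodic", interval_h = 1))
  run_experiment(ex, duration_h = 6, tick_h = 0.5)

  fresh <- make_counter()
  replay_log(ex$log, list(counter = fresh))
  expect_identical(fresh$state$value, ex$instruments$counter$state$value)
  expect_identical(fresh$state$ticks, ex$instruments$counter$state$ticks)

  # and through the JSON-lines file
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_experiment_log(ex, f)
  fresh2 <- make_counter()
  replay_log(read_experiment_log(f), list(counter = fresh2))
  expect_identical(fresh2$state$value, ex$instruments$counter$state$value)
})

test_that("disabling an event removes exactly its records", {
  build <- function(with_b) {
    ex <- new_experiment(list(ca = make_counter(), cb = make_counter()))
    register_event(ex, experiment_event(
      "a", action = function(ctx) invoke_logged(ctx, "ca", "add",
                                                list(x = 1)),
      schedule = "periodic", interval_h = 1))
    register_event(ex, experiment_event(
      "b", action = function(ctx) invoke_logged(ctx, "cb", "add",
                                                list(x = 100)),
      schedule = "periodic", interval_h = 2, enabled = with_b))
    run_experiment(ex, duration_h = 6, tick_h = 0.5)
    ex
  }
  with_b <- build(TRUE)
  without_b <- build(FALSE)
  drop_b <- Filter(function(r) !grepl("event/b", r$source) &&
                     !(grepl("instrument/cb", r$source) &&
                         r$operation == "add"), with_b$log)
  strip_seq <- function(l) lapply(l, function(r) r[setdiff(names(r), "seq")])
  expect_equal(strip_seq(drop_b), strip_seq(without_b$log))
})

test_that("status notifications are deterministic and complete", {
  msg <- format_notification(list(
    t = 12.3456,
    reactors = list(r1 = list(od = 0.5, target = 0.75, measured = 0.7489)),
    last_event = "mpc"))
  expect_match(msg, "t = 12.3 h")
  expect_match(msg, "r1: OD 0.500")
  expect_match(msg, "target 0.750 RPU")
  expect_match(msg, "measured 0.749 RPU")
  expect_match(msg, "last event: mpc")
  expect_identical(msg, format_notification(list(
    t = 12.3456,
    reactors = list(r1 = list(od = 0.5, target = 0.75, measured = 0.7489)),
    last_event = "mpc")))
  expect_equal(format_notification(), "[reacloop] experiment status")
})

test_that("the event-driven light-control loop tracks its target", {
  par <- expression_params()
  res <- run_light_control(0.75, par, duration_h = 8,
                           config = light_mpc_config(n_starts = 2))
  expect_lt(abs(res$final_FP - 0.75) / 0.75, 0.02)
  # orchestration transparency: the reactor's applied history drives the
  # plant to exactly the state direct simulation gives
  hist <- res$experiment$instruments$reactor$state$applied
  direct <- simulate_expression(par, expression_state(),
                                light_program(hist), 8)
  expect_equal(res$final_FP, direct$FP)
})
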