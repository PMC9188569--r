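# Seeded internals must not perturb the caller's RNG stream: save the global
# state before set.seed and restore it on exit of the seeded function.
save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Shared bounded multi-start optimizer: L-BFGS-B from a deterministic set of
# seeded random starts (plus any caller-supplied warm starts). Used by the
# expression fit and both model-predictive planners, matching their common
# "multi-dimensional, bounded, gradient-based search" contract.
multistart_optim <- function(objective, lower, upper, n_starts = 20L,
                             seed = 0L, extra_starts = list(),
                             log_sample = FALSE,
                             control = list(maxit = 500L, factr = 1e4)) {
  k <- length(lower)
  stopifnot(length(upper) == k)
  old_rng <- save_rng()
  on.exit(restore_rng(old_rng), add = TRUE)
  set.seed(seed)
  starts <- extra_starts
  for (i in seq_len(n_starts)) {
    s <- if (log_sample) {
      exp(stats::runif(k, log(pmax(lower, 1e-12)), log(upper)))
    } else {
      stats::runif(k, lower, upper)
    }
    starts[[length(starts) + 1L]] <- s
  }
  runs <- lapply(starts, function(p0) {
    p0 <- pmin(pmax(p0, lower), upper)
    res <- tryCatch(
      stats::optim(p0, objective, method = "L-BFGS-B",
                   lower = lower, upper = upper, control = control),
      error = function(e) list(par = p0, value = Inf, convergence = 99L,
                               message = conditionMessage(e)))
    res
  })
  vals <- vapply(runs, function(r) r$value, numeric(1))
  if (all(!is.finite(vals))) {
    msgs <- unique(unlist(lapply(runs, function(r) r$message)))
    stop("all optimizer starts failed: ", paste(msgs, collapse = "; "),
         call. = FALSE)
  }
  list(runs = runs, values = vals, best = which.min(vals))
}

# format a number to 3 significant digits for status lines
fmt3 <- function(x) formatC(signif(x, 3), format = "fg", flag = "#", digits = 3)
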