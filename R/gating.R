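#' Gating configuration
#'
#' Two named parameters control automatic gating, mirroring the acquisition
#' pipeline's defaults (size threshold = 0.5, doublet threshold = 0.5). Both
#' act monotonically: raising either removes more events.
#'
#' @param size_threshold in (0, 1]: events whose log-FSC kernel-density value
#'   falls below `size_threshold` times the density mode are discarded
#'   (debris, dead and dying cells).
#' @param doublet_threshold in (0, 1]: controls the cut on the standardized
#'   orthogonal residual of the robust log-SSC vs log-FSC fit below which
#'   events are called doublets (see [gate()]).
#' @export
gate_config <- function(size_threshold = 0.5, doublet_threshold = 0.5) {
  if (size_threshold <= 0 || size_threshold > 1 ||
      doublet_threshold <= 0 || doublet_threshold > 1)
    stop("gate thresholds must lie in (0, 1]", call. = FALSE)
  structure(list(size_threshold = size_threshold,
                 doublet_threshold = doublet_threshold),
            class = "gate_config")
}

#' Automatic size and doublet gating
#'
#' Retains single, intact cells by two sequential filters:
#'
#' * **Size gate** — a kernel density estimate of log-FSC is computed with a
#'   deliberately wide bandwidth (2.5 x the MAD of log-FSC), so a homogeneous
#'   population forms one broad mode and is kept essentially entirely, while
#'   debris and dead-cell modes far below the main mode have density under
#'   `size_threshold` x mode and are removed.
#' * **Doublet gate** — a robust line ([MASS::rlm()]) of log-SSC on log-FSC is
#'   fitted; orthogonal residuals are standardized by their MAD. Coincident
#'   doublets are event-wise sums, which fall *below* the singlet line
#'   whenever the singlet SSC grows super-linearly with FSC, so events with
#'   standardized residual below `-qnorm(1 - doublet_threshold / 200)`
#'   (z = -2.81 at the default 0.5) are removed.
#'
#' With fewer than 3 events gating is meaningless: an all-true mask is
#' returned with a `"warning"` attribute recording why.
#'
#' @param events an [event_table()].
#' @param config a [gate_config()].
#' @return Logical keep-mask of length `n_events(events)`, with attributes
#'   `kept` (count) and possibly `warning`.
#' @examples
#' S <- diag(1); dimnames(S) <- list("c1", "f1")
#' sp <- population_spec(list(wt = list(fraction = 1, meanlog = c(f1 = 5),
#'                                      sdlog = c(f1 = 0.2))),
#'                       spectral_signature(S), 500, seed = 1)
#' g <- generate_events(sp)
#' mean(gate(g$events, gate_config()))
#' @export
gate <- function(events, config = gate_config()) {
  stopifnot(inherits(config, "gate_config"))
  n <- n_events(events)
  if (n == 0L) return(logical(0))
  if (n < 3L) {
    mask <- rep(TRUE, n)
    attr(mask, "warning") <- "fewer than 3 events: gating skipped"
    attr(mask, "kept") <- n
    return(mask)
  }
  lf <- log(pmax(events$fsc, .Machine$double.xmin))
  ls <- log(pmax(events$ssc, .Machine$double.xmin))

  # size gate: wide-bandwidth KDE, keep density >= threshold * mode
  bw <- 2.5 * stats::mad(lf)
  if (!is.finite(bw) || bw <= 0) bw <- max(stats::bw.nrd0(lf), 1e-3)
  dens <- stats::density(lf, bw = bw, n = 1024L,
                         from = min(lf) - bw, to = max(lf) + bw)
  d_at <- stats::approx(dens$x, dens$y, xout = lf, rule = 2L)$y
  keep_size <- d_at >= config$size_threshold * max(dens$y)

  # doublet gate: robust line in log-log scatter space, one-sided cut below
  keep_dbl <- rep(TRUE, n)
  fit <- tryCatch(MASS::rlm(ls ~ lf, maxit = 50L), error = function(e) NULL)
  if (!is.null(fit)) {
    beta <- stats::coef(fit)[2L]
    resid <- ls - stats::fitted(fit)
    orth <- resid / sqrt(1 + beta^2)
    s <- stats::mad(orth[keep_size])
    if (is.finite(s) && s > 0) {
      zcut <- -stats::qnorm(1 - config$doublet_threshold / 200)
      keep_dbl <- (orth / s) >= zcut
    }
  }
  mask <- keep_size & keep_dbl
  attr(mask, "kept") <- sum(mask)
  mask
}
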