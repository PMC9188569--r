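#' Synthetic cytometry population specification
#'
#' A `population_spec` describes the single-cell population a simulated
#' cytometer acquisition draws from: per-strain event fractions, log-normal
#' fluorophore expression (in the same arbitrary units as the spectral
#' signature's unit amounts), log-normal forward scatter, a side-scatter law,
#' plus doublet/debris contamination and multiplicative measurement noise.
#' The generator is the package's ground-truth fixture factory: every event
#' is labeled with the strain (or `"doublet"`/`"debris"`) it came from.
#'
#' Side scatter follows `log(ssc) = ssc_intercept + ssc_exponent * log(fsc)`
#' plus Gaussian noise. The default exponent 1.8 (> 1) matters: doublets are
#' simulated as channel-wise sums of two singlets, and only when the singlet
#' SSC-FSC relation is super-linear do summed events fall measurably off the
#' singlet line, as they do for real cell doublets.
#'
#' @param strains named list; each element a list with `fraction` (summing to
#'   1 over strains), `meanlog`/`sdlog` (named numeric vectors over
#'   fluorophores: log-mean and log-sd of expressed amounts, a.u.; omitted
#'   fluorophores are absent), and optional `fsc_meanlog`, `fsc_sdlog`.
#' @param signature a [spectral_signature()] used to mix amounts into
#'   channels (`y = S x + a`).
#' @param n_events number of events to draw.
#' @param doublet_fraction,debris_fraction fractions of `n_events` emitted as
#'   doublets / debris, in `[0, 1]`.
#' @param noise_sd log-scale sd of multiplicative measurement noise applied to
#'   every channel (0 = noise-free).
#' @param fsc_meanlog,fsc_sdlog default log-normal forward-scatter parameters.
#' @param ssc_intercept,ssc_exponent,ssc_sdlog side-scatter law parameters.
#' @param debris_fsc_factor debris FSC mode relative to the singlet mode
#'   (default 0.05: far below intact cells).
#' @param seed integer random seed; generation is fully reproducible.
#' @return A `population_spec` object.
#' @export
population_spec <- function(strains, signature, n_events,
                            doublet_fraction = 0, debris_fraction = 0,
                            noise_sd = 0.05,
                            fsc_meanlog = log(1000), fsc_sdlog = 0.25,
                            ssc_intercept = -3, ssc_exponent = 1.8,
                            ssc_sdlog = 0.05,
                            debris_fsc_factor = 0.05, seed = 1L) {
  stopifnot(inherits(signature, "spectral_signature"))
  if (n_events < 0 || n_events != round(n_events))
    stop("n_events must be a non-negative integer", call. = FALSE)
  fr <- vapply(strains, function(s) s$fraction, numeric(1))
  if (any(fr < 0)) stop("strain fractions must be >= 0", call. = FALSE)
  if (length(fr) > 0 && abs(sum(fr) - 1) > 1e-8)
    stop("strain fractions must sum to 1", call. = FALSE)
  if (doublet_fraction < 0 || doublet_fraction > 1 ||
      debris_fraction < 0 || debris_fraction > 1)
    stop("doublet/debris fractions must be in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(strains = strains, signature = signature,
                 n_events = as.integer(n_events),
                 doublet_fraction = doublet_fraction,
                 debris_fraction = debris_fraction, noise_sd = noise_sd,
                 fsc_meanlog = fsc_meanlog, fsc_sdlog = fsc_sdlog,
                 ssc_intercept = ssc_intercept, ssc_exponent = ssc_exponent,
                 ssc_sdlog = ssc_sdlog, debris_fsc_factor = debris_fsc_factor,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Draw a synthetic cytometry acquisition
#'
#' Samples `n_events` events from a [population_spec()]: singlets are drawn
#' per strain with channel vectors `S x + a` under multiplicative log-normal
#' noise; doublets are channel-wise (and scatter-wise) sums of two singlets;
#' debris events sit far below the singlet FSC mode with
#' autofluorescence-level channels. Ground-truth labels accompany the table.
#'
#' @param spec a [population_spec()].
#' @return A list with `events` (an [event_table()]), `labels` (character:
#'   strain name, `"doublet"` or `"debris"`) and `amounts` (true per-event
#'   fluorophore amounts; rows of doublets hold the summed amounts, debris 0).
#' @examples
#' S <- diag(2); dimnames(S) <- list(c("c1", "c2"), c("f1", "f2"))
#' sp <- population_spec(
#'   strains = list(wt = list(fraction = 1, meanlog = c(f1 = 5), sdlog = c(f1 = 0.2))),
#'   signature = spectral_signature(S), n_events = 100, seed = 7)
#' ev <- generate_events(sp)
#' table(ev$labels)
#' @export
generate_events <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  sig <- spec$signature
  flu <- sig$fluorophore_names
  nch <- length(sig$channel_names)
  n <- spec$n_events
  if (n == 0L) {
    ev <- event_table(numeric(0), numeric(0),
                      stats::setNames(rep(list(numeric(0)), nch),
                                      sig$channel_names))
    return(list(events = ev, labels = character(0),
                amounts = matrix(numeric(0), 0L, length(flu),
                                 dimnames = list(NULL, flu))))
  }
  old_rng <- save_rng()
  on.exit(restore_rng(old_rng), add = TRUE)
  set.seed(spec$seed)

  n_dbl <- round(n * spec$doublet_fraction)
  n_deb <- round(n * spec$debris_fraction)
  n_sgl <- n - n_dbl - n_deb

  draw_singlets <- function(m) {
    if (m == 0L) {
      return(list(x = matrix(0, 0L, length(flu), dimnames = list(NULL, flu)),
                  fsc = numeric(0), label = character(0)))
    }
    nm <- names(spec$strains)
    fr <- vapply(spec$strains, function(s) s$fraction, numeric(1))
    lab <- if (length(nm)) sample(nm, m, replace = TRUE, prob = fr)
           else stop("no strains in spec", call. = FALSE)
    x <- matrix(0, m, length(flu), dimnames = list(NULL, flu))
    fsc <- numeric(m)
    for (s in nm) {
      idx <- which(lab == s)
      if (!length(idx)) next
      st <- spec$strains[[s]]
      fml <- if (!is.null(st$fsc_meanlog)) st$fsc_meanlog else spec$fsc_meanlog
      fsl <- if (!is.null(st$fsc_sdlog)) st$fsc_sdlog else spec$fsc_sdlog
      fsc[idx] <- stats::rlnorm(length(idx), fml, fsl)
      for (f in names(st$meanlog)) {
        if (!f %in% flu)
          stop(sprintf("strain '%s' expresses unknown fluorophore '%s'", s, f),
               call. = FALSE)
        x[idx, f] <- stats::rlnorm(length(idx), st$meanlog[[f]],
                                   st$sdlog[[f]])
      }
    }
    list(x = x, fsc = fsc, label = lab)
  }

  sgl <- draw_singlets(n_sgl)
  # doublets: coincident pairs of singlets summed event-wise
  pa <- draw_singlets(n_dbl)
  pb <- draw_singlets(n_dbl)

  ssc_of <- function(fsc) {
    exp(spec$ssc_intercept + spec$ssc_exponent * log(fsc) +
          stats::rnorm(length(fsc), 0, spec$ssc_sdlog))
  }
  channels_of <- function(x) {
    y <- x %*% t(sig$S)
    sweep(y, 2L, sig$a, `+`)
  }

  fsc_s <- sgl$fsc
  ssc_s <- ssc_of(fsc_s)
  y_s <- channels_of(sgl$x)

  y_d <- channels_of(pa$x + pb$x)
  fsc_d <- pa$fsc + pb$fsc
  ssc_d <- ssc_of(pa$fsc) + ssc_of(pb$fsc)

  fsc_deb <- stats::rlnorm(n_deb, spec$fsc_meanlog + log(spec$debris_fsc_factor),
                           spec$fsc_sdlog)
  ssc_deb <- ssc_of(fsc_deb)
  y_deb <- channels_of(matrix(0, n_deb, length(flu)))

  y <- rbind(y_s, y_d, y_deb)
  fsc <- c(fsc_s, fsc_d, fsc_deb)
  ssc <- c(ssc_s, ssc_d, ssc_deb)
  x_true <- rbind(sgl$x, pa$x + pb$x, matrix(0, n_deb, length(flu)))
  labels <- c(sgl$label, rep("doublet", n_dbl), rep("debris", n_deb))

  if (spec$noise_sd > 0) {
    y <- y * exp(matrix(stats::rnorm(length(y), 0, spec$noise_sd), nrow(y)))
    fsc <- fsc * exp(stats::rnorm(length(fsc), 0, spec$noise_sd))
  }

  ord <- sample.int(length(fsc))        # shuffle so labels carry no order info
  ev <- event_table(fsc[ord], ssc[ord],
                    stats::setNames(as.data.frame(y[ord, , drop = FALSE]),
                                    sig$channel_names))
  list(events = ev, labels = labels[ord],
       amounts = x_true[ord, , drop = FALSE])
}
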