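#' Spectral signatures of fluorophores
#'
#' A spectral signature holds, for each detection channel, the expected
#' intensity contributed by one unit of each fluorophore (matrix `S`,
#' channels x fluorophores) together with the expected per-channel
#' autofluorescence background `a`. Signatures are estimated once from
#' single-color control strains plus an autofluorescence-only control and
#' reused for every sample: a measured channel vector `y` is modeled as
#' `S %*% x + a` for per-event fluorophore amounts `x`.
#'
#' @param S numeric matrix, channels x fluorophores, with dimnames; all
#'   entries must be >= 0 and the columns linearly independent.
#' @param autofluorescence numeric vector of per-channel background, a.u.,
#'   length `nrow(S)`; defaults to zero.
#' @return A `spectral_signature` object.
#' @examples
#' S <- matrix(c(1, 0.3, 0, 1), 2, 2,
#'             dimnames = list(c("GRN-B", "BLU-V"), c("mNeonGreen", "mCerulean")))
#' sig <- spectral_signature(S, autofluorescence = c(5, 3))
#' @export
spectral_signature <- function(S, autofluorescence = NULL) {
  S <- as.matrix(S)
  if (is.null(rownames(S)) || is.null(colnames(S)))
    stop("S needs channel rownames and fluorophore colnames", call. = FALSE)
  if (any(S < 0)) stop("signature entries must be >= 0", call. = FALSE)
  if (is.null(autofluorescence)) autofluorescence <- numeric(nrow(S))
  a <- as.numeric(autofluorescence)
  if (length(a) != nrow(S))
    stop("autofluorescence must have one entry per channel", call. = FALSE)
  if (any(a < 0)) stop("autofluorescence must be >= 0", call. = FALSE)
  if (qr(S)$rank < ncol(S)) stop(collinear_msg(S), call. = FALSE)
  structure(list(S = S, a = stats::setNames(a, rownames(S)),
                 channel_names = rownames(S),
                 fluorophore_names = colnames(S)),
            class = "spectral_signature")
}

# name the most-collinear fluorophore pair for the rank-deficiency error
collinear_msg <- function(S) {
  cn <- colnames(S)
  if (ncol(S) < 2L) return("signature matrix is rank deficient")
  cc <- suppressWarnings(stats::cor(S))
  cc[!is.finite(cc)] <- 1
  diag(cc) <- 0
  ij <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1L, ]
  sprintf("signature matrix is rank deficient: fluorophores '%s' and '%s' are spectrally collinear",
          cn[ij[1L]], cn[ij[2L]])
}

#' @export
print.spectral_signature <- function(x, ...) {
  cat(sprintf("<spectral_signature: %d channels x %d fluorophores>\n",
              nrow(x$S), ncol(x$S)))
  print(cbind(x$S, autofluorescence = x$a))
  invisible(x)
}

#' Read a spectral signature from a TSV matrix
#'
#' The file layout is one row per channel, one column per fluorophore, plus an
#' `autofluorescence` column; the first column holds the channel names.
#'
#' @param path path to the TSV file.
#' @return A [spectral_signature()].
#' @export
read_signature <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          row.names = 1L)
  if (!"autofluorescence" %in% names(df))
    stop("signature file needs an 'autofluorescence' column", call. = FALSE)
  a <- df$autofluorescence
  S <- as.matrix(df[, setdiff(names(df), "autofluorescence"), drop = FALSE])
  spectral_signature(S, a)
}

#' @rdname read_signature
#' @param sig a [spectral_signature()].
#' @export
write_signature <- function(sig, path) {
  df <- as.data.frame(sig$S)
  df$autofluorescence <- as.numeric(sig$a)
  utils::write.table(cbind(channel = rownames(sig$S), df), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-event spectral deconvolution (unmixing)
#'
#' Recovers per-event fluorophore amounts `x` from measured channel vectors
#' `y` by ordinary least squares on the model `y = S x + a`: for every event
#' the returned `x` minimizes `||S x + a - y||^2`. With spectrally
#' distinguishable fluorophores (full column rank `S`) the solution is unique.
#' Estimates are unconstrained by default, so small negative amounts can and
#' do occur for dim events — they carry the measurement noise and must not be
#' clipped before median summaries. `nonneg = TRUE` optionally projects the
#' solution onto the non-negative orthant by active-set refitting.
#'
#' @param events an [event_table()] whose channel set matches `sig`.
#' @param sig a [spectral_signature()].
#' @param nonneg logical; constrain amounts to be non-negative (default FALSE).
#' @return A list with `amounts` (events x fluorophores matrix) and
#'   `residual_norm` (per-event Euclidean norm of the channel residual).
#' @examples
#' S <- matrix(c(1, 0.3, 0, 1), 2, 2,
#'             dimnames = list(c("c1", "c2"), c("f1", "f2")))
#' sig <- spectral_signature(S)
#' ev <- event_table(1000, 500, list(c1 = 2, c2 = 1.6))
#' deconvolve(ev, sig)$amounts
#' @export
deconvolve <- function(events, sig, nonneg = FALSE) {
  stopifnot(inherits(sig, "spectral_signature"))
  ch <- channel_names(events)
  if (!setequal(ch, sig$channel_names))
    stop("channel sets of events and signature do not match", call. = FALSE)
  S <- sig$S
  Y <- channel_matrix(events)[, rownames(S), drop = FALSE]
  n <- nrow(Y)
  if (n == 0L) {
    amounts <- matrix(numeric(0), 0L, ncol(S),
                      dimnames = list(NULL, colnames(S)))
    return(list(amounts = amounts, residual_norm = numeric(0)))
  }
  B <- t(Y) - sig$a                      # channels x events, background removed
  qrS <- qr(S)
  X <- t(qr.coef(qrS, B))                # events x fluorophores
  colnames(X) <- colnames(S)
  if (nonneg) {
    neg <- which(apply(X < 0, 1L, any))
    for (i in neg) X[i, ] <- nnls_active_set(S, B[, i])
  }
  R <- B - S %*% t(X)
  list(amounts = X, residual_norm = sqrt(colSums(R^2)))
}

# tiny active-set NNLS for the handful of fluorophores per event
nnls_active_set <- function(S, b) {
  k <- ncol(S)
  best <- NULL
  for (free in rev(seq_len(2^k) - 1L)) {     # subsets of free coordinates
    idx <- which(bitwAnd(free, 2^(seq_len(k) - 1L)) > 0L)
    x <- numeric(k)
    if (length(idx) > 0L) {
      xi <- qr.coef(qr(S[, idx, drop = FALSE]), b)
      if (any(xi < 0)) next
      x[idx] <- xi
    }
    rss <- sum((b - S %*% x)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(x = x, rss = rss)
  }
  best$x
}
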