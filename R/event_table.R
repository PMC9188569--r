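#' Single-cell cytometry event tables
#'
#' An `event_table` is the substrate of all cytometry processing: one row per
#' detected event, with forward scatter (`fsc`), side scatter (`ssc`) and an
#' ordered set of named fluorescence channels, all in instrument arbitrary
#' units (a.u.). It is a plain `data.frame` with class `"event_table"`; the
#' channel columns are every column other than `fsc` and `ssc`.
#'
#' @param fsc numeric vector of forward-scatter values, a.u. (> 0).
#' @param ssc numeric vector of side-scatter values, a.u. (> 0), same length.
#' @param channels data.frame or named list of fluorescence channel columns,
#'   each the same length as `fsc`. Channel names must be unique.
#' @return An `event_table` data.frame with columns `fsc`, `ssc`, then the
#'   channels in their given order.
#' @examples
#' ev <- event_table(fsc = c(900, 1100), ssc = c(400, 520),
#'                   channels = list(`GRN-B` = c(10, 2000), `ORG-G` = c(5, 8)))
#' n_events(ev)
#' channel_names(ev)
#' @export
event_table <- function(fsc, ssc, channels = list()) {
  fsc <- as.numeric(fsc)
  ssc <- as.numeric(ssc)
  if (length(ssc) != length(fsc))
    stop("`fsc` and `ssc` must have the same length", call. = FALSE)
  channels <- as.data.frame(channels, optional = TRUE, check.names = FALSE)
  if (nrow(channels) == 0L && length(channels) > 0L && length(fsc) == 0L) {
    channels <- channels[0L, , drop = FALSE]
  }
  if (length(channels) > 0L && nrow(channels) != length(fsc))
    stop("channel columns must have length n_events", call. = FALSE)
  nm <- names(channels)
  if (anyDuplicated(nm) || any(nm %in% c("fsc", "ssc")))
    stop("channel names must be unique and distinct from 'fsc'/'ssc'",
         call. = FALSE)
  out <- data.frame(fsc = fsc, ssc = ssc, check.names = FALSE)
  if (length(channels) > 0L) out <- cbind(out, channels)
  class(out) <- c("event_table", "data.frame")
  out
}

#' @rdname event_table
#' @param x an `event_table`.
#' @export
n_events <- function(x) nrow(x)

#' @rdname event_table
#' @export
channel_names <- function(x) setdiff(names(x), c("fsc", "ssc"))

#' @rdname event_table
#' @export
channel_matrix <- function(x) {
  as.matrix(as.data.frame(x)[, channel_names(x), drop = FALSE])
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table: %d events, channels: %s>\n", nrow(x),
              paste(channel_names(x), collapse = ", ")))
  if (nrow(x) > 0L) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Read and write event tables as delimited text
#'
#' Event tables are exchanged as CSV/TSV with a one-line header naming the
#' columns `fsc`, `ssc` and then the fluorescence channels, matching the
#' cytometer-export convention used throughout the package.
#'
#' @param path file path. Extension `.tsv`/`.txt` selects tab separation,
#'   anything else comma; `sep` overrides.
#' @param sep field separator, or `NULL` to infer from the extension.
#' @return `read_events()` returns an `event_table`; `write_events()` returns
#'   `path` invisibly.
#' @export
read_events <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("fsc", "ssc") %in% names(df)))
    stop("event file must have 'fsc' and 'ssc' columns", call. = FALSE)
  event_table(df$fsc, df$ssc, df[, setdiff(names(df), c("fsc", "ssc")),
                                 drop = FALSE])
}

#' @rdname read_events
#' @param events an `event_table`.
#' @export
write_events <- function(events, path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(events), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
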