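#' Relative promoter unit (RPU) reference
#'
#' RPU normalization makes fluorophore levels comparable across experiments
#' and instruments: per-event amounts are divided by forward scatter (a cell
#' size proxy), then by the median FSC-normalized signal of a single-color
#' control strain expressing the fluorophore from the strong constitutive
#' pTDH3 promoter. By construction the reference strain itself sits at a
#' median of exactly 1 RPU.
#'
#' `rpu_reference()` builds the reference from per-fluorophore medians;
#' `estimate_rpu_reference()` computes those medians from a gated,
#' deconvolved single-color control acquisition.
#'
#' @param medians strictly positive named numeric vector: per-fluorophore
#'   median of FSC-normalized deconvolved signal of the pTDH3 control,
#'   a.u./a.u.
#' @return An `rpu_reference` object.
#' @export
rpu_reference <- function(medians) {
  medians <- unlist(medians)
  if (is.null(names(medians)) || any(!nzchar(names(medians))))
    stop("reference medians must be named by fluorophore", call. = FALSE)
  if (any(medians <= 0))
    stop("reference medians must be strictly positive", call. = FALSE)
  structure(list(medians = medians), class = "rpu_reference")
}

#' @rdname rpu_reference
#' @param amounts events x fluorophores matrix of deconvolved amounts from the
#'   control sample (see [deconvolve()]).
#' @param fsc per-event forward scatter of the same events.
#' @param fluorophores which fluorophores the control strain actually
#'   expresses; defaults to all columns.
#' @export
estimate_rpu_reference <- function(amounts, fsc, fluorophores = colnames(amounts)) {
  med <- apply(amounts[, fluorophores, drop = FALSE] / fsc, 2L, stats::median)
  rpu_reference(med)
}

#' Convert deconvolved amounts to relative promoter units
#'
#' `RPU(event, f) = (amount(event, f) / fsc(event)) / reference_median(f)`.
#' Events with non-positive FSC cannot be normalized; they are dropped from
#' the output and counted in the `excluded` attribute.
#'
#' @param amounts events x fluorophores matrix of deconvolved amounts.
#' @param fsc per-event forward scatter, a.u.
#' @param ref an [rpu_reference()] covering every fluorophore column.
#' @return Matrix of per-event RPU values (rows with bad FSC removed), with
#'   attributes `excluded` (count) and `kept_index` (row indices retained).
#' @export
to_rpu <- function(amounts, fsc, ref) {
  stopifnot(inherits(ref, "rpu_reference"))
  amounts <- as.matrix(amounts)
  missing_f <- setdiff(colnames(amounts), names(ref$medians))
  if (length(missing_f))
    stop(sprintf("reference lacks fluorophore(s): %s",
                 paste(missing_f, collapse = ", ")), call. = FALSE)
  if (length(fsc) != nrow(amounts))
    stop("fsc must have one value per event", call. = FALSE)
  ok <- is.finite(fsc) & fsc > 0
  out <- sweep(amounts[ok, , drop = FALSE] / fsc[ok], 2L,
               ref$medians[colnames(amounts)], `/`)
  attr(out, "excluded") <- sum(!ok)
  attr(out, "kept_index") <- which(ok)
  out
}

#' Genotype classification rules
#'
#' Each genotype label is a conjunction of threshold predicates on RPU values
#' (for instance, the constitutively mCerulean-marked wild type is called at
#' `mCerulean >= 1 RPU`). Labels are tried in order and the first whose
#' predicates all hold wins; events matching no label are `"unassigned"`,
#' which keeps the label set mutually exclusive and exhaustive.
#'
#' @param rules data.frame with columns `label`, `fluorophore`, `dir`
#'   (`">="` or `"<"`), `threshold` (RPU). Rows sharing a label are ANDed.
#' @return A `genotype_rules` object.
#' @examples
#' genotype_rules(data.frame(
#'   label = c("wild-type", "mutant"),
#'   fluorophore = c("mCerulean", "mCerulean"),
#'   dir = c(">=", "<"), threshold = c(1, 1)))
#' @export
genotype_rules <- function(rules) {
  rules <- as.data.frame(rules)
  need <- c("label", "fluorophore", "dir", "threshold")
  if (!all(need %in% names(rules)))
    stop("rules need columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (!all(rules$dir %in% c(">=", "<", ">", "<=")))
    stop("dir must be one of >=, >, <, <=", call. = FALSE)
  structure(list(rules = rules, labels = unique(rules$label)),
            class = "genotype_rules")
}

#' Classify events by genotype and tally fractions
#'
#' @param rpu events x fluorophores matrix of RPU values (see [to_rpu()]).
#' @param rules a [genotype_rules()]; every referenced fluorophore must be a
#'   column of `rpu`.
#' @return A list with `labels` (per-event character vector) and `fractions`
#'   (named numeric over all rule labels plus `"unassigned"`, summing to 1;
#'   all-`NaN`-free even for zero events, where fractions are 0).
#' @export
classify <- function(rpu, rules) {
  stopifnot(inherits(rules, "genotype_rules"))
  rpu <- as.matrix(rpu)
  miss <- setdiff(unique(rules$rules$fluorophore), colnames(rpu))
  if (length(miss))
    stop(sprintf("rules reference missing fluorophore(s)/channel(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  n <- nrow(rpu)
  lab <- rep("unassigned", n)
  unset <- rep(TRUE, n)
  for (L in rules$labels) {
    sub <- rules$rules[rules$rules$label == L, , drop = FALSE]
    hit <- rep(TRUE, n)
    for (i in seq_len(nrow(sub))) {
      v <- rpu[, sub$fluorophore[i]]
      hit <- hit & switch(sub$dir[i],
                          ">=" = v >= sub$threshold[i],
                          ">"  = v >  sub$threshold[i],
                          "<=" = v <= sub$threshold[i],
                          "<"  = v <  sub$threshold[i])
    }
    take <- hit & unset
    lab[take] <- L
    unset <- unset & !take
  }
  all_lab <- c(rules$labels, "unassigned")
  counts <- vapply(all_lab, function(L) sum(lab == L), numeric(1))
  fractions <- if (n > 0) counts / n else counts
  list(labels = lab, fractions = fractions)
}
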