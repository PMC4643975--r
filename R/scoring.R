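#' Confusion matrices and the Matthews correlation coefficient
#'
#' A confusion matrix here is a one-row tibble carrying TP/TN/FP/FN counts
#' plus context labels (model, medium, biomass, reference list), so that
#' matrices from a grid of screening conditions stack into one tidy table
#' and can be pooled.
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @param model_id,medium,biomass,reference context labels.
#' @return a tibble of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, tn, fp, fn, model_id = NA_character_,
                             medium = NA_character_, biomass = NA_character_,
                             reference = NA_character_) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  out <- tibble::tibble(model_id = model_id, medium = medium,
                        biomass = biomass, reference = reference,
                        TP = as.numeric(tp), TN = as.numeric(tn),
                        FP = as.numeric(fp), FN = as.numeric(fn))
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' Score single-gene essentiality predictions against a reference list
#'
#' Polarity follows the growth-screen convention: POSITIVE means
#' non-essential (viable). A true positive is a gene predicted viable that
#' is annotated viable; a gene correctly predicted essential is a true
#' negative.
#'
#' The evaluated gene universe depends on the kind of reference list:
#' \describe{
#'   \item{`"intersect"`}{(Kuepfer-style screens of a defined gene
#'     collection) only genes that are in the model, in the screen's
#'     `reference_universe`, and evaluated — genes outside the screened
#'     collection carry no annotation.}
#'   \item{`"model_genes"`}{(SGD-style whole-genome lists) all evaluated
#'     model genes; any gene not on the essential list is annotated
#'     viable.}
#' }
#'
#' @param screen a `single_screen_result`.
#' @param essential_reference character vector of ORFs annotated essential
#'   (or a file path understood by [read_gene_list()]).
#' @param universe_policy `"model_genes"` (default) or `"intersect"`.
#' @param reference_universe for `"intersect"`: the full set of genes the
#'   reference screen evaluated (defaults to `essential_reference`, which
#'   makes every universe gene annotated-essential — normally you want the
#'   full screened collection here).
#' @param reference_name label recorded in the output.
#' @return a `confusion_matrix` row.
#' @export
build_confusion_single <- function(screen, essential_reference,
                                   universe_policy = c("model_genes", "intersect"),
                                   reference_universe = NULL,
                                   reference_name = "essential_genes") {
  universe_policy <- match.arg(universe_policy)
  if (is.character(essential_reference) && length(essential_reference) == 1L &&
      file.exists(essential_reference)) {
    essential_reference <- read_gene_list(essential_reference)
  }
  g <- screen$genes[screen$genes$in_model, ]
  if (universe_policy == "intersect") {
    reference_universe <- reference_universe %||% essential_reference
    g <- g[g$gene %in% reference_universe, ]
  }
  if (nrow(g) == 0L) stop("empty evaluation universe")
  annotated_essential <- g$gene %in% essential_reference
  predicted_essential <- g$essential
  confusion_matrix(
    tp = sum(!predicted_essential & !annotated_essential),
    tn = sum(predicted_essential & annotated_essential),
    fp = sum(!predicted_essential & annotated_essential),
    fn = sum(predicted_essential & !annotated_essential),
    model_id = screen$model_id, medium = screen$medium,
    biomass = screen$biomass, reference = reference_name
  )
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' ranging from -1 (predictions exactly opposite the reference) to +1
#' (perfect agreement). When any factor of the denominator is zero the MCC
#' is defined as 0 (the usual convention for a degenerate margin), and a
#' message notes it. The denominator is computed as a product of square
#' roots so genome-scale pair counts cannot overflow double-precision
#' integer arithmetic.
#'
#' @param cm a `confusion_matrix` row (or any list/tibble with elements
#'   `TP`, `TN`, `FP`, `FN`).
#' @return numeric in \[-1, 1\].
#' @export
mcc <- function(cm) {
  tp <- as.numeric(cm$TP); tn <- as.numeric(cm$TN)
  fp <- as.numeric(cm$FP); fn <- as.numeric(cm$FN)
  stopifnot(length(tp) == 1L)
  denom_factors <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(denom_factors == 0)) {
    message("mcc: zero denominator factor, returning 0 by convention")
    return(0)
  }
  # clamp: the square-root factorization can overshoot |1| by an ulp
  max(-1, min(1, (tp * tn - fp * fn) / prod(sqrt(denom_factors))))
}

#' Pooled MCC across conditions
#'
#' The MCC of the element-wise summed confusion matrix — not the mean of
#' per-condition MCCs, which is a different (and non-equivalent) statistic.
#' This is the cross-condition aggregate used when ranking models over a
#' screening grid.
#'
#' @param cms a `confusion_matrix` tibble with one or more rows (stacked
#'   matrices).
#' @return numeric in \[-1, 1\].
#' @export
overall_mcc <- function(cms) {
  stopifnot(nrow(cms) >= 1L)
  mcc(list(TP = sum(cms$TP), TN = sum(cms$TN),
           FP = sum(cms$FP), FN = sum(cms$FN)))
}

#' @export
tidy.confusion_matrix <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x))
  out$mcc <- vapply(seq_len(nrow(out)), function(i) {
    suppressMessages(mcc(out[i, ]))
  }, numeric(1))
  out
}

#' @export
glance.confusion_matrix <- function(x, ...) {
  tibble::tibble(
    n = sum(x$TP + x$TN + x$FP + x$FN),
    conditions = nrow(x),
    pooled_mcc = suppressMessages(overall_mcc(x))
  )
}
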