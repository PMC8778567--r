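#' @importFrom rlang := sym
NULL

#' Two-class confusion counts
#'
#' Tallies true/false positives and negatives for a declared positive
#' class. Any label other than `positive` counts as negative, so
#' multiclass labels can be scored one-versus-rest.
#'
#' @param truth,estimate Vectors of labels, equal length.
#' @param positive The label treated as positive.
#' @return A one-row tibble with integer columns `trp`, `flp`, `trn`,
#'   `fln`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 0), positive = 1)
#' @export
confusion_counts <- function(truth, estimate, positive) {
  if (length(truth) != length(estimate)) {
    stop("`truth` and `estimate` must have equal length", call. = FALSE)
  }
  tp <- as.character(truth) == as.character(positive)
  ep <- as.character(estimate) == as.character(positive)
  tibble::tibble(
    trp = sum(tp & ep), flp = sum(!tp & ep),
    trn = sum(!tp & !ep), fln = sum(tp & !ep)
  )
}

#' Confusion-matrix metric suite
#'
#' Accuracy (as a percentage), precision, recall, specificity, and
#' F-score from a 2x2 tally. Two F-score variants are available:
#' `"standard"` is `2TP / (2TP + FP + FN)`; `"as_printed"` replaces the
#' false-negative term with true negatives, `2TP / (2TP + FP + TN)` — a
#' nonstandard form kept for fidelity with the source formulation, off
#' by default. A metric whose denominator is zero is reported as `NA`
#' (undefined), never as 0.
#'
#' @param counts A one-row tibble or list with `trp`, `flp`, `trn`,
#'   `fln` (e.g. from [confusion_counts()]).
#' @param f_variant `"standard"` (default) or `"as_printed"`.
#' @return A one-row tibble: `accuracy` (percent), `precision`,
#'   `recall`, `specificity`, `f_score`.
#' @examples
#' metric_suite(list(trp = 50, flp = 5, trn = 40, fln = 5))
#' @export
metric_suite <- function(counts, f_variant = c("standard", "as_printed")) {
  f_variant <- match.arg(f_variant)
  trp <- counts$trp
  flp <- counts$flp
  trn <- counts$trn
  fln <- counts$fln
  stopifnot(trp >= 0, flp >= 0, trn >= 0, fln >= 0)
  total <- trp + flp + trn + fln
  if (total == 0) stop("all counts are zero", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  f_den <- if (f_variant == "standard") 2 * trp + flp + fln else
    2 * trp + flp + trn
  tibble::tibble(
    accuracy = ratio(trp + trn, total) * 100,
    precision = ratio(trp, trp + flp),
    recall = ratio(trp, trp + fln),
    specificity = ratio(trn, trn + flp),
    f_score = ratio(2 * trp, f_den)
  )
}

#' Per-class classification report
#'
#' Scores predictions with each class taken as the positive class in
#' turn (one row per class), mirroring the usual normal/abnormal
#' two-row layout of clinical classification tables.
#'
#' @param truth,estimate Label vectors of equal length.
#' @param f_variant Passed to [metric_suite()].
#' @return A tibble of class `metric_report`: columns `class`,
#'   `accuracy`, `precision`, `recall`, `specificity`, `f_score`.
#' @export
classification_report <- function(truth, estimate,
                                  f_variant = c("standard", "as_printed")) {
  f_variant <- match.arg(f_variant)
  classes <- sort(unique(as.character(truth)))
  rows <- purrr::map(classes, function(cl) {
    dplyr::bind_cols(
      tibble::tibble(class = cl),
      metric_suite(confusion_counts(truth, estimate, positive = cl),
                   f_variant = f_variant)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("metric_report", class(out))
  out
}

#' Bar chart of a per-class metric report
#'
#' @param object A `metric_report` from [classification_report()] or
#'   [evaluate_malo_lda()].
#' @param ... Unused.
#' @return A ggplot with one panel per metric.
#' @method autoplot metric_report
#' @export
autoplot.metric_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(object), accuracy = .data$accuracy / 100),
    -"class", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value,
                                     fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Value (accuracy as fraction)") +
    ggplot2::theme_minimal()
}
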