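#' Confusion matrix of expert vs automated staging
#'
#' Counts epochs by (expert stage, predicted stage).  Inputs with an `epoch`
#' column (hypnograms, prediction tables) are matched on the epoch index and
#' only shared epochs are compared, so unscored record edges drop out of
#' both sides; plain vectors must have equal length.
#'
#' @param expert Expert labels: a [hypnogram()], prediction tibble, or
#'   factor/character vector.
#' @param predicted Automated labels, same forms.
#' @return A 3x3 integer matrix of class `confusion_matrix`; rows are expert
#'   stages, columns predicted stages.
#' @export
confusion_matrix <- function(expert, predicted) {
  if (is.data.frame(expert) && is.data.frame(predicted) &&
      "epoch" %in% names(expert) && "epoch" %in% names(predicted)) {
    shared <- intersect(expert$epoch, predicted$epoch)
    if (length(shared) == 0) abort("no shared epochs to compare")
    e <- stage_factor(expert$stage[match(shared, expert$epoch)])
    p <- stage_factor(predicted$stage[match(shared, predicted$epoch)])
  } else {
    e <- stages_of(expert)
    p <- stages_of(predicted)
    if (length(e) != length(p)) {
      abort(sprintf("length mismatch: %d expert vs %d predicted epochs",
                    length(e), length(p)))
    }
  }
  cm <- table(expert = e, predicted = p)
  out <- matrix(as.integer(cm), 3, 3,
                dimnames = list(expert = STAGE_LEVELS,
                                predicted = STAGE_LEVELS))
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' Coerce a plain 3x3 count matrix to a confusion matrix
#' @param counts 3x3 non-negative matrix, rows = expert, columns = predicted.
#' @return A `confusion_matrix`.
#' @export
as_confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3, 3))) abort("counts must be 3x3")
  if (any(counts < 0)) abort("counts must be non-negative")
  out <- matrix(as.numeric(counts), 3, 3,
                dimnames = list(expert = STAGE_LEVELS,
                                predicted = STAGE_LEVELS))
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' Agreement metrics from a confusion matrix
#'
#' Computes the standard performance indices: per-stage recall
#' (`E[s,s] / row-sum`, over expert marginals) and precision
#' (`E[s,s] / column-sum`, over predicted marginals), overall accuracy
#' (`trace / M`), the chance-agreement probability
#' `p_e = sum_s (row_s / M) * (col_s / M)`, and Cohen's kappa
#' `(accuracy - p_e) / (1 - p_e)`.  A kappa above 0.8 is conventionally
#' read as nearly perfect agreement.  A stage absent from a marginal yields
#' `NA` (undefined) for that metric, never 0.
#'
#' @param cm A [confusion_matrix()] (or 3x3 count matrix).
#' @return A `sleep_metrics` object.
#' @examples
#' cm <- as_confusion_matrix(diag(c(10, 8, 2)))
#' compute_metrics(cm)$kappa  # 1
#' @export
compute_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) cm <- as_confusion_matrix(cm)
  M <- sum(cm)
  if (M < 1) abort("confusion matrix must contain at least one epoch")
  rows <- rowSums(cm)
  cols <- colSums(cm)
  recall <- ifelse(rows > 0, diag(cm) / rows, NA_real_)
  precision <- ifelse(cols > 0, diag(cm) / cols, NA_real_)
  accuracy <- sum(diag(cm)) / M
  p_e <- sum((rows / M) * (cols / M))
  kappa <- if (p_e < 1) (accuracy - p_e) / (1 - p_e) else NA_real_
  structure(list(confusion = cm,
                 recall = setNames(recall, STAGE_LEVELS),
                 precision = setNames(precision, STAGE_LEVELS),
                 accuracy = accuracy, p_e = p_e, kappa = kappa, n = M),
            class = "sleep_metrics")
}

#' @export
print.sleep_metrics <- function(x, ...) {
  cat(sprintf("<sleep_metrics> %s epochs: accuracy %.1f%%, kappa %.2f\n",
              format(x$n, big.mark = ","), 100 * x$accuracy, x$kappa))
  print(format_metrics_table(x))
  invisible(x)
}

#' @export
tidy.sleep_metrics <- function(x, ...) {
  bind_rows(
    tibble(metric = "recall", stage = STAGE_LEVELS, value = unname(x$recall)),
    tibble(metric = "precision", stage = STAGE_LEVELS,
           value = unname(x$precision)),
    tibble(metric = c("accuracy", "p_e", "kappa"), stage = NA_character_,
           value = c(x$accuracy, x$p_e, x$kappa)))
}

#' @export
glance.sleep_metrics <- function(x, ...) {
  tibble(accuracy = x$accuracy, kappa = x$kappa, p_e = x$p_e, n = x$n)
}

#' Format a metrics report as a display table
#'
#' One row in the conventional benchmark layout: recall and precision per
#' stage as percentages with one decimal, accuracy likewise, kappa with two
#' decimals; undefined metrics render as an em dash.
#'
#' @param report A `sleep_metrics` object.
#' @return A one-row tibble of formatted strings.
#' @export
format_metrics_table <- function(report) {
  stopifnot(inherits(report, "sleep_metrics"))
  pct <- function(v) {
    v <- unname(v)
    ifelse(is.na(v), "\u2014", sprintf("%.1f%%", 100 * v))
  }
  tibble(wake_recall = pct(report$recall["WAKE"]),
         wake_precision = pct(report$precision["WAKE"]),
         nrem_recall = pct(report$recall["NREM"]),
         nrem_precision = pct(report$precision["NREM"]),
         rem_recall = pct(report$recall["REM"]),
         rem_precision = pct(report$precision["REM"]),
         accuracy = pct(report$accuracy),
         kappa = ifelse(is.na(report$kappa), "\u2014",
                        sprintf("%.2f", report$kappa)))
}

#' Parse a formatted metrics table back to numbers
#'
#' Inverse of [format_metrics_table()] up to display rounding.
#'
#' @param table One-row tibble of formatted strings.
#' @return Named numeric vector (proportions, not percent).
#' @export
parse_metrics_table <- function(table) {
  vals <- vapply(as.list(table[1, ]), function(s) {
    if (s == "\u2014") return(NA_real_)
    if (grepl("%$", s)) as.numeric(sub("%$", "", s)) / 100 else as.numeric(s)
  }, numeric(1))
  vals
}
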