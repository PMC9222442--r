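#' Confusion matrix from labels
#'
#' @param truth,predicted Label vectors of equal length.
#' @param classes Class order (default: sorted union; the study convention
#'   is control first, dex second).
#' @return Square counts matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  stopifnot(length(truth) == length(predicted))
  if (is.null(classes)) classes <- sort(unique(c(as.character(truth),
                                                 as.character(predicted))))
  tab <- table(factor(truth, levels = classes),
               factor(predicted, levels = classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

#' Per-class classification metrics
#'
#' For class k: sensitivity = correctly assigned k / true k;
#' specificity = correctly assigned non-k / true non-k;
#' precision = correctly assigned k / predicted k. The Non-Error-Rate
#' (NER%) is the unweighted mean of the per-class sensitivities (robust to
#' class imbalance); accuracy% is the trace over the total. All values are
#' percentages; the print method shows 2 decimals (the reporting
#' convention), values are kept at full precision.
#'
#' For two classes, sensitivity of one class equals specificity of the
#' other — both count the same correctly classified samples.
#'
#' @param cm Square confusion matrix (rows = truth) from
#'   [confusion_matrix()].
#' @return A `class_metrics` list: `ner_pct`, `accuracy_pct`, `per_class`
#'   tibble (class, n, precision_pct, sensitivity_pct, specificity_pct)
#'   and the matrix itself.
#' @export
compute_metrics <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), all(cm >= 0))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  n_true <- rowSums(cm)
  if (any(n_true == 0)) {
    stop("class(es) with no true samples: sensitivity undefined for ",
         paste(rownames(cm)[n_true == 0], collapse = ", "))
  }
  n_pred <- colSums(cm)
  correct <- diag(cm)
  sens <- correct / n_true * 100
  spec <- vapply(seq_len(nrow(cm)), function(k) {
    sum(correct[-k]) / sum(n_true[-k]) * 100
  }, numeric(1))
  prec <- ifelse(n_pred > 0, correct / n_pred * 100, NA_real_)
  if (anyNA(prec)) {
    warning("class(es) never predicted: precision undefined for ",
            paste(rownames(cm)[is.na(prec)], collapse = ", "))
  }
  structure(list(
    ner_pct = mean(sens),
    accuracy_pct = sum(correct) / total * 100,
    per_class = tibble::tibble(class = rownames(cm), n = as.integer(n_true),
                               precision_pct = unname(prec),
                               sensitivity_pct = unname(sens),
                               specificity_pct = unname(spec)),
    confusion = cm
  ), class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("NER%% %.2f  Accuracy%% %.2f\n", x$ner_pct, x$accuracy_pct))
  pc <- x$per_class
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  %-12s precision %6.2f  sensitivity %6.2f  specificity %6.2f\n",
                pc$class[i], pc$precision_pct[i], pc$sensitivity_pct[i],
                pc$specificity_pct[i]))
  }
  invisible(x)
}
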