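# Confusion-matrix evaluation: per-class precision/recall/F1 via one-vs-rest
# reduction, macro (unweighted) and support-weighted aggregation, one-vs-rest
# ROC-AUC, and McNemar's paired test.

#' Confusion matrix from label vectors
#'
#' @param truth,pred Vectors of true and predicted class labels, equal
#'   length, drawn from `class_labels`.
#' @param class_labels Ordered class names fixing row/column order.
#' @return Integer C x C matrix; rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, pred, class_labels) {
  if (length(truth) != length(pred))
    stop("truth and pred must have the same length", call. = FALSE)
  truth <- as.character(truth); pred <- as.character(pred)
  unknown <- setdiff(unique(c(truth, pred)), class_labels)
  if (length(unknown) > 0)
    stop("unknown label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  tab <- table(factor(truth, levels = class_labels),
               factor(pred, levels = class_labels))
  m <- matrix(as.integer(tab), nrow = length(class_labels),
              dimnames = list(true = class_labels, predicted = class_labels))
  m
}

#' Classification report from a confusion matrix
#'
#' One-vs-rest reduction per class c: `TP = diag(c)`, `FP = colsum - TP`,
#' `FN = rowsum - TP`; precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' F1 `TP/(TP + (FP+FN)/2)`. Zero-denominator metrics are reported as 0
#' with a warning (a conservative convention). Headline aggregates are
#' macro (unweighted means across classes); support-weighted versions are
#' reported alongside but never mixed into the macro cells. Displayed
#' values round half away from zero to `rounding` decimals.
#'
#' @param confusion C x C count matrix from [confusion_matrix()].
#' @param rounding Decimal places used by the print method (default 4).
#' @return An object of class `evaluation_report`: list with `confusion`,
#'   `per_class` (data frame: precision, recall, f1, support), `accuracy`,
#'   `macro_precision`, `macro_recall`, `macro_f1`, their
#'   `weighted_*` counterparts, and `rounding`.
#' @export
classification_report <- function(confusion, rounding = 4) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  if (any(confusion < 0) || any(confusion != round(confusion)))
    stop("confusion entries must be nonnegative counts", call. = FALSE)
  labels <- rownames(confusion) %||% paste0("class", seq_len(nrow(confusion)))
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  support <- rowSums(confusion)
  total <- sum(confusion)

  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad))
      warning(sprintf("%s undefined (zero denominator) for class(es) %s; reported as 0",
                      what, paste(labels[bad], collapse = ", ")),
              call. = FALSE)
    ifelse(den == 0, 0, num / den)
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- safe_div(tp, tp + (fp + fn) / 2, "F1")

  wmean <- function(v) if (total == 0) 0 else sum(v * support) / total
  structure(list(
    confusion = confusion,
    per_class = data.frame(class = labels, precision = precision,
                           recall = recall, f1 = f1, support = support,
                           row.names = NULL),
    accuracy = if (total == 0) 0 else sum(tp) / total,
    macro_precision = macro_average(precision),
    macro_recall = macro_average(recall),
    macro_f1 = macro_average(f1),
    weighted_precision = wmean(precision),
    weighted_recall = wmean(recall),
    weighted_f1 = wmean(f1),
    rounding = rounding), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  r <- function(v) round_half_up(v, x$rounding)
  cat(sprintf("<evaluation_report> %d samples, %d classes\n",
              sum(x$confusion), nrow(x$confusion)))
  pc <- x$per_class
  pc[c("precision", "recall", "f1")] <- lapply(
    pc[c("precision", "recall", "f1")], r)
  print(pc, row.names = FALSE)
  cat(sprintf("accuracy %s | macro P %s R %s F1 %s\n",
              r(x$accuracy), r(x$macro_precision), r(x$macro_recall),
              r(x$macro_f1)))
  invisible(x)
}

#' Macro (unweighted) average of per-class metric values
#'
#' @param values Numeric vector of per-class values, length >= 1.
#' @return Their unweighted arithmetic mean. Use [round_half_up()] for the
#'   conventional 4-decimal display.
#' @examples
#' macro_average(c(0.9583, 1, 1))  # 0.98610
#' @export
macro_average <- function(values) {
  if (length(values) == 0) stop("no per-class values to average", call. = FALSE)
  mean(values)
}

#' One-vs-rest ROC-AUC
#'
#' Per-class AUC via the rank (Mann-Whitney) statistic with ties counted
#' half: treating class c as positive and everything else negative,
#' `AUC_c = (sum of positive ranks - n_pos (n_pos + 1) / 2) / (n_pos n_neg)`.
#' A class with no positives or no negatives has an undefined AUC and is
#' reported as `NA`, never as 0.
#'
#' @param class_scores Numeric matrix (samples x classes) of
#'   higher-is-better scores; for fused output see [fds_to_scores()].
#' @param truth True class labels, one per row.
#' @return List with `per_class` (named numeric, possibly `NA`) and `macro`
#'   (mean over the defined classes).
#' @export
roc_auc_ovr <- function(class_scores, truth) {
  stopifnot(is.matrix(class_scores), nrow(class_scores) == length(truth))
  if (any(!is.finite(class_scores)))
    stop("scores must be finite", call. = FALSE)
  labels <- colnames(class_scores) %||% paste0("class",
                                               seq_len(ncol(class_scores)))
  truth <- as.character(truth)
  auc <- vapply(seq_along(labels), function(j) {
    pos <- truth == labels[j]
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(class_scores[, j], ties.method = "average")
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  names(auc) <- labels
  list(per_class = auc, macro = mean(auc, na.rm = TRUE))
}

#' McNemar's paired test on two classifiers' predictions
#'
#' Compares two classifiers on the same samples through the discordant
#' counts b (first correct, second wrong) and c (first wrong, second
#' correct). For `b + c < 25` the exact two-sided binomial p-value is used
#' (doubled smaller tail under Binomial(b + c, 1/2), clamped at 1);
#' otherwise the continuity-corrected chi-square statistic
#' `(|b - c| - 1)^2 / (b + c)` on 1 degree of freedom.
#'
#' @param pred_a,pred_b Predicted labels from the two classifiers.
#' @param truth True labels; all three vectors equal length.
#' @return An object of class `mcnemar_result`: list with `b`, `c`,
#'   `statistic` (chi-square value or `NA` for the exact branch), `p_value`,
#'   `method` (`"exact"` or `"chi2_cc"`), and `degenerate` (`TRUE` when
#'   `b + c == 0`, in which case `p_value = 1`).
#' @examples
#' truth <- rep("a", 12)
#' pa <- rep("a", 12); pb <- c(rep("b", 10), rep("a", 2))
#' mcnemar_test(pa, pb, truth)  # b = 10, c = 0 pattern
#' @export
mcnemar_test <- function(pred_a, pred_b, truth) {
  if (length(pred_a) != length(truth) || length(pred_b) != length(truth))
    stop("pred_a, pred_b and truth must have the same length", call. = FALSE)
  ok_a <- as.character(pred_a) == as.character(truth)
  ok_b <- as.character(pred_b) == as.character(truth)
  b <- sum(ok_a & !ok_b)
  c <- sum(!ok_a & ok_b)
  n <- b + c
  if (n == 0) {
    res <- list(b = b, c = c, statistic = NA_real_, p_value = 1,
                method = "exact", degenerate = TRUE)
  } else if (n < 25) {
    p <- min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
    res <- list(b = b, c = c, statistic = NA_real_, p_value = p,
                method = "exact", degenerate = FALSE)
  } else {
    stat <- (abs(b - c) - 1)^2 / n
    res <- list(b = b, c = c, statistic = stat,
                p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                method = "chi2_cc", degenerate = FALSE)
  }
  structure(res, class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("McNemar test (%s): b = %d, c = %d, p = %.4g%s\n",
              x$method, x$b, x$c, x$p_value,
              if (x$degenerate) " [degenerate: no discordant pairs]" else ""))
  invisible(x)
}
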