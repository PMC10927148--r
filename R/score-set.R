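#' Build an ensemble score set
#'
#' Container for the aligned per-classifier confidence matrices that every
#' fusion routine in the package consumes. Each of the M matrices holds one
#' base classifier's per-class confidence (softmax output) for the same
#' samples in the same order; rows are samples, columns are classes.
#'
#' @param matrices List of M numeric matrices (samples x classes) with
#'   identical dimensions.
#' @param sample_ids Character vector of sample identifiers (defaults to
#'   rownames of the first matrix, or `s1..sn`).
#' @param class_labels Character vector of class names, length C >= 2
#'   (defaults to colnames of the first matrix, or `class1..classC`).
#' @param classifier_names Character vector of M classifier identifiers.
#' @return An object of class `score_set`: a list with fields `matrices`,
#'   `sample_ids`, `class_labels`, `classifier_names`.
#' @examples
#' m <- matrix(c(0.7, 0.2, 0.1), 1, dimnames = list("s1", c("a", "b", "c")))
#' score_set(list(m, m))
#' @export
score_set <- function(matrices, sample_ids = NULL, class_labels = NULL,
                      classifier_names = NULL) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  matrices <- lapply(matrices, function(m) {
    if (!is.matrix(m)) m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  d <- dim(matrices[[1]])
  if (d[2] < 2) stop("at least two classes are required", call. = FALSE)
  ok <- vapply(matrices, function(m) identical(dim(m), d), logical(1))
  if (!all(ok)) stop("all classifier matrices must share the same shape",
                     call. = FALSE)
  sample_ids <- sample_ids %||% rownames(matrices[[1]]) %||%
    paste0("s", seq_len(d[1]))
  class_labels <- class_labels %||% colnames(matrices[[1]]) %||%
    paste0("class", seq_len(d[2]))
  classifier_names <- classifier_names %||% names(matrices) %||%
    paste0("model", seq_along(matrices))
  stopifnot(length(sample_ids) == d[1], length(class_labels) == d[2],
            length(classifier_names) == length(matrices))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  for (i in seq_along(matrices)) {
    rn <- rownames(matrices[[i]]); cn <- colnames(matrices[[i]])
    if (!is.null(rn) && !identical(rn, as.character(sample_ids)))
      stop(sprintf("classifier '%s': sample ids disagree with the set",
                   classifier_names[i]), call. = FALSE)
    if (!is.null(cn) && !identical(cn, as.character(class_labels)))
      stop(sprintf("classifier '%s': class labels disagree with the set",
                   classifier_names[i]), call. = FALSE)
    dimnames(matrices[[i]]) <- list(sample_ids, class_labels)
  }
  names(matrices) <- classifier_names
  structure(list(matrices = matrices,
                 sample_ids = as.character(sample_ids),
                 class_labels = as.character(class_labels),
                 classifier_names = as.character(classifier_names)),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("<score_set> %d classifiers x %d samples x %d classes\n",
              length(x$matrices), length(x$sample_ids),
              length(x$class_labels)))
  cat("  classifiers:", paste(x$classifier_names, collapse = ", "), "\n")
  cat("  classes:    ", paste(x$class_labels, collapse = ", "), "\n")
  invisible(x)
}

n_models <- function(x) length(x$matrices)
n_classes <- function(x) length(x$class_labels)
n_samples <- function(x) length(x$sample_ids)

#' Validate (and optionally renormalize) a score set
#'
#' Enforces the probability-simplex contract: every row of every classifier
#' matrix must be nonnegative and sum to 1 within `tolerance`. Softmax
#' outputs saved at limited precision rarely sum to 1 exactly, so the
#' default policy rescales each positive-sum row by its sum (with a warning
#' when any row was off by more than `tolerance`); the `"strict"` policy
#' errors instead of rescaling.
#'
#' @param x A [score_set()].
#' @param tolerance Maximum tolerated absolute deviation of a row sum from 1
#'   (default `1e-6`).
#' @param policy `"renormalize"` (default) or `"strict"`.
#' @return The validated `score_set`, with every row summing to 1 within
#'   `tolerance`.
#' @examples
#' m <- matrix(c(2, 3, 5), 1, dimnames = list("s1", c("a", "b", "c")))
#' validate_scores(score_set(list(m)), policy = "renormalize")
#' @export
validate_scores <- function(x, tolerance = 1e-6,
                            policy = c("renormalize", "strict")) {
  stopifnot(inherits(x, "score_set"), tolerance > 0)
  policy <- match.arg(policy)
  for (i in seq_along(x$matrices)) {
    m <- x$matrices[[i]]
    if (any(m < -1e-9))
      stop(sprintf("classifier '%s': negative confidence at sample %s",
                   x$classifier_names[i],
                   x$sample_ids[which(rowSums(m < -1e-9) > 0)[1]]),
           call. = FALSE)
    m[m < 0] <- 0
    rs <- rowSums(m)
    if (any(rs <= 0))
      stop(sprintf("classifier '%s': zero-sum confidence row at sample %s",
                   x$classifier_names[i], x$sample_ids[which(rs <= 0)[1]]),
           call. = FALSE)
    off <- abs(rs - 1) > tolerance
    if (any(off)) {
      if (policy == "strict")
        stop(sprintf(
          "classifier '%s': row sum %.8f at sample %s deviates from 1 by more than %g",
          x$classifier_names[i], rs[which(off)[1]],
          x$sample_ids[which(off)[1]], tolerance), call. = FALSE)
      warning(sprintf(
        "classifier '%s': renormalized %d row(s) whose sums deviated from 1 by more than %g",
        x$classifier_names[i], sum(off), tolerance), call. = FALSE)
    }
    x$matrices[[i]] <- m / rs
  }
  x
}
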