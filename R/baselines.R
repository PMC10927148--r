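# Classical decision-fusion baselines sharing the score_set contract:
# maximum probability, average probability, sum rule, majority voting and
# accuracy-weighted average.

BASELINE_METHODS <- c("maximum_probability", "average_probability",
                      "sum_rule", "majority_voting", "weighted_average")

#' Fuse a score set with a classical ensemble rule
#'
#' @param scores A validated [score_set()].
#' @param method One of `"maximum_probability"` (argmax over classes of the
#'   per-class maximum across classifiers), `"average_probability"` (argmax
#'   of the mean), `"sum_rule"` (argmax of the sum; always yields the same
#'   labels as the average), `"majority_voting"` (plurality over each
#'   classifier's argmax vote, ties broken by highest mean confidence then
#'   class order), or `"weighted_average"` (argmax of the weighted mean).
#' @param weights Per-classifier nonnegative weights, required for
#'   `"weighted_average"`; normalized to sum to 1. See [accuracy_weights()].
#' @return List with `label` (character vector of fused labels) and `score`
#'   (the per-class fused score matrix the argmax was taken over; for
#'   majority voting, the vote counts).
#' @examples
#' m1 <- matrix(c(0.7, 0.2, 0.1), 1); m2 <- matrix(c(0.6, 0.3, 0.1), 1)
#' m3 <- matrix(c(0.1, 0.8, 0.1), 1)
#' baseline_fuse(score_set(list(m1, m2, m3)), "majority_voting")$label
#' @export
baseline_fuse <- function(scores, method = BASELINE_METHODS, weights = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(scores, "score_set"))
  M <- n_models(scores)
  labels <- scores$class_labels
  arr <- simplify2array(scores$matrices)  # samples x classes x M
  if (n_samples(scores) == 1)
    arr <- array(arr, dim = c(1, n_classes(scores), M))

  score <- switch(method,
    maximum_probability = apply(arr, c(1, 2), max),
    average_probability = apply(arr, c(1, 2), mean),
    sum_rule = apply(arr, c(1, 2), sum),
    majority_voting = {
      votes <- matrix(0, dim(arr)[1], dim(arr)[2])
      for (i in seq_len(M)) {
        w <- apply(arr[, , i, drop = FALSE], 1, which.max)
        votes[cbind(seq_along(w), w)] <- votes[cbind(seq_along(w), w)] + 1
      }
      votes
    },
    weighted_average = {
      if (is.null(weights))
        stop("weighted_average requires per-classifier weights", call. = FALSE)
      if (length(weights) != M)
        stop(sprintf("expected %d weights, got %d", M, length(weights)),
             call. = FALSE)
      if (any(weights < 0) || sum(weights) <= 0)
        stop("weights must be nonnegative and not all zero", call. = FALSE)
      w <- weights / sum(weights)
      out <- 0
      for (i in seq_len(M)) out <- out + w[i] * arr[, , i]
      matrix(out, dim(arr)[1], dim(arr)[2])
    })
  dimnames(score) <- list(scores$sample_ids, labels)

  if (method == "majority_voting") {
    # plurality; ties -> highest mean confidence among tied classes, then
    # class order (which.max is first-wins)
    mean_cof <- apply(arr, c(1, 2), mean)
    pick <- integer(nrow(score))
    for (s in seq_len(nrow(score))) {
      tied <- which(score[s, ] == max(score[s, ]))
      pick[s] <- if (length(tied) == 1) tied
                 else tied[which.max(mean_cof[s, tied])]
    }
    label <- labels[pick]
  } else {
    label <- labels[apply(score, 1, which.max)]
  }
  list(label = label, score = score, method = method)
}

#' Accuracy-proportional classifier weights
#'
#' The weighted-average baseline weights each base classifier only by its
#' accuracy: `w_i = acc_i / sum(acc)`.
#'
#' @param accuracies Numeric vector of per-classifier accuracies in
#'   \[0, 1\], not all zero.
#' @return Weights summing to 1.
#' @examples
#' accuracy_weights(c(0.9902, 0.9726, 0.9945))
#' @export
accuracy_weights <- function(accuracies) {
  stopifnot(is.numeric(accuracies), length(accuracies) >= 1)
  if (any(accuracies < 0 | accuracies > 1))
    stop("accuracies must lie in [0, 1]", call. = FALSE)
  if (sum(accuracies) <= 0)
    stop("accuracies must not all be zero", call. = FALSE)
  accuracies / sum(accuracies)
}
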