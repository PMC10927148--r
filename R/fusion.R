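# Fusion core: ordinal top-k membership, penalized fuzzy rank sum (FRS),
# complemented confidence factor sum (CCFS), final decision score
# FDS = FRS * CCFS, and the fused argmin decision.

PENALTY_RANK <- 1   # rank assigned to a class outside a classifier's top-k
PENALTY_COF <- 0    # confidence contribution of such a class

#' Ordinal ranks of classes by ascending fuzzy rank
#'
#' For each sample, classes are sorted by ascending fuzzy-rank value (i.e.
#' descending confidence, since the transform is decreasing) and receive
#' ordinal ranks 1..C. Ties are broken by class position: the first listed
#' class wins, keeping the output deterministic and order-stable.
#'
#' @param ranks Fuzzy-rank matrix (samples x classes) from
#'   [rank_transform()], or a list of such matrices (one per classifier).
#' @return Integer matrix (or list of matrices) of ordinal ranks, 1 = best.
#' @export
ordinal_ranks <- function(ranks) {
  if (is.list(ranks)) return(lapply(ranks, ordinal_ranks))
  stopifnot(is.matrix(ranks))
  out <- matrix(0L, nrow(ranks), ncol(ranks), dimnames = dimnames(ranks))
  for (s in seq_len(nrow(ranks)))
    out[s, ] <- rank(ranks[s, ], ties.method = "first")
  out
}

#' Top-k membership from ordinal ranks
#'
#' @param ordinals Integer matrix (samples x classes) of ordinal ranks, or a
#'   list of them (one per classifier).
#' @param k Integer cut, `1 <= k <= C`. Each membership row contains exactly
#'   `k` classes; `k = C` includes every class so no penalties are ever
#'   applied downstream.
#' @return Logical matrix (or list) marking the classes whose ordinal rank
#'   is at most `k`.
#' @export
select_topk <- function(ordinals, k) {
  if (is.list(ordinals)) return(lapply(ordinals, select_topk, k = k))
  stopifnot(is.matrix(ordinals))
  C <- ncol(ordinals)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > C || k != round(k))
    stop(sprintf("k must be an integer in 1..%d, got %s", C,
                 deparse(k)), call. = FALSE)
  ordinals <= as.integer(k)
}

#' Penalized fuzzy rank sum (FRS)
#'
#' Sums each class's fuzzy rank across classifiers, substituting the rank
#' penalty `P_R = 1` (the transform's value at confidence 0) whenever the
#' class misses that classifier's top-k. The result lies in \[0, M\]; a
#' class in no top-k set attains exactly M.
#'
#' @param ranks List of M fuzzy-rank matrices.
#' @param membership List of M logical top-k membership matrices from
#'   [select_topk()].
#' @return Numeric matrix (samples x classes) of FRS values.
#' @export
fuzzy_rank_sum <- function(ranks, membership) {
  stopifnot(is.list(ranks), is.list(membership),
            length(ranks) == length(membership))
  out <- matrix(0, nrow(ranks[[1]]), ncol(ranks[[1]]),
                dimnames = dimnames(ranks[[1]]))
  for (i in seq_along(ranks))
    out <- out + ifelse(membership[[i]], ranks[[i]], PENALTY_RANK)
  out
}

#' Complemented confidence factor sum (CCFS)
#'
#' Averages each class's confidence across the classifiers whose top-k
#' contains it, substituting the confidence penalty `P_CoF = 0` elsewhere.
#' Under the default `"complement"` variant the result is one minus that
#' mean, so a class absent from every top-k gets CCFS = 1 — together with
#' FRS = M this prevents an improbable class from winning the argmin. The
#' `"literal"` variant returns the raw mean itself and is kept for audit
#' only: combined with the argmin rule it would hand the decision to
#' low-confidence classes.
#'
#' @param scores A validated [score_set()].
#' @param membership List of M logical top-k matrices.
#' @param variant `"complement"` (default) or `"literal"`.
#' @return Numeric matrix (samples x classes) of CCFS values; the complement
#'   variant lies in \[0, 1\].
#' @export
complement_confidence_sum <- function(scores, membership,
                                      variant = c("complement", "literal")) {
  variant <- match.arg(variant)
  stopifnot(inherits(x = scores, "score_set"),
            length(membership) == n_models(scores))
  M <- n_models(scores)
  acc <- matrix(0, n_samples(scores), n_classes(scores),
                dimnames = list(scores$sample_ids, scores$class_labels))
  for (i in seq_len(M))
    acc <- acc + ifelse(membership[[i]], scores$matrices[[i]], PENALTY_COF)
  mean_cof <- acc / M
  if (variant == "complement") 1 - mean_cof else mean_cof
}

#' Final decision score
#'
#' @param frs FRS matrix from [fuzzy_rank_sum()].
#' @param ccfs CCFS matrix from [complement_confidence_sum()].
#' @return Elementwise product `FDS = FRS * CCFS`.
#' @export
final_decision_score <- function(frs, ccfs) {
  stopifnot(identical(dim(frs), dim(ccfs)))
  frs * ccfs
}

#' Fused label from final decision scores
#'
#' The fused class for each sample is the one minimizing FDS; ties are
#' broken by class order (first listed wins).
#'
#' @param fds Numeric matrix (samples x classes) of final decision scores.
#' @return Character vector of fused class labels (column names of `fds`).
#' @export
decide <- function(fds) {
  stopifnot(is.matrix(fds), ncol(fds) >= 2)
  labels <- colnames(fds) %||% paste0("class", seq_len(ncol(fds)))
  labels[apply(fds, 1, which.min)]
}

#' Fuzzy-rank ensemble fusion
#'
#' The full decision-fusion pipeline: validates the score set, applies the
#' Mitscherlich rank transform to every classifier's confidence matrix,
#' derives ordinal top-k membership per classifier and sample, accumulates
#' the penalized fuzzy rank sum (FRS) and complemented confidence factor
#' sum (CCFS), multiplies them into the final decision score (FDS), and
#' picks the class minimizing FDS. Fully deterministic.
#'
#' @param scores A [score_set()] (validated here with the given policy).
#' @param k Top-k cut, default 2: with three or more classes this exercises
#'   the penalty machinery while keeping the two plausible classes of each
#'   classifier in play; `k = C` disables penalties entirely.
#' @param variant CCFS reading, `"complement"` (default) or `"literal"`;
#'   see [complement_confidence_sum()].
#' @param fn Rank transform, a [rank_function()].
#' @param tolerance,policy Passed to [validate_scores()].
#' @return An object of class `fusion_result`: list with matrices `frs`,
#'   `ccfs`, `fds` (samples x classes), `fused_label` (character vector),
#'   `k`, `variant`, and the fixed `penalties` `(P_R = 1, P_CoF = 0)`.
#' @examples
#' m1 <- matrix(c(0.7, 0.2, 0.1), 1); m2 <- matrix(c(0.6, 0.3, 0.1), 1)
#' m3 <- matrix(c(0.1, 0.8, 0.1), 1)
#' fuse(score_set(list(m1, m2, m3)), k = 2)$fused_label
#' @export
fuse <- function(scores, k = 2, variant = c("complement", "literal"),
                 fn = rank_function(), tolerance = 1e-6,
                 policy = "renormalize") {
  variant <- match.arg(variant)
  scores <- validate_scores(scores, tolerance = tolerance, policy = policy)
  ranks <- lapply(scores$matrices, rank_transform, fn = fn)
  membership <- select_topk(ordinal_ranks(ranks), k = k)
  frs <- fuzzy_rank_sum(ranks, membership)
  ccfs <- complement_confidence_sum(scores, membership, variant = variant)
  fds <- final_decision_score(frs, ccfs)
  structure(list(frs = frs, ccfs = ccfs, fds = fds,
                 fused_label = decide(fds),
                 k = as.integer(k), variant = variant,
                 penalties = c(P_R = PENALTY_RANK, P_CoF = PENALTY_COF),
                 class_labels = scores$class_labels,
                 sample_ids = scores$sample_ids),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result> %d samples, %d classes, k = %d, variant = %s\n",
              nrow(x$fds), ncol(x$fds), x$k, x$variant))
  print(utils::head(table(fused = x$fused_label)))
  invisible(x)
}

#' Convert final decision scores to ROC-usable class scores
#'
#' FDS is a loss (lower is better); one-vs-rest ROC needs a higher-is-better
#' score. Uses `s_c = (M - FDS_c) / sum_c (M - FDS_c)`, a normalized
#' reflection about the maximum attainable FDS.
#'
#' @param result A `fusion_result`.
#' @param n_models Number of base classifiers M (the FDS upper bound).
#' @return Numeric matrix of per-class scores, rows summing to 1.
#' @export
fds_to_scores <- function(result, n_models) {
  stopifnot(inherits(result, "fusion_result"), n_models >= 1)
  s <- n_models - result$fds
  s / rowSums(s)
}
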