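#' Mitscherlich fuzzy-rank transform
#'
#' Maps a confidence score (softmax probability) in \[0, 1\] to a fuzzy rank
#' in \[0, 1\] using the re-parameterized Mitscherlich function
#' \deqn{R(x) = 2\,(1 - 2^{x-1}),}
#' an exponential saturation law borrowed from the crop-yield response
#' family. Lower rank values are better: `R(1) = 0` is the best attainable
#' rank and `R(0) = 1` is the worst, which doubles as the rank penalty
#' applied to classes outside a classifier's top-k. The curve is strictly
#' decreasing and drops most steeply as the confidence approaches 1, so
#' near-certain predictions are separated much more sharply than uncertain
#' ones.
#'
#' @param cof Numeric vector of confidence scores in \[0, 1\]. Values outside
#'   the interval by at most `1e-9` (ulp-level softmax overshoot) are
#'   clamped; larger excursions are an error.
#' @return Numeric vector of fuzzy ranks in \[0, 1\], same length as `cof`.
#' @examples
#' mitscherlich_rank(c(0, 0.5, 1))
#' @seealso [rank_transform()], [rank_function()]
#' @export
mitscherlich_rank <- function(cof) {
  cof <- clamp_unit(cof)
  2 * (1 - 2^(cof - 1))
}

#' Rank-function objects
#'
#' A `rank_function` bundles a name with a transform mapping confidence to
#' fuzzy rank and the penalty rank it assigns at confidence 0. Only the
#' Mitscherlich transform ships with the package, but the constructor is the
#' extension point for benchmarking alternative decreasing transforms: any
#' candidate must satisfy `transform(0) = 1`, `transform(1) = 0` and strict
#' monotone decrease on \[0, 1\], which the constructor checks on a grid.
#'
#' @param name Identifier for the transform.
#' @param transform Vectorized function from confidence in \[0,1\] to rank in
#'   \[0,1\].
#' @return An object of class `rank_function` with fields `name`,
#'   `transform` and `penalty_rank` (the value at confidence 0, always 1).
#' @examples
#' fn <- rank_function()
#' fn$transform(0.5)
#' @export
rank_function <- function(name = "mitscherlich", transform = mitscherlich_rank) {
  stopifnot(is.character(name), length(name) == 1, is.function(transform))
  grid <- seq(0, 1, by = 0.01)
  y <- transform(grid)
  if (abs(y[1] - 1) > 1e-12 || abs(y[length(y)]) > 1e-12)
    stop("rank function must satisfy transform(0) = 1 and transform(1) = 0",
         call. = FALSE)
  if (any(diff(y) >= 0))
    stop("rank function must be strictly decreasing on [0,1]", call. = FALSE)
  structure(list(name = name, transform = transform, penalty_rank = y[1]),
            class = "rank_function")
}

#' @export
print.rank_function <- function(x, ...) {
  cat("<rank_function>", x$name,
      sprintf("  [f(0) = %g, f(1) = %g]\n", x$penalty_rank, x$transform(1)))
  invisible(x)
}

#' Apply a rank transform elementwise to a confidence matrix
#'
#' @param scores Numeric matrix of confidences (samples in rows, classes in
#'   columns), entries in \[0, 1\].
#' @param fn A [rank_function()]; defaults to the Mitscherlich transform.
#' @return A fuzzy-rank matrix of the same shape and dimnames.
#' @examples
#' m <- matrix(c(1, 0, 0, 1/3, 1/3, 1/3), nrow = 2, byrow = TRUE)
#' rank_transform(m)
#' @export
rank_transform <- function(scores, fn = rank_function()) {
  stopifnot(is.matrix(scores) || is.numeric(scores))
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = 1)
  if (length(scores) == 0) return(scores)
  out <- tryCatch(fn$transform(scores), error = function(e) {
    bad <- which(scores < -1e-9 | scores > 1 + 1e-9, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf("confidence out of [0,1] at sample %s, class %s: %.6g",
                   rownames(scores)[bad[1, 1]] %||% bad[1, 1],
                   colnames(scores)[bad[1, 2]] %||% bad[1, 2],
                   scores[bad[1, 1], bad[1, 2]]), call. = FALSE)
    }
    stop(e)
  })
  dim(out) <- dim(scores)
  dimnames(out) <- dimnames(scores)
  out
}

#' Tabulate a rank transform on a grid
#'
#' Convenience used by the `rankfn` command-line subcommand: evaluates the
#' transform on an evenly spaced grid and returns a two-column data frame.
#'
#' @param start,stop,step Grid specification on \[0, 1\].
#' @param fn A [rank_function()].
#' @return A data frame with columns `cof` and `rank`.
#' @export
tabulate_rank_function <- function(start = 0, stop = 1, step = 0.01,
                                   fn = rank_function()) {
  stopifnot(start >= 0, stop <= 1, step > 0, start < stop)
  g <- seq(start, stop, by = step)
  data.frame(cof = g, rank = fn$transform(g))
}
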