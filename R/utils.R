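#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, the convention used for
#' all displayed metric values in this package. Base R's `round()` rounds
#' half to even, which turns a macro recall of 0.92945 into 0.9294 instead
#' of the conventional 0.9295.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 4).
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(0.92945, 4)  # 0.9295
#' @export
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  # nudge by an ulp-scale epsilon so values stored just under x.xxxx5 still
  # round up; standard trick for decimal half-up on binary doubles
  sign(x) * trunc(abs(x) * p + 0.5 + 1e-9) / p
}

# Clamp values to [lo, hi] when within tol of the interval; error otherwise.
clamp_unit <- function(x, tol = 1e-9, what = "confidence") {
  bad <- x < -tol | x > 1 + tol
  if (any(bad, na.rm = TRUE)) {
    i <- which(bad)[1]
    stop(sprintf("%s value %.6g at position %d is outside [0,1] by more than %g",
                 what, x[i], i, tol), call. = FALSE)
  }
  pmin(pmax(x, 0), 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
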