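# Sample-size-weighted summary statistics.

#' Sample-size-weighted mean
#'
#' Weighted arithmetic mean `sum(w*v)/sum(w)`, used to pool study-level
#' concentration values with weights equal to the study sample sizes.
#'
#' @param values Numeric vector.
#' @param weights Non-negative numeric weights of the same length; `NULL`
#'   means equal weights.
#' @return The weighted mean.
#' @export
#' @examples
#' weighted_mean(c(2, 4), c(3, 1))  # 2.5
weighted_mean <- function(values, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(values))
  check_weights(values, weights)
  stats::weighted.mean(values, weights)
}

check_weights <- function(values, weights) {
  if (length(values) != length(weights)) {
    stop("'values' and 'weights' lengths differ", call. = FALSE)
  }
  if (length(values) == 0) stop("no values supplied", call. = FALSE)
  if (any(!is.finite(values)) || any(!is.finite(weights))) {
    stop("non-finite values or weights", call. = FALSE)
  }
  if (any(weights < 0)) stop("negative weights", call. = FALSE)
  if (sum(weights) <= 0) stop("weights sum to zero", call. = FALSE)
  invisible(TRUE)
}

#' Sample-size-weighted percentile
#'
#' Weighted quantile under the midpoint (Hazen) convention. Tied values are
#' pooled (their weights summed); the pooled values, sorted, are placed at the
#' midpoints of their normalised cumulative weight intervals,
#' `p_i = (c_{i-1} + c_i)/2`, and the quantile is the linear interpolation of
#' the values at `q`, clamped to the smallest/largest value outside
#' `[p_1, p_n]`. The convention is invariant to rescaling all weights by a
#' constant, and for integer weights it agrees exactly with applying the same
#' convention to the weight-expanded multiset. With unit weights and distinct
#' values it reduces to the ordinary midpoint-convention sample percentile
#' (`quantile(..., type = 5)`).
#'
#' `method = "step"` gives the left-continuous inverse of the weighted step
#' CDF (the smallest value whose cumulative weight share reaches `q`) as a
#' non-interpolating alternative.
#'
#' @param values Numeric vector.
#' @param weights Non-negative weights, same length; `NULL` = equal weights.
#' @param q Quantile fraction(s), strictly inside (0, 1).
#' @param method `"hazen"` (default, interpolating) or `"step"`.
#' @return Numeric vector of quantiles, one per element of `q`.
#' @export
#' @examples
#' weighted_percentile(c(1, 2, 3, 4), q = 0.5)            # 2.5
#' weighted_percentile(c(10, 20, 30), c(1, 1, 8), 0.75)   # 30
weighted_percentile <- function(values, weights = NULL, q,
                                method = c("hazen", "step")) {
  method <- match.arg(method)
  if (is.null(weights)) weights <- rep(1, length(values))
  check_weights(values, weights)
  if (any(q <= 0 | q >= 1)) {
    stop("'q' must lie strictly within (0, 1)", call. = FALSE)
  }
  # sort, then pool tied values so the convention is expansion-consistent
  o <- order(values)
  v0 <- values[o]; w0 <- weights[o]
  grp <- cumsum(c(TRUE, v0[-1] != v0[-length(v0)]))
  v <- v0[!duplicated(grp)]
  w <- as.numeric(tapply(w0, grp, sum))
  keep <- w > 0
  v <- v[keep]; w <- w[keep]
  if (length(v) == 1) return(rep(v, length(q)))  # degenerate: single value

  cw <- cumsum(w) / sum(w)
  if (method == "step") {
    idx <- findInterval(q, cw, left.open = TRUE) + 1
    return(v[idx])
  }
  p <- (c(0, cw[-length(cw)]) + cw) / 2
  stats::approx(p, v, xout = q, rule = 2, ties = "ordered")$y
}
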