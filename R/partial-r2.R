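#' Partial R-squared from a Wald statistic
#'
#' Variance in the outcome uniquely attributable to one model term,
#' computed from the term's t (or z) statistic and its residual degrees of
#' freedom as `t^2 / (t^2 + df)`. For ordinary least squares this equals
#' the squared partial correlation between outcome and term given the
#' remaining terms. Tree-block summaries apply it to the median statistic
#' over the block.
#'
#' @param t Wald statistic(s).
#' @param df residual degrees of freedom (`>= 1`).
#' @return numeric in `[0, 1)`, same length as `t`.
#' @export
partial_r2 <- function(t, df) {
  if (any(!is.finite(df)) || any(df < 1))
    stop("df must be finite and >= 1")
  t^2 / (t^2 + df)
}
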