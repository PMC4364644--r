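#' Convert beta-values to M-values
#'
#' The M-value is the log2 ratio of methylated to unmethylated signal,
#' i.e. the logit2 of the beta-value: `M = log2(beta / (1 - beta))`.
#' M-values are the modelling scale used throughout this package because
#' beta-values are heteroscedastic near 0 and 1 while M-values are
#' approximately homoscedastic.
#'
#' Beta-values are clamped into `[eps, 1 - eps]` before the logit so that
#' fully (un)methylated probes map to finite M-values; interior values are
#' not materially moved.
#'
#' @param beta Numeric vector or matrix of beta-values in `[0, 1]`.
#'   `NA` cells pass through as `NA`.
#' @param eps Clamp width at the boundaries. Default `1e-6`.
#' @return Object of the same shape with M-values.
#' @seealso [m_to_beta()] for the inverse.
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8))
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  bad <- !is.na(beta) & (beta < 0 | beta > 1)
  if (any(bad)) {
    abort(sprintf(
      "`beta` must lie in [0, 1]; %d value(s) outside (first offender: %g).",
      sum(bad), beta[bad][1]
    ))
  }
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Convert M-values to beta-values
#'
#' Inverse of [beta_to_m()] away from the clamp region:
#' `beta = 2^M / (1 + 2^M)`.
#'
#' @param m Numeric vector or matrix of finite M-values.
#' @return Object of the same shape with beta-values in `(0, 1)`.
#' @examples
#' m_to_beta(c(-2, 0, 2))
#' @export
m_to_beta <- function(m) {
  # 2^m / (1 + 2^m) rewritten to avoid overflow at large |m|
  1 / (1 + 2^(-m))
}
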