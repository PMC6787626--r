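#' Fit a log-normal distribution from a (median, q25, q75) summary
#'
#' Clinical marker tables typically report a median with the 25th-75th
#' percentile band. A log-normal stand-in with
#' \eqn{\mu = \ln(median)} and \eqn{\sigma = \ln(q75/q25) / (2 z_{0.75})}
#' (with \eqn{z_{0.75}} the standard-normal 75th-percentile deviate)
#' reproduces the median exactly and the quartile ratio `q75/q25` exactly;
#' the individual quartiles are matched only when the printed triple is
#' log-symmetric. A degenerate triple (q25 = median = q75) yields a point
#' mass (`sdlog = 0`).
#'
#' @param median,q25,q75 Positive marker quantiles with
#'   `q25 <= median <= q75`. Vectorised.
#' @return A data frame with columns `meanlog` and `sdlog` (one row per
#'   input triple); for scalar input this is a single row.
#' @examples
#' fit_lognormal_from_quantiles(100, 100 * exp(-0.6744898 * 0.3),
#'                              100 * exp(0.6744898 * 0.3))
#' @export
fit_lognormal_from_quantiles <- function(median, q25, q75) {
  n <- max(length(median), length(q25), length(q75))
  median <- rep_len(as.numeric(median), n)
  q25 <- rep_len(as.numeric(q25), n)
  q75 <- rep_len(as.numeric(q75), n)
  if (anyNA(c(median, q25, q75)) || any(q25 <= 0 | median <= 0 | q75 <= 0)) {
    stop("quantiles must be positive and non-missing", call. = FALSE)
  }
  if (any(q25 > median | median > q75)) {
    stop("quantiles must satisfy q25 <= median <= q75", call. = FALSE)
  }
  z75 <- stats::qnorm(0.75)
  data.frame(meanlog = log(median), sdlog = log(q75 / q25) / (2 * z75))
}
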