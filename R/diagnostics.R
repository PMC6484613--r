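#' Effective sample size of a chain
#'
#' Initial-positive-sequence estimator: the autocorrelation sum is truncated
#' at the first nonpositive pair of consecutive-lag sums.
#'
#' @param x numeric vector of draws.
#' @return estimated effective sample size (capped at `length(x)`).
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4 || stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 2, 500), plot = FALSE,
                    demean = TRUE)$acf[-1]
  m <- floor(length(rho) / 2)
  s <- 0
  for (k in seq_len(m)) {
    pair <- rho[2 * k - 1] + rho[2 * k]
    if (pair <= 0) break
    s <- s + pair
  }
  min(n, n / (1 + 2 * s))
}

#' Split-\eqn{\hat R} of a single chain
#'
#' Splits the chain into two halves and computes the potential scale
#' reduction factor between them; values near 1 indicate the two halves
#' explore the same distribution.
#'
#' @param x numeric vector of draws.
#' @return split-\eqn{\hat R} (NA for degenerate chains shorter than 8).
#' @export
split_rhat <- function(x) {
  n <- length(x)
  if (n < 8) return(NA_real_)
  h <- floor(n / 2)
  a <- x[1:h]; b <- x[(n - h + 1):n]
  W <- (stats::var(a) + stats::var(b)) / 2
  if (W == 0) return(1)
  mu <- c(mean(a), mean(b))
  B <- h * stats::var(mu)
  sqrt(((h - 1) / h * W + B / h) / W)
}
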