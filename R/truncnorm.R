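#' Truncated normal density and random draws on an interval
#'
#' Density and random generation for the normal distribution restricted to
#' `(lower, upper)`. Daily backspace rates live on (0, 1), so the mixture
#' components used throughout the package are normal densities renormalized to
#' that interval; these helpers are the single implementation used by the
#' likelihood, the Gibbs sampler and the cohort generator.
#'
#' Sampling uses the inverse-CDF method: `u ~ U(F(lower), F(upper))` mapped
#' through `qnorm`. For the parameter ranges that occur here (means well inside
#' the interval, sd an order of magnitude smaller than the interval width) this
#' is numerically safe and exact in distribution.
#'
#' @param x vector of quantiles.
#' @param n number of draws.
#' @param mean,sd mean and standard deviation of the parent normal; `sd > 0`.
#' @param lower,upper truncation bounds, `lower < upper`.
#' @param log logical; return log density.
#' @return `dtruncnorm` a density vector (zero outside the interval);
#'   `rtruncnorm` a vector of `n` draws strictly inside the interval.
#' @examples
#' dtruncnorm(0.14, mean = 0.112, sd = 0.048)
#' summary(rtruncnorm(1000, mean = 0.18, sd = 0.048))
#' @export
dtruncnorm <- function(x, mean = 0, sd = 1, lower = 0, upper = 1, log = FALSE) {
  stopifnot(sd > 0, lower < upper)
  lz <- log_trunc_mass(mean, sd, lower, upper)
  ld <- stats::dnorm(x, mean, sd, log = TRUE) - lz
  ld[x <= lower | x >= upper] <- -Inf
  if (log) ld else exp(ld)
}

#' @rdname dtruncnorm
#' @export
rtruncnorm <- function(n, mean = 0, sd = 1, lower = 0, upper = 1) {
  stopifnot(all(sd > 0), lower < upper)
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  x <- stats::qnorm(u, mean, sd)
  # guard against u hitting an endpoint in floating point
  pmin(pmax(x, lower + .Machine$double.eps), upper - .Machine$double.eps)
}

# log of the truncation normalizer Phi((upper-mean)/sd) - Phi((lower-mean)/sd),
# vectorized over mean and sd. Computed in log space (reflecting into the
# lower tail) so means far outside the interval stay finite instead of
# underflowing to log(0).
log_trunc_mass <- function(mean, sd, lower = 0, upper = 1) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  flip <- (a + b) > 0
  aa <- ifelse(flip, -b, a)
  bb <- ifelse(flip, -a, b)
  la <- stats::pnorm(aa, log.p = TRUE)
  lb <- stats::pnorm(bb, log.p = TRUE)
  d <- -expm1(pmin(la - lb, 0))
  ifelse(d > 0, lb + log(d), -Inf)
}
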