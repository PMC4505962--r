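#' Truncated-Gaussian prior over the sensitivity L
#'
#' The prior used for every fixed-L model: Normal(`mu`, `sd`) truncated
#' to `[lo, hi]`, with the defaults mean 0, s.d. 5, truncation at plus
#' or minus 10. Also serves as the hyperprior on the population mean in
#' the hierarchical model.
#'
#' @param mu,sd location and scale of the untruncated Gaussian; `sd > 0`.
#' @param lo,hi truncation bounds, `lo < hi`.
#' @return an object of class `"trunc_norm_prior"` with a `$logdens`
#'   function (normalized log density, `-Inf` outside the support).
#' @export
trunc_norm_prior <- function(mu = 0, sd = 5, lo = -10, hi = 10) {
  stopifnot(sd > 0, lo < hi)
  lognorm <- log(stats::pnorm(hi, mu, sd) - stats::pnorm(lo, mu, sd))
  obj <- list(mu = mu, sd = sd, lo = lo, hi = hi)
  obj$logdens <- function(x) {
    ifelse(x >= lo & x <= hi,
           stats::dnorm(x, mu, sd, log = TRUE) - lognorm,
           -Inf)
  }
  structure(obj, class = "trunc_norm_prior")
}

#' Lognormal prior on the population standard deviation of L
#'
#' Hyperprior for the hierarchical individual-differences model:
#' `log(sigma) ~ Normal(mu, sd)`, defaults mu 0, s.d. 1.
#'
#' @param mu,sd parameters of the log-scale Gaussian; `sd > 0`.
#' @return an object of class `"lognorm_prior"` with a `$logdens`
#'   function over sigma.
#' @export
lognorm_prior <- function(mu = 0, sd = 1) {
  stopifnot(sd > 0)
  obj <- list(mu = mu, sd = sd)
  obj$logdens <- function(x) {
    ifelse(x > 0, stats::dlnorm(x, mu, sd, log = TRUE), -Inf)
  }
  structure(obj, class = "lognorm_prior")
}
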