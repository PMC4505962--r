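#' MCMC configuration for the L samplers
#'
#' Defaults follow the reference analysis: five chains started at
#' L = -8, -2, 0, 2, 8, Gaussian proposal steps of standard deviation
#' 0.1 retuned every 200 steps (burn-in only), and 6,000 pooled
#' post-burn-in samples across the chains. Each chain runs for
#' `n_samples / n_chains` kept iterations preceded by a burn-in of half
#' that many (i.e. the first third of the chain is discarded).
#'
#' @param n_chains number of chains.
#' @param starts start value per chain (length `n_chains`).
#' @param proposal_sd initial Gaussian proposal scale.
#' @param tune_interval steps between proposal-scale adaptations during
#'   burn-in; adaptation is frozen afterwards so the kept portion of the
#'   chain is Markovian.
#' @param n_samples total pooled post-burn-in samples across chains.
#' @param rhat_threshold Gelman-Rubin split-R-hat below which the chains
#'   count as converged.
#' @param max_extensions times the chain length is doubled when R-hat
#'   stays above the threshold, before the fit is flagged.
#' @param seed optional integer seed applied before sampling.
#' @return an object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_chains = 5L, starts = c(-8, -2, 0, 2, 8),
                        proposal_sd = 0.1, tune_interval = 200L,
                        n_samples = 6000L, rhat_threshold = 1.1,
                        max_extensions = 4L, seed = NULL) {
  n_chains <- as.integer(n_chains)
  if (length(starts) != n_chains) stop("length(starts) must equal n_chains")
  stopifnot(proposal_sd > 0, tune_interval >= 1, n_samples >= n_chains,
            rhat_threshold > 1)
  structure(list(n_chains = n_chains, starts = starts,
                 proposal_sd = proposal_sd,
                 tune_interval = as.integer(tune_interval),
                 n_samples = as.integer(n_samples),
                 rhat_threshold = rhat_threshold,
                 max_extensions = as.integer(max_extensions), seed = seed),
            class = "mcmc_config")
}

# staged proposal-scale adaptation by acceptance band (standard
# adaptive-MH practice; applied during burn-in only)
tune_scale <- function(scale, acc) {
  if (acc < 0.001) scale * 0.1
  else if (acc < 0.05) scale * 0.5
  else if (acc < 0.2) scale * 0.9
  else if (acc > 0.95) scale * 10
  else if (acc > 0.75) scale * 2
  else if (acc > 0.5) scale * 1.1
  else scale
}

#' Random-walk Metropolis-Hastings chain
#'
#' Gaussian-proposal random walk on a (possibly multivariate) target.
#' The proposal scale is adapted every `tune_interval` steps during the
#' burn-in phase (the first half of `n_keep` iterations, i.e. a third
#' of the total run) and frozen afterwards.
#'
#' @param logdensity function mapping a parameter vector to a log
#'   density; must be finite at `start`.
#' @param start numeric start vector.
#' @param config an [mcmc_config()]; `proposal_sd` and `tune_interval`
#'   are used here.
#' @param n_keep number of post-burn-in iterations to return (defaults
#'   to `config$n_samples / config$n_chains`).
#' @return list with `samples` (matrix `n_keep` x d), `logdens` (vector
#'   of log densities of the kept samples), `accept_rate`, and the final
#'   `proposal_sd`.
#' @export
mh_chain <- function(logdensity, start, config = mcmc_config(),
                     n_keep = NULL) {
  start <- as.numeric(start)
  d <- length(start)
  lp <- logdensity(start)
  if (!is.finite(lp)) stop("logdensity must be finite at the start value")
  n_keep <- as.integer(n_keep %||% ceiling(config$n_samples / config$n_chains))
  n_burn <- as.integer(ceiling(n_keep / 2))
  total <- n_burn + n_keep
  scale <- config$proposal_sd
  cur <- start
  samples <- matrix(NA_real_, n_keep, d)
  lps <- numeric(n_keep)
  acc_window <- 0L
  acc_total <- 0L
  for (it in seq_len(total)) {
    prop <- cur + stats::rnorm(d, 0, scale)
    lpp <- logdensity(prop)
    if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
      cur <- prop
      lp <- lpp
      acc_window <- acc_window + 1L
      if (it > n_burn) acc_total <- acc_total + 1L
    }
    if (it <= n_burn && it %% config$tune_interval == 0L) {
      scale <- tune_scale(scale, acc_window / config$tune_interval)
      acc_window <- 0L
    }
    if (it > n_burn) {
      samples[it - n_burn, ] <- cur
      lps[it - n_burn] <- lp
    }
  }
  list(samples = samples, logdens = lps,
       accept_rate = acc_total / n_keep, proposal_sd = scale)
}

#' Gelman-Rubin potential scale reduction factor (split-chain)
#'
#' Each chain is split in half and the classic between/within variance
#' ratio is computed over the resulting half-chains:
#' \eqn{\hat R = \sqrt{((n-1)/n \, W + B/n) / W}}.
#'
#' @param chains list of at least two numeric vectors of equal length
#'   (>= 4 so each half has >= 2 draws).
#' @return the R-hat scalar (>= 1 up to numerical tolerance; values
#'   near 1 indicate convergence).
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L) {
    stop("need at least 2 chains")
  }
  len <- unique(lengths(chains))
  if (length(len) != 1L || len < 4L) {
    stop("chains must have equal length >= 4")
  }
  n <- len %/% 2L
  halves <- unlist(lapply(chains, function(ch) {
    list(ch[seq_len(n)], ch[n + seq_len(n)])
  }), recursive = FALSE)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B_over_n <- stats::var(means)
  if (W == 0) {
    return(if (B_over_n == 0) 1 else Inf)
  }
  sqrt(((n - 1) / n * W + B_over_n) / W)
}
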