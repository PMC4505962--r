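#' Marginal log-likelihood of one participant under the population model
#'
#' Integrates the two-selection likelihood against the population
#' Gaussian: \eqn{\log \int P(\mathrm{choices} \mid L)\,
#' N(L; \mu, \sigma)\, dL}, by adaptive quadrature over
#' `[mu - 8 sigma, mu + 8 sigma]` intersected with the numeric window
#' `[-30, 30]`. Used to score the hierarchical model with the
#' participant effects integrated out.
#'
#' @param record one-row choice table.
#' @param graph stimulus graph.
#' @param mu,sigma population mean and standard deviation (`sigma >= 0`;
#'   `sigma = 0` degenerates to the likelihood at `mu`).
#' @return scalar log marginal likelihood.
#' @export
marginal_loglik <- function(record, graph, mu, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  ll <- function(L) as.numeric(choice_loglik(record, graph, L))
  if (sigma < 1e-8) return(ll(mu))
  lo <- max(mu - 8 * sigma, L_WINDOW[1L])
  hi <- min(mu + 8 * sigma, L_WINDOW[2L])
  c0 <- ll(pmin(pmax(mu, lo), hi))
  f <- function(L) exp(ll(L) - c0) * stats::dnorm(L, mu, sigma)
  val <- stats::integrate(f, lo, hi, rel.tol = 1e-8)$value
  c0 + log(val)
}

# fast vectorized cohort marginal log-likelihood via Gauss-Legendre
# quadrature on [mu - 8 sigma, mu + 8 sigma] (used inside optimization;
# agreement with marginal_loglik is pinned by tests)
cohort_marginal_loglik <- function(records, graph, mu, sigma, n_nodes = 64L) {
  if (sigma < 1e-8) {
    return(sum(choice_loglik(records, graph, mu)))
  }
  gl <- gauss_legendre(n_nodes)
  lo <- max(mu - 8 * sigma, L_WINDOW[1L])
  hi <- min(mu + 8 * sigma, L_WINDOW[2L])
  nodes <- (hi - lo) / 2 * gl$nodes + (hi + lo) / 2
  logw <- log((hi - lo) / 2 * gl$weights) +
    stats::dnorm(nodes, mu, sigma, log = TRUE)
  ll <- choice_loglik(records, graph, nodes)        # P x K
  sum(row_logsumexp(ll + rep(logw, each = nrow(ll))))
}

#' Corrected Akaike Information Criterion
#'
#' \eqn{\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n - k - 1)}: the AIC with
#' the finite-sample correction term.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters.
#' @param n_obs number of observations; must exceed `k + 1`.
#' @return the AICc value.
#' @examples
#' aicc(0, 2, 5)  # 4 + 12/2 = 10
#' @export
aicc <- function(loglik, k, n_obs) {
  stopifnot(k >= 1)
  if (n_obs <= k + 1) stop("n_obs must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
}

#' Compare the shared-L and individual-differences models by AICc
#'
#' The shared model has one free parameter (the common L), scored at
#' its maximum likelihood over the prior support. The hierarchical
#' model has two (mu, sigma), scored at the maximum of the summed
#' marginal likelihoods with the participant-level effects integrated
#' out (so they are not counted as free parameters). The observation
#' count is two selections per participant. A positive `delta`
#' (aicc_shared - aicc_hier) favors the model with individual
#' differences.
#'
#' @param records choice table.
#' @param graph stimulus graph.
#' @param lo,hi search bounds for L and mu.
#' @param sigma_max upper search bound for the population sd.
#' @return a `model_comparison`: `aicc_shared`, `aicc_hier`, `delta`,
#'   `n_obs`, `k_shared`, `k_hier`, plus the fitted `L_hat`, `mu_hat`,
#'   `sigma_hat` and maximized log-likelihoods.
#' @export
compare_models <- function(records, graph, lo = -10, hi = 10,
                           sigma_max = 20) {
  P <- nrow(records)
  if (P < 2L) stop("model comparison needs >= 2 participants")
  n_obs <- 2L * P
  shared_ll <- shared_loglik_fn(records, graph)
  opt_s <- stats::optimize(function(L) shared_ll(L), c(lo, hi),
                           maximum = TRUE, tol = 1e-8)
  obj <- function(par) {
    -cohort_marginal_loglik(records, graph, par[1L], exp(par[2L]))
  }
  opt_h <- stats::optim(c(opt_s$maximum, 0), obj, method = "L-BFGS-B",
                        lower = c(lo, log(1e-3)),
                        upper = c(hi, log(sigma_max)))
  ll_s <- opt_s$objective
  ll_h <- -opt_h$value
  a_s <- aicc(ll_s, 1L, n_obs)
  a_h <- aicc(ll_h, 2L, n_obs)
  structure(list(aicc_shared = a_s, aicc_hier = a_h, delta = a_s - a_h,
                 n_obs = n_obs, k_shared = 1L, k_hier = 2L,
                 L_hat = opt_s$maximum, mu_hat = opt_h$par[1L],
                 sigma_hat = exp(opt_h$par[2L]),
                 loglik_shared = ll_s, loglik_hier = ll_h),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("<model_comparison> AICc shared %.1f (L = %.2f) vs ",
           "hierarchical %.1f (mu = %.2f, sigma = %.2f); delta = %.1f\n"),
    x$aicc_shared, x$L_hat, x$aicc_hier, x$mu_hat, x$sigma_hat, x$delta))
  invisible(x)
}
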