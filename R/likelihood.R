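# ---- choice-table validation and likelihood machinery ----
#
# A choice table is a data.frame with columns participant_id,
# first_choice, second_choice; node ids are 0-based arrival order
# (igraph vertex i is node id i - 1). The likelihood of one
# participant's two selections is the softmax probability of the first
# choice over all nodes times the softmax probability of the second
# over all nodes minus the first, both evaluated at the true stimulus
# degrees.

validate_records <- function(records, graph) {
  stopifnot(is.data.frame(records))
  need <- c("participant_id", "first_choice", "second_choice")
  if (!all(need %in% names(records))) {
    stop("choice table must have columns ", paste(need, collapse = ", "))
  }
  n <- igraph::gorder(graph)
  f <- as.integer(records$first_choice)
  s <- as.integer(records$second_choice)
  if (any(f < 0L | f >= n) || any(s < 0L | s >= n)) {
    stop("choice node ids must lie in 0..", n - 1L)
  }
  if (any(f == s)) stop("first_choice and second_choice must differ")
  list(f = f + 1L, s = s + 1L, id = records$participant_id)
}

#' Log-likelihood matrix of choice records over a vector of L values
#'
#' For each record and each L, the log probability of the observed
#' selection(s) under the softmax choice rule at the stimulus degrees:
#' the first choice is over all nodes, the second over all nodes with
#' the first choice excluded.
#'
#' @param records choice table (`participant_id`, `first_choice`,
#'   `second_choice`; 0-based node ids).
#' @param graph the stimulus graph (`igraph`).
#' @param L numeric vector of sensitivity values.
#' @param choice which terms enter: `"both"` (default), `"first"`, or
#'   `"second"`.
#' @return numeric matrix, `nrow(records)` by `length(L)`.
#' @export
choice_loglik <- function(records, graph, L, choice = c("both", "first", "second")) {
  choice <- match.arg(choice)
  v <- validate_records(records, graph)
  logd <- log(igraph::degree(graph))
  if (any(!is.finite(logd))) stop("stimulus graph has isolated nodes (degree 0)")
  K <- length(L)
  P <- length(v$f)

  # log Z(L) over all nodes, one value per L
  lZ <- col_logsumexp(outer(logd, L))
  # log Z(L) with each possible first choice excluded: only the
  # distinct excluded nodes matter
  uf <- sort(unique(v$f))
  lZx <- matrix(0, length(uf), K)
  for (j in seq_along(uf)) {
    lZx[j, ] <- col_logsumexp(outer(logd[-uf[j]], L))
  }
  rowx <- match(v$f, uf)

  t1 <- outer(logd[v$f], L) - rep(lZ, each = P)
  t2 <- outer(logd[v$s], L) - lZx[rowx, , drop = FALSE]
  out <- switch(choice, both = t1 + t2, first = t1, second = t2)
  dimnames(out) <- NULL
  out
}

#' Log-likelihood of one participant's two selections
#'
#' @param record a one-row choice table (or a row index into a larger
#'   one is not needed; subset first).
#' @param graph the stimulus graph.
#' @param L scalar sensitivity.
#' @return `log P(first | all nodes, L) + log P(second | rest, L)`.
#' @export
participant_loglik <- function(record, graph, L) {
  if (nrow(record) != 1L) stop("record must be a single row")
  as.numeric(choice_loglik(record, graph, L, choice = "both"))
}

#' Log posterior density of L for one participant
#'
#' Sum of [participant_loglik()] and the truncated-Gaussian log prior;
#' `-Inf` outside the prior support.
#'
#' @inheritParams participant_loglik
#' @param prior a [trunc_norm_prior()].
#' @export
log_posterior <- function(record, graph, L, prior = trunc_norm_prior()) {
  lp <- prior$logdens(L)
  if (!is.finite(lp)) return(-Inf)
  lp + participant_loglik(record, graph, L)
}

# pooled sufficient-statistic log-likelihood: returns a fast function
# of a vector of L values, summing the chosen terms over all records
shared_loglik_fn <- function(records, graph, choice = "both") {
  v <- validate_records(records, graph)
  logd <- log(igraph::degree(graph))
  P <- length(v$f)
  S <- switch(choice,
              both = sum(logd[v$f]) + sum(logd[v$s]),
              first = sum(logd[v$f]),
              second = sum(logd[v$s]))
  uf <- sort(unique(v$f))
  nf <- tabulate(match(v$f, uf), nbins = length(uf))
  use_first <- choice %in% c("both", "first")
  use_second <- choice %in% c("both", "second")
  logd_excl <- lapply(uf, function(u) logd[-u])
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  function(L) {
    if (length(L) == 1L) {
      # scalar fast path for the MH inner loop
      out <- L * S
      if (use_first) out <- out - P * lse(L * logd)
      if (use_second) {
        for (j in seq_along(uf)) {
          out <- out - nf[j] * lse(L * logd_excl[[j]])
        }
      }
      return(out)
    }
    out <- L * S
    if (use_first) out <- out - P * col_logsumexp(outer(logd, L))
    if (use_second) {
      lZx <- vapply(uf, function(u) col_logsumexp(outer(logd[-u], L)),
                    numeric(length(L)))
      out <- out - as.numeric(lZx %*% nf)
    }
    out
  }
}
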