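#' Softmax choice probabilities over node degrees
#'
#' Computes the probability of befriending each candidate node when the
#' decision maker values popularity: the probability of choosing node
#' \eqn{a} is \eqn{d_a^L / \sum_b d_b^L}, where \eqn{d} is degree and
#' \eqn{L} the sensitivity exponent. \eqn{L = 0} is value-blind (uniform
#' choice), \eqn{L = 1} is linear probability matching (classic
#' preferential attachment), \eqn{L < 0} is antipreferential
#' ("demophobic") behavior.
#'
#' Computation is carried out in log space with max-subtraction, so
#' \eqn{|L|} up to 10 with degrees up to 1e4 neither overflows nor
#' collapses to a degenerate distribution unless it is mathematically
#' degenerate.
#'
#' @param degrees integer vector of node degrees; all must be >= 1
#'   (powers of 0 are undefined for negative L).
#' @param L real sensitivity exponent.
#' @param excluded integer vector of 1-based positions into `degrees`
#'   that are unavailable (e.g. already-chosen nodes). Must leave at
#'   least one candidate.
#' @return numeric vector of the same length as `degrees`, summing to 1;
#'   excluded positions carry probability 0.
#' @examples
#' choice_probabilities(c(1, 2, 1), L = 1)            # 0.25 0.50 0.25
#' choice_probabilities(c(7, 2, 9, 4), L = 0)          # uniform
#' choice_probabilities(c(1, 2, 1), L = 1, excluded = 2)
#' @export
choice_probabilities <- function(degrees, L, excluded = integer()) {
  if (length(degrees) == 0L) {
    stop("empty alternative set: no degrees supplied")
  }
  if (any(!is.finite(degrees)) || any(degrees < 1)) {
    stop("all degrees must be finite and >= 1")
  }
  stopifnot(is.numeric(L), length(L) == 1L, is.finite(L))
  n <- length(degrees)
  excluded <- as.integer(excluded)
  if (length(excluded) > 0L) {
    if (any(excluded < 1L | excluded > n)) {
      stop("excluded positions out of range")
    }
    if (length(unique(excluded)) >= n) {
      stop("excluded set must leave at least one alternative")
    }
  }
  lw <- L * log(degrees)
  if (length(excluded)) lw[excluded] <- -Inf
  p <- exp(lw - max(lw))
  p / sum(p)
}

#' Sample a newcomer's m attachments without replacement
#'
#' Draws `m` distinct nodes sequentially: each draw uses
#' [choice_probabilities()] with all previously drawn nodes excluded.
#' Degrees are frozen at the newcomer's arrival — they are not updated
#' between the m draws, so the whole set is a successive sample from
#' the single distribution defined at arrival.
#'
#' @param x an `igraph` graph or a vector of degrees (all >= 1).
#' @param L sensitivity exponent.
#' @param m number of attachments; must not exceed the number of nodes.
#' @return integer vector of `m` distinct 1-based node positions.
#' @export
sample_attachments <- function(x, L, m) {
  degrees <- if (inherits(x, "igraph")) igraph::degree(x) else x
  degrees <- as.numeric(degrees)
  n <- length(degrees)
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  if (m > n) stop("m exceeds the number of candidate nodes")
  if (any(degrees < 1)) stop("all degrees must be >= 1")
  if (m == n) return(seq_len(n))
  lw <- L * log(degrees)
  w <- exp(lw - max(lw))
  # sequential weighted draws without replacement == successive sampling
  sample.int(n, size = m, replace = FALSE, prob = w)
}
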