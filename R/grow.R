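#' Attachment policy: how newcomers weigh popularity
#'
#' A policy is either a single shared sensitivity `L` (`kind = "fixed"`)
#' or a population with Gaussian individual differences
#' (`kind = "gaussian"`): each newcomer draws its own L from
#' Normal(`L_mean`, `L_sd`) truncated to `[lo, hi]` before choosing its
#' attachments.
#'
#' @param kind `"fixed"` or `"gaussian"`.
#' @param L sensitivity exponent (fixed policy).
#' @param L_mean,L_sd population mean and standard deviation of L
#'   (gaussian policy); `L_sd >= 0`.
#' @param lo,hi truncation bounds for per-newcomer L draws; kept at the
#'   support of the inference prior so generator and estimator agree.
#' @return an object of class `"attachment_policy"`.
#' @export
attachment_policy <- function(kind = c("fixed", "gaussian"), L = 1,
                              L_mean = 0, L_sd = 1, lo = -10, hi = 10) {
  kind <- match.arg(kind)
  stopifnot(lo < hi)
  if (kind == "fixed") {
    if (L < lo || L > hi) stop("fixed L must lie within [lo, hi]")
  } else {
    if (L_sd < 0) stop("L_sd must be >= 0")
  }
  structure(list(kind = kind, L = L, L_mean = L_mean, L_sd = L_sd,
                 lo = lo, hi = hi),
            class = "attachment_policy")
}

#' @export
print.attachment_policy <- function(x, ...) {
  if (x$kind == "fixed") {
    cat(sprintf("<attachment_policy> fixed L = %g\n", x$L))
  } else {
    cat(sprintf("<attachment_policy> gaussian L ~ N(%g, %g^2) on [%g, %g]\n",
                x$L_mean, x$L_sd, x$lo, x$hi))
  }
  invisible(x)
}

# inverse-CDF truncated-normal draws (single uniform stream)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Grow a network by popularity-guided choice
#'
#' Starts from a complete graph on `m + 1` seed nodes and adds newcomers
#' one at a time; each newcomer links to `m` existing nodes sampled
#' without replacement from the softmax distribution over current
#' degrees (see [choice_probabilities()]). With a fixed policy every
#' newcomer shares one L; with a gaussian policy each newcomer draws its
#' own L, which is recorded in the vertex attribute `L`.
#'
#' Node ids are 0-based arrival order: ids `0..m` are the seed clique,
#' id `m + k` is the k-th newcomer. (igraph vertex `i` is node id
#' `i - 1`.) The result always has
#' `m(m+1)/2 + (n_final - m - 1) m` edges and minimum degree >= m.
#'
#' @param n_final total number of nodes, at least `m + 1`.
#' @param m edges added per newcomer.
#' @param policy an [attachment_policy()]; a bare number is shorthand
#'   for a fixed policy with that L.
#' @param seed optional integer; when supplied the RNG is seeded so the
#'   same call reproduces the identical edge set.
#' @return an `igraph` graph with graph attributes `m` and `policy_kind`
#'   and a numeric vertex attribute `L` (NA for seed nodes).
#' @examples
#' g <- grow_network(25, m = 3, policy = 1, seed = 1)
#' igraph::gsize(g)  # 69
#' @export
grow_network <- function(n_final, m, policy = 1, seed = NULL) {
  if (is.numeric(policy)) policy <- attachment_policy("fixed", L = policy)
  stopifnot(inherits(policy, "attachment_policy"))
  m <- as.integer(m)
  n_final <- as.integer(n_final)
  if (m < 1L) stop("m must be a positive integer")
  if (n_final < m + 1L) stop("n_final must be at least m + 1")
  if (!is.null(seed)) set.seed(seed)

  n_new <- n_final - m - 1L
  Ls <- if (policy$kind == "fixed") {
    rep(policy$L, max(n_new, 0L))
  } else {
    pmin(pmax(rtruncnorm(n_new, policy$L_mean, policy$L_sd,
                         policy$lo, policy$hi), policy$lo), policy$hi)
  }

  n_edges <- (m * (m + 1L)) %/% 2L + n_new * m
  from <- integer(n_edges)
  to <- integer(n_edges)
  seed_pairs <- utils::combn(m + 1L, 2L)
  k <- ncol(seed_pairs)
  from[seq_len(k)] <- seed_pairs[1L, ]
  to[seq_len(k)] <- seed_pairs[2L, ]

  deg <- numeric(n_final)
  deg[seq_len(m + 1L)] <- m
  logd <- numeric(n_final)
  logd[seq_len(m + 1L)] <- log(m)

  e <- k
  n_cur <- m + 1L
  for (i in seq_len(n_new)) {
    L <- Ls[i]
    lw <- L * logd[seq_len(n_cur)]
    targets <- if (m == n_cur) {
      seq_len(n_cur)
    } else {
      sample.int(n_cur, size = m, replace = FALSE,
                 prob = exp(lw - max(lw)))
    }
    newcomer <- n_cur + 1L
    idx <- e + seq_len(m)
    from[idx] <- targets
    to[idx] <- newcomer
    e <- e + m
    deg[targets] <- deg[targets] + 1
    logd[targets] <- log(deg[targets])
    deg[newcomer] <- m
    logd[newcomer] <- log(m)
    n_cur <- newcomer
  }

  g <- igraph::make_empty_graph(n = n_final, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::V(g)$L <- c(rep(NA_real_, m + 1L), Ls)
  g$m <- m
  g$policy_kind <- policy$kind
  g
}
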