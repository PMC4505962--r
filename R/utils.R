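`%||%` <- function(a, b) if (is.null(a)) b else a

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise log-sum-exp of a matrix, stable, no apply() overhead
row_logsumexp <- function(M) {
  mx <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  out <- mx + log(rowSums(exp(M - mx)))
  out[!is.finite(mx)] <- mx[!is.finite(mx)]
  out
}

col_logsumexp <- function(M) row_logsumexp(t(M))

# Gauss-Legendre nodes/weights on [-1, 1] via Golub-Welsch
gauss_legendre <- function(k) {
  i <- seq_len(k - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = rev(e$values), weights = rev(2 * e$vectors[1L, ]^2))
}
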