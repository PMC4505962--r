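# shared fixtures and independent oracles, all built in code

graph_from_pairs <- function(n, pairs) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::add_edges(g, pairs)
}

path3 <- function() graph_from_pairs(3, c(1, 2, 2, 3))          # degrees 1,2,1
k4 <- function() igraph::make_full_graph(4)
k4_minus_edge <- function() graph_from_pairs(4, c(1, 2, 1, 3, 1, 4, 2, 3, 2, 4))
star_graph <- function(n) graph_from_pairs(n, rbind(1, 2:n))

make_record <- function(f, s, id = 1L) {
  data.frame(participant_id = id, first_choice = f, second_choice = s)
}

quick_mcmc <- function(seed = 1, n_samples = 3000) {
  mcmc_config(n_samples = n_samples, tune_interval = 100,
              proposal_sd = 1, seed = seed)
}

# independent oracle: exhaustive enumeration of the sequential-draw
# tree for sampling m nodes without replacement with weights deg^L
enum_attachment_sets <- function(degrees, L, m) {
  n <- length(degrees)
  w <- degrees^L
  acc <- new.env()
  rec <- function(chosen, p) {
    if (length(chosen) == m) {
      key <- paste(sort(chosen), collapse = "-")
      acc[[key]] <- (acc[[key]] %||% 0) + p
      return(invisible())
    }
    avail <- setdiff(seq_len(n), chosen)
    pw <- w[avail] / sum(w[avail])
    for (i in seq_along(avail)) rec(c(chosen, avail[i]), p * pw[i])
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  rec(integer(), 1)
  as.list(acc)
}

# naive direct-arithmetic two-choice log-likelihood (oracle for the
# log-space implementation; valid away from overflow regimes)
naive_loglik <- function(record, graph, L) {
  d <- igraph::degree(graph)
  f <- record$first_choice + 1L
  s <- record$second_choice + 1L
  log(d[f]^L / sum(d^L)) + log(d[s]^L / sum(d[-f]^L))
}

# binned total-variation distance between pooled samples and a grid
# posterior
tv_samples_vs_grid <- function(samples, grid, bin_width = 1) {
  br <- seq(-10, 10, by = bin_width)
  hs <- hist(samples, breaks = br, plot = FALSE)$counts / length(samples)
  pg <- tapply(grid$posterior, cut(grid$L, br, include.lowest = TRUE), sum)
  pg[is.na(pg)] <- 0
  0.5 * sum(abs(hs - pg))
}
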