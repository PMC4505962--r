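test_that("degree tables match closed-form fixtures", {
  dd <- degree_distribution_table(k4())
  expect_equal(dd$degree, 3L)
  expect_equal(dd$count, 4L)
  expect_equal(dd$ccdf, 1)
  dd5 <- degree_distribution_table(star_graph(5))
  expect_equal(dd5$degree, c(1L, 4L))
  expect_equal(dd5$count, c(4L, 1L))
  expect_equal(dd5$ccdf, c(1, 0.2))
  expect_error(degree_distribution_table(igraph::make_empty_graph(0)),
               "empty")
  # ccdf is non-increasing and counts sum to the node count
  g <- grow_network(500, 3, policy = 1, seed = 61)
  dd <- degree_distribution_table(g)
  expect_true(all(diff(dd$ccdf) <= 0))
  expect_equal(sum(dd$count), 500L)
})

test_that("characteristic path length matches closed forms", {
  expect_equal(characteristic_path_length(k4())$value, 1)
  expect_equal(characteristic_path_length(path3())$value, 4 / 3)
  n <- 10
  star_formula <- (2 * choose(n - 1, 2) + (n - 1)) / choose(n, 2)
  expect_equal(characteristic_path_length(star_graph(n))$value, star_formula)
  disc <- igraph::make_empty_graph(4, directed = FALSE)
  expect_error(characteristic_path_length(disc), "disconnected")
})

test_that("sampled path length tracks the exact value", {
  g <- grow_network(2000, 3, policy = 1, seed = 62)
  exact <- characteristic_path_length(g)
  expect_true(exact$exact)
  sampled <- characteristic_path_length(g, max_exact_n = 100,
                                        n_sources = 500, seed = 1)
  expect_false(sampled$exact)
  expect_lt(abs(sampled$value - exact$value) / exact$value, 0.02)
})

test_that("mean local clustering matches hand enumeration", {
  expect_equal(mean_local_clustering(k4()), 1)
  expect_equal(mean_local_clustering(star_graph(8)), 0)
  expect_equal(mean_local_clustering(path3()), 0)
  # K4 minus one edge: the two degree-2 nodes see their 1 neighbour
  # pair linked, the two degree-3 nodes see 2 of 3
  expect_equal(mean_local_clustering(k4_minus_edge()),
               (2 * 1 + 2 * (2 / 3)) / 4)
})

test_that("network_metrics aggregates and serializes", {
  g <- grow_network(800, 3, policy = 1, seed = 63)
  m <- network_metrics(g, seed = 1)
  expect_s3_class(m, "network_metrics")
  expect_true(m$path_length_exact)
  expect_gte(m$mean_clustering, 0)
  expect_lte(m$mean_clustering, 1)
  expect_lt(m$ccdf_slope, 0)
  f <- withr::local_tempfile(fileext = ".json")
  netmatch:::metrics_to_json(m, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$n_nodes, 800L)
  expect_equal(j$mean_clustering, m$mean_clustering)
})
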