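test_that("pearson correlation matches hand computation", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, c(2, 1, 4, 3)), 0.6)
  expect_error(pearson_r(x, rep(1, 4)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(1:4, 1:5), "equal length")
})

test_that("percentile bootstrap matches the CLT on a large sample", {
  set.seed(71)
  x <- rnorm(1e4)
  ci <- bootstrap_ci(mean, x, n_boot = 4000)
  half_width <- (ci[2] - ci[1]) / 2
  expect_lt(abs(half_width - 1.96 * stats::sd(x) / 100) /
              (1.96 * stats::sd(x) / 100), 0.1)
  expect_lt(ci[1], mean(x))
  expect_gt(ci[2], mean(x))
})

test_that("bootstrap handles degenerate data and nested levels", {
  ci <- bootstrap_ci(mean, rep(5, 10), n_boot = 1000)
  expect_equal(ci, c(5, 5))
  set.seed(72)
  x <- rnorm(50); y <- 0.5 * x + rnorm(50)
  widths <- vapply(c(0.8, 0.95, 0.99), function(lev) {
    set.seed(99)  # same resample stream, nested percentiles
    ci <- bootstrap_ci(function(a, b) stats::cor(a, b), x, y,
                       n_boot = 2000, level = lev)
    ci[2] - ci[1]
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
  expect_error(bootstrap_ci(mean, rnorm(10), n_boot = 10), "1000")
})

test_that("correlation results stay inside [-1, 1] and are reproducible", {
  set.seed(73)
  for (i in 1:5) {
    x <- rnorm(20); y <- rnorm(20)
    set.seed(100 + i)
    res <- netmatch:::correlation_result(x, y, n_boot = 1000)
    expect_gte(res$ci_low, -1)
    expect_lte(res$ci_high, 1)
    expect_true(res$ci_low <= res$r && res$r <= res$ci_high)
    set.seed(100 + i)
    res2 <- netmatch:::correlation_result(x, y, n_boot = 1000)
    expect_identical(res, res2)
  }
})

test_that("first/second consistency approaches 1 without estimation noise", {
  co <- generate_cohort(cohort_config(n_participants = 300, cohort_seed = 74))
  fits <- data.frame(L_map_first = co$true_L, L_map_second = co$true_L)
  res <- first_second_consistency(fits, n_boot = 1000)
  expect_equal(res$r, 1)
  # permuted pairing at large n has near-zero correlation
  set.seed(75)
  fits2 <- data.frame(L_map_first = co$true_L,
                      L_map_second = sample(co$true_L))
  expect_lt(abs(first_second_consistency(fits2, n_boot = 1000)$r), 0.15)
})

test_that("trait correlations pick out a planted signal", {
  co <- generate_cohort(cohort_config(n_participants = 400, cohort_seed = 76))
  fake <- co$personality
  fake$openness <- co$true_L            # planted perfect correlate
  res <- trait_correlations(co$true_L, fake, n_boot = 1000)
  expect_named(res, c("openness", "conscientiousness", "extraversion",
                      "agreeableness", "neuroticism"))
  expect_equal(res$openness$r, 1)
  # traits generated independently of L stay near zero
  expect_lt(abs(res$conscientiousness$r), 0.15)
  expect_lt(abs(res$agreeableness$r), 0.15)
  expect_error(trait_correlations(co$true_L[1:10], fake), "match")
})
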