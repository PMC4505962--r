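test_that("choice probabilities reproduce the softmax rule", {
  expect_equal(choice_probabilities(c(1, 2, 1), L = 1), c(0.25, 0.5, 0.25))
  expect_equal(choice_probabilities(c(7, 2, 9, 4), L = 0), rep(0.25, 4))
  expect_equal(choice_probabilities(c(1, 3), L = 2), c(0.1, 0.9))
  expect_equal(choice_probabilities(c(1, 2, 1), L = 1, excluded = 2),
               c(0.5, 0, 0.5))
})

test_that("choice probabilities reject invalid input", {
  expect_error(choice_probabilities(numeric(), 1), "empty")
  expect_error(choice_probabilities(c(0, 2), 1), ">= 1")
  expect_error(choice_probabilities(c(1, 2), 1, excluded = c(1, 2)),
               "at least one")
  expect_error(choice_probabilities(c(1, 2), 1, excluded = 5), "range")
})

test_that("normalization, scale invariance and monotonicity hold", {
  set.seed(42)
  for (rep in 1:20) {
    deg <- sample(1:50, 8, replace = TRUE)
    L <- runif(1, -10, 10)
    p <- choice_probabilities(deg, L)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    # Eq is homogeneous of degree 0 in the values
    expect_equal(choice_probabilities(deg * 7L, L), p, tolerance = 1e-12)
  }
  deg <- c(2, 5, 9, 30)
  p_pos <- choice_probabilities(deg, 1.5)
  p_neg <- choice_probabilities(deg, -1.5)
  expect_true(all(diff(p_pos) > 0))
  expect_true(all(diff(p_neg) < 0))
  expect_equal(choice_probabilities(deg, 0), rep(0.25, 4))
})

test_that("extreme L with large degrees stays numerically stable", {
  deg <- c(1, 10, 100, 10000)
  for (L in c(-10, 10)) {
    p <- choice_probabilities(deg, L)
    expect_true(all(is.finite(p)))
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
  # degenerate only where mathematically degenerate
  expect_gt(choice_probabilities(deg, 10)[4], 1 - 1e-9)
  expect_gt(choice_probabilities(deg, -10)[1], 1 - 1e-9)
})

test_that("attachment sampling matches the sequential-draw-tree oracle", {
  # K4, L = 0: every 3-subset equally likely
  set.seed(7)
  draws <- replicate(20000, paste(sort(sample_attachments(k4(), 0, 3)),
                                  collapse = "-"))
  counts <- table(draws)
  expect_length(counts, 4L)
  expect_gt(stats::chisq.test(counts, p = rep(0.25, 4))$p.value, 1e-4)

  # irregular degrees, L = 1, m = 2 against exhaustive enumeration
  deg <- c(1, 2, 3, 2, 4)
  oracle <- enum_attachment_sets(deg, L = 1, m = 2)
  set.seed(11)
  draws <- replicate(30000, paste(sort(sample_attachments(deg, 1, 2)),
                                  collapse = "-"))
  counts <- table(draws)
  expect_setequal(names(counts), names(oracle))
  p_exp <- unlist(oracle)[names(counts)]
  expect_gt(stats::chisq.test(counts, p = p_exp)$p.value, 1e-4)
})

test_that("attachment sampling honors limits and errors", {
  # hub with degree 50 vs 50 leaves at L = 10: hub essentially certain
  p_hub <- choice_probabilities(c(50, rep(1, 50)), 10)[1]
  expect_equal(p_hub, 50^10 / (50^10 + 50), tolerance = 1e-12)
  set.seed(3)
  hub_draws <- replicate(500, sample_attachments(c(50, rep(1, 50)), 10, 1))
  expect_true(all(hub_draws == 1L))
  # exhaustion and errors
  expect_equal(sort(sample_attachments(c(2, 2, 2), 1, 3)), 1:3)
  expect_error(sample_attachments(c(2, 2), 1, 3), "exceeds")
  expect_error(sample_attachments(c(0, 2), 1, 1), ">= 1")
})
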