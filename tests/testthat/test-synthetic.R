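test_that("the stimulus is a reproducible 25-node scale-free network", {
  hubs <- 0L
  for (seed in 1:20) {
    g <- make_stimulus(seed)
    expect_equal(igraph::gorder(g), 25L)
    expect_equal(igraph::gsize(g), 69L)
    expect_true(igraph::is_connected(g))
    expect_gte(min(igraph::degree(g)), 3)
    if (max(igraph::degree(g)) > 3) hubs <- hubs + 1L
  }
  expect_gte(hubs, 19L)                      # hub formation in >= 95% of seeds
  expect_identical(igraph::as_edgelist(make_stimulus(5)),
                   igraph::as_edgelist(make_stimulus(5)))
})

test_that("value-blind cohorts choose uniformly", {
  co <- generate_cohort(cohort_config(n_participants = 10000, L_mean = 0,
                                      L_sd = 0, cohort_seed = 81))
  counts <- tabulate(co$records$first_choice + 1L, nbins = 25)
  expect_gt(stats::chisq.test(counts, p = rep(1 / 25, 25))$p.value, 1e-3)
  expect_true(all(co$records$first_choice != co$records$second_choice))
  expect_true(all(co$records$first_choice %in% 0:24))
  expect_true(all(co$records$second_choice %in% 0:24))
})

test_that("the planted extraversion correlation is realized", {
  co <- generate_cohort(cohort_config(cohort_seed = 82))
  expect_equal(nrow(co$personality), 600L)
  r_ext <- stats::cor(co$true_L, co$personality$extraversion)
  expect_lt(abs(r_ext - 0.17), 0.12)
  for (tr in c("openness", "conscientiousness", "agreeableness",
               "neuroticism")) {
    expect_lt(abs(stats::cor(co$true_L, co$personality[[tr]])), 0.12)
  }
  rng <- range(as.matrix(co$personality[, -1]))
  expect_gte(rng[1], 1)
  expect_lte(rng[2], 5)
})

test_that("popular-node choice share rises with the population mean L", {
  g <- make_stimulus(1)
  top <- which.max(igraph::degree(g)) - 1L
  share <- vapply(c(-2, 0, 2), function(mu) {
    co <- generate_cohort(cohort_config(n_participants = 2000, L_mean = mu,
                                        L_sd = 0, cohort_seed = 83))
    mean(co$records$first_choice == top)
  }, numeric(1))
  expect_true(all(diff(share) > 0))
})

test_that("cohorts are seed-deterministic and round-trip through disk", {
  cfg <- cohort_config(n_participants = 40, cohort_seed = 84)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$true_L, c2$true_L)
  expect_identical(c1$personality, c2$personality)

  dir <- withr::local_tempdir()
  write_cohort(c1, dir)
  back <- read_cohort(dir)
  expect_equal(back$records, c1$records)
  expect_equal(back$personality, c1$personality, tolerance = 1e-12)
  expect_equal(back$true_L, c1$true_L, tolerance = 1e-12)
  expect_equal(igraph::gsize(back$stimulus), 69L)

  # pipeline-facing mode: no ground truth file
  unlink(file.path(dir, "truth.csv"))
  expect_length(read_cohort(dir)$true_L, 0L)
  unlink(file.path(dir, "personality.csv"))
  expect_error(read_cohort(dir), "personality.csv")
})
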