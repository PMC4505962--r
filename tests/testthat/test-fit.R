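test_that("participant fit lands on the dense-grid MAP", {
  co <- generate_cohort(cohort_config(n_participants = 10, cohort_seed = 31))
  g <- co$stimulus
  for (i in c(1L, 4L)) {
    rec <- co$records[i, ]
    fit <- fit_participant(rec, g, config = quick_mcmc(seed = i, n_samples = 6000))
    grid <- posterior_grid(rec, g)
    expect_lt(abs(fit$L_map - grid$L[which.max(grid$posterior)]), 0.05)
    expect_true(fit$converged)
    expect_lte(fit$rhat, 1.1)
    expect_length(fit$samples, 6000L)
    expect_true(fit$L_map >= -10 && fit$L_map <= 10)
  }
})

test_that("swapped equal-degree choices give the identical posterior", {
  g <- make_stimulus(1)
  deg <- igraph::degree(g)
  d0 <- as.integer(names(which.max(table(deg))))      # a repeated degree
  pair <- which(deg == d0)[1:2] - 1L                  # two same-degree ids
  g1 <- posterior_grid(make_record(pair[1], pair[2]), g)
  g2 <- posterior_grid(make_record(pair[2], pair[1]), g)
  expect_equal(g1$posterior, g2$posterior, tolerance = 1e-12)
})

test_that("separate per-choice fits behave and the fast cohort path agrees", {
  co <- generate_cohort(cohort_config(n_participants = 25, cohort_seed = 32))
  rec <- co$records[2, ]
  fits <- fit_choices_separately(rec, co$stimulus,
                                 config = quick_mcmc(seed = 5, n_samples = 4000))
  gridf <- posterior_grid(rec, co$stimulus, choice = "first")
  grids <- posterior_grid(rec, co$stimulus, choice = "second")
  expect_lt(abs(fits$first$L_map - gridf$L[which.max(gridf$posterior)]), 0.1)
  expect_lt(abs(fits$second$L_map - grids$L[which.max(grids$posterior)]), 0.1)
  maps <- fit_choices_cohort(co$records, co$stimulus)
  expect_equal(nrow(maps), 25L)
  i <- which(maps$participant_id == rec$participant_id)
  expect_lt(abs(maps$L_map_first[i] - fits$first$L_map), 0.1)
  expect_lt(abs(maps$L_map_second[i] - fits$second$L_map), 0.1)
})

test_that("shared fit reduces to the participant fit on one record", {
  co <- generate_cohort(cohort_config(n_participants = 5, cohort_seed = 33))
  rec <- co$records[1, ]
  cfg <- quick_mcmc(seed = 17, n_samples = 3000)
  f1 <- fit_participant(rec, co$stimulus, config = cfg)
  f2 <- fit_shared(rec, co$stimulus, config = cfg)
  expect_equal(f2$samples, f1$samples, tolerance = 1e-12)
  expect_equal(f2$L_map, f1$L_map, tolerance = 1e-8)
  expect_error(fit_shared(co$records[0, ], co$stimulus), "no choice records")
})

test_that("shared fit recovers a homogeneous cohort's L", {
  co <- generate_cohort(cohort_config(n_participants = 200, L_mean = 1,
                                      L_sd = 0, cohort_seed = 34))
  fit <- fit_shared(co$records, co$stimulus,
                    config = quick_mcmc(seed = 6, n_samples = 6000))
  grid_fn <- netmatch:::shared_loglik_fn(co$records, co$stimulus)
  pr <- trunc_norm_prior()
  Lg <- seq(-10, 10, length.out = 401)
  gmax <- Lg[which.max(grid_fn(Lg) + pr$logdens(Lg))]
  expect_lt(abs(fit$L_map - gmax), 0.05)
  # posterior from 400 observations is tight around the true value
  expect_lt(abs(fit$L_map - 1), 0.4)
  expect_lt(stats::sd(fit$samples), 0.5)
})
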