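test_that("two-selection log-likelihood matches hand and naive oracles", {
  g <- path3()                                  # degrees 1, 2, 1
  rec <- make_record(1, 0)                      # center then an endpoint
  expect_equal(participant_loglik(rec, g, 1), log(0.25))
  # L = 0: uniform over n, then n - 1
  g25 <- make_stimulus(1)
  rec25 <- make_record(3, 17)
  expect_equal(participant_loglik(rec25, g25, 0), log(1 / 25) + log(1 / 24))
  # direct-arithmetic oracle on the stimulus at several L
  set.seed(21)
  for (i in 1:10) {
    f <- sample(0:24, 1)
    s <- sample(setdiff(0:24, f), 1)
    L <- runif(1, -3, 3)
    r <- make_record(f, s)
    expect_equal(participant_loglik(r, g25, L), naive_loglik(r, g25, L),
                 tolerance = 1e-12)
  }
})

test_that("choice tables are validated against the graph", {
  g <- path3()
  expect_error(choice_loglik(make_record(0, 5), g, 1), "0\\.\\.2")
  expect_error(choice_loglik(make_record(1, 1), g, 1), "differ")
  expect_error(choice_loglik(data.frame(a = 1), g, 1), "columns")
})

test_that("choice_loglik matrix agrees with scalar calls and splits terms", {
  g <- make_stimulus(2)
  recs <- data.frame(participant_id = 1:3, first_choice = c(0, 5, 20),
                     second_choice = c(9, 0, 3))
  Ls <- c(-2, 0, 1.3)
  M <- choice_loglik(recs, g, Ls)
  expect_equal(dim(M), c(3L, 3L))
  for (i in 1:3) for (k in 1:3) {
    expect_equal(M[i, k], participant_loglik(recs[i, ], g, Ls[k]),
                 tolerance = 1e-12)
  }
  expect_equal(choice_loglik(recs, g, Ls, "first") +
                 choice_loglik(recs, g, Ls, "second"), M, tolerance = 1e-12)
})

test_that("pooled shared-likelihood closure equals the per-record sum", {
  g <- make_stimulus(3)
  co <- generate_cohort(cohort_config(n_participants = 40, cohort_seed = 9))
  fn <- netmatch:::shared_loglik_fn(co$records, g)
  Ls <- c(-4, -0.5, 0, 2.2)
  direct <- colSums(choice_loglik(co$records, g, Ls))
  expect_equal(fn(Ls), direct, tolerance = 1e-10)
  # scalar fast path agrees with the vector path
  for (L in Ls) expect_equal(fn(L), direct[match(L, Ls)], tolerance = 1e-10)
})

test_that("log posterior combines likelihood and truncated prior", {
  g <- path3()
  rec <- make_record(1, 0)
  pr <- trunc_norm_prior()
  expect_identical(log_posterior(rec, g, 11, pr), -Inf)
  expect_identical(log_posterior(rec, g, -10.5, pr), -Inf)
  L <- 1.7
  expect_equal(log_posterior(rec, g, L, pr),
               participant_loglik(rec, g, L) + pr$logdens(L))
  # for two low-degree picks both terms fall away from 0, so the
  # posterior must too
  expect_gt(log_posterior(make_record(0, 2), g, 0.1, pr),
            log_posterior(make_record(0, 2), g, 3, pr))
})
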