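test_that("the Gaussian KL closed form matches known values and the quadrature oracle", {
  g <- gaussian1d(0.3, 0.7)
  expect_equal(gaussian_kl(g, g), 0)
  expect_equal(gaussian_kl(gaussian1d(0, 1), gaussian1d(1, 1)), 0.5)
  expect_equal(gaussian_kl(gaussian1d(0.2, 0.5), gaussian1d(0.7, 0.3)),
               quadrature_kl(list(mean = 0.2, sd = 0.5), list(mean = 0.7, sd = 0.3)),
               tolerance = 1e-6)
  expect_error(gaussian_kl(g, list(mean = 1, sd = 1)), "gaussian1d")
})

test_that("the KL divergence is non-negative, zero only at equality, and asymmetric", {
  withr::with_seed(61, {
    for (i in 1:25) {
      a <- gaussian1d(rnorm(1), runif(1, 0.1, 3))
      b <- gaussian1d(rnorm(1), runif(1, 0.1, 3))
      kl <- gaussian_kl(a, b)
      expect_gte(kl, 0)
      if (a$sd != b$sd) expect_false(isTRUE(all.equal(kl, gaussian_kl(b, a))))
      expect_equal(gaussian_kl(a, b), quadrature_kl(a, b), tolerance = 1e-6)
    }
  })
  # surprising data (narrow prior far from the MLE) is penalized much more
  # than a merely wide prior
  mle <- gaussian1d(2, 0.5)
  narrow_off <- gaussian1d(0, 0.2)
  wide <- gaussian1d(0, 5)
  expect_gt(gaussian_kl(mle, narrow_off), gaussian_kl(mle, wide))
})

test_that("average ranks use the minimum rule and ignore row scaling", {
  m <- rbind(a = c(3, 1, 2), b = c(2, 2, 2), c = c(1, 5, 5))
  r <- average_rank(m)
  expect_equal(unname(r), c(mean(c(3, 1, 1)), mean(c(1, 1, 2)), mean(c(2, 1, 2))))
  expect_equal(unname(average_rank(rbind(c(7, 7, 7)))), c(1, 1, 1))
  withr::with_seed(62, {
    x <- matrix(runif(40), 8, 5)
    expect_equal(average_rank(exp(3 * x)), average_rank(x))
    expect_equal(average_rank(x^3), average_rank(x))
  })
  expect_error(average_rank(matrix(numeric(0), 0, 0)), "empty")
  expect_error(average_rank(rbind(c(1, NA))), "finite")
})

test_that("kl_table scores marginals per variable and excludes the intercept", {
  d <- toy_dataset(seed = 63, n = 200, p = 3, family = "logistic")
  mle <- fit_mle(d, "logistic")
  doc <- prior_document("toy", list(
    uniform_prior_set(d, 0.2, 0.5, label = "A", weight = 0.5),
    uniform_prior_set(d, 0, 2, label = "B", weight = 0.5)))
  rep <- kl_table(mle, doc)
  expect_identical(rep$variables, d$variable_names)
  expect_false("(Intercept)" %in% rep$variables)
  for (v in d$variable_names) {
    expect_equal(rep$kl[v, "A"],
                 gaussian_kl(marginal(mle, v), gaussian1d(0.2, 0.5)))
  }
  expect_equal(unname(rep$column_means), unname(colMeans(rep$kl)))

  single <- prior_document("toy", list(uniform_prior_set(d, 0, 1, label = "only")))
  expect_equal(unname(kl_table(mle, single)$avg_ranks), 1)

  bad <- prior_document("toy", list(prior_set("A", "weak", 1,
                                              list(x1 = prior_entry(0, 1)))))
  expect_error(kl_table(mle, bad), "missing")
})

test_that("KL report writers emit a footer table and a full-precision JSON twin", {
  rep <- kl_report_from_matrix(shipped_kl_matrix("heart"))
  stem <- file.path(withr::local_tempdir(), "kl")
  write_kl_report(rep, stem)
  tab <- readLines(paste0(stem, ".tsv"))
  expect_length(tab, 1 + 6 + 2)
  expect_match(tab[8], "^Avg KL Div\\.")
  expect_match(tab[9], "^Avg Rank")
  twin <- jsonlite::fromJSON(paste0(stem, ".json"))
  expect_equal(unname(unlist(twin$column_means)), unname(rep$column_means),
               tolerance = 1e-12)
  back <- read_kl_matrix(paste0(stem, ".tsv"))
  expect_equal(back[1:6, ], round_display(rep$kl), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("prior predictive draws match analytic moments in limiting cases", {
  d <- toy_dataset(seed = 64, n = 30, p = 2, family = "linear")
  X1 <- cbind(1, d$X)

  point <- uniform_prior_set(d, 0.4, 1e-12)
  sims <- prior_predictive_sample(d, "linear", point,
                                  intercept_prior = gaussian1d(1, 1e-12),
                                  n_draws = 4000, seed = 1, sigma2 = 0.25)
  mu <- drop(X1 %*% c(1, 0.4, 0.4))
  expect_equal(unname(colMeans(sims)), mu, tolerance = 0.05)
  expect_equal(mean(apply(sims, 2, var)), 0.25, tolerance = 0.02)

  diag_prior <- uniform_prior_set(d, 0.2, 0.6)
  sims2 <- prior_predictive_sample(d, "linear", diag_prior,
                                   intercept_prior = gaussian1d(0, 0.5),
                                   n_draws = 4000, seed = 2, sigma2 = 1)
  S <- diag(c(0.5, 0.6, 0.6)^2)
  expected_var <- rowSums((X1 %*% S) * X1) + 1
  expect_equal(apply(sims2, 2, var) / expected_var, rep(1, 30), tolerance = 0.12)

  db <- toy_dataset(seed = 65, n = 40, p = 2, family = "logistic")
  sims3 <- prior_predictive_sample(db, "logistic", uniform_prior_set(db, 0, 1),
                                   intercept_prior = gaussian1d(0, 1),
                                   n_draws = 4000, seed = 3)
  expect_equal(mean(sims3), 0.5, tolerance = 0.02)
})

test_that("prior predictive checks localize the observed data among simulations", {
  d <- toy_dataset(seed = 66, n = 50, p = 2, family = "linear")
  priors <- uniform_prior_set(d, 0.3, 0.5)
  sims <- prior_predictive_sample(d, "linear", priors, n_draws = 500, seed = 4,
                                  sigma2 = 1)
  expect_error(summarize_ppc(sims[1:50, ], d$y), "at least 100")

  # observed response drawn from the same prior predictive: no extreme tails
  ppc_self <- summarize_ppc(sims[-1, ], sims[1, ])
  expect_s3_class(ppc_self, "ppc_summary")
  expect_true(all(ppc_self$tail_prop >= 0 & ppc_self$tail_prop <= 0.5))

  far <- rep(1e6, 50)
  ppc_far <- summarize_ppc(sims, far)
  expect_true(all(ppc_far$tail_prop[ppc_far$statistic == "mean"] == 0))
})

test_that("self-calibrated checks rarely produce extreme tail proportions", {
  d <- toy_dataset(seed = 67, n = 40, p = 2, family = "linear")
  priors <- uniform_prior_set(d, 0.2, 0.4)
  ok <- 0L
  reps <- 40L
  for (r in seq_len(reps)) {
    sims <- prior_predictive_sample(d, "linear", priors, n_draws = 301,
                                    seed = 100 + r, sigma2 = 1)
    ppc <- summarize_ppc(sims[-1, ], sims[1, ])
    if (all(ppc$tail_prop >= 0.001)) ok <- ok + 1L
  }
  expect_gte(ok / reps, 0.95)
})
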