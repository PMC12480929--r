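test_that("flat priors recover the MLE, dominant priors recover the prior mean", {
  for (family in c("logistic", "linear")) {
    d <- toy_dataset(seed = 31, n = 150, p = 2, family = family)
    mle <- fit_mle(d, family)
    flat <- laplace_posterior(d, family, uniform_prior_set(d, 0, 1e6),
                              intercept_prior = gaussian1d(0, 1e6))
    expect_equal(unname(flat$mode), unname(mle$theta_hat), tolerance = 1e-4)

    tight <- laplace_posterior(d, family, uniform_prior_set(d, 0.3, 1e-6),
                               intercept_prior = gaussian1d(-0.1, 1e-6))
    expect_equal(unname(tight$mode), c(-0.1, 0.3, 0.3), tolerance = 1e-4)
  }
})

test_that("the linear-family posterior equals the conjugate closed form", {
  d <- toy_dataset(seed = 32, n = 90, p = 3, family = "linear")
  priors <- uniform_prior_set(d, 0.2, 0.7)
  lap <- laplace_posterior(d, "linear", priors)
  sigma2 <- fit_mle(d, "linear")$sigma2
  conj <- conjugate_linear_posterior(d, priors, sigma2 = sigma2)
  expect_equal(lap$mode, conj$mode, tolerance = 1e-8)
  expect_equal(lap$cov, conj$cov, tolerance = 1e-8)
  expect_identical(lap$method, "conjugate")
})

test_that("the conjugate closed form matches an independent numerical optimizer", {
  d <- toy_dataset(seed = 33, n = 60, p = 2, family = "linear")
  priors <- uniform_prior_set(d, 0.5, 0.6)
  sigma2 <- 1.3
  post <- conjugate_linear_posterior(d, priors,
                                     intercept_prior = gaussian1d(0, 2),
                                     sigma2 = sigma2)
  X1 <- cbind(1, d$X)
  m <- c(0, 0.5, 0.5); s <- c(2, 0.6, 0.6)
  negpost <- function(b) {
    sum((d$y - X1 %*% b)^2) / (2 * sigma2) + sum((b - m)^2 / (2 * s^2))
  }
  opt <- optim(c(0, 0, 0), negpost, method = "BFGS", hessian = TRUE,
               control = list(reltol = 1e-14))
  expect_equal(unname(post$mode), opt$par, tolerance = 1e-5)
  expect_equal(unname(post$cov), solve(opt$hessian), tolerance = 1e-4)
})

test_that("posterior precision is prior precision plus data precision", {
  d <- toy_dataset(seed = 34, n = 50, p = 3, family = "linear")
  priors <- uniform_prior_set(d, 0, 0.8)
  sigma2 <- 2.1
  post <- conjugate_linear_posterior(d, priors,
                                     intercept_prior = gaussian1d(0, 5),
                                     sigma2 = sigma2)
  X1 <- cbind(1, d$X)
  expected <- diag(1 / c(5, 0.8, 0.8, 0.8)^2) + crossprod(X1) / sigma2
  expect_equal(unname(solve(post$cov)), unname(expected), tolerance = 1e-8)
})

test_that("wide priors recover least squares; intercept-only matches the textbook", {
  d <- toy_dataset(seed = 35, n = 70, p = 2, family = "linear")
  wide <- conjugate_linear_posterior(d, uniform_prior_set(d, 0, 1e7),
                                     intercept_prior = gaussian1d(0, 1e7),
                                     sigma2 = 1)
  ols <- coef(lm(d$y ~ d$X))
  expect_equal(unname(wide$mode), unname(ols), tolerance = 1e-6)

  withr::with_seed(36, y <- rnorm(25, 1.4))
  d0 <- regression_dataset(matrix(numeric(0), nrow = 25, ncol = 0), y)
  empty <- prior_set("none", "custom", 1, list())
  p0 <- conjugate_linear_posterior(d0, empty,
                                   intercept_prior = gaussian1d(0, 1),
                                   sigma2 = 1)
  expect_equal(unname(p0$mode), mean(y) * 25 / 26, tolerance = 1e-12)
  expect_equal(unname(p0$cov[1, 1]), 1 / 26, tolerance = 1e-12)
})

test_that("posterior sds never exceed prior or MLE marginal sds (linear-Gaussian)", {
  for (seed in 41:45) {
    d <- toy_dataset(seed = seed, n = 80, p = 3, family = "linear")
    mle <- fit_mle(d, "linear")
    priors <- uniform_prior_set(d, 0.1, runif(1, 0.2, 2))
    post <- laplace_posterior(d, "linear", priors)
    for (v in d$variable_names) {
      psd <- marginal(post, v)$sd
      expect_lte(psd, priors$entries[[v]]$prior$sd + 1e-12)
      expect_lte(psd, marginal(mle, v)$sd + 1e-12)
    }
  }
})

test_that("the single-covariate posterior mode lies between prior mean and MLE", {
  withr::with_seed(51, {
    x <- rnorm(50); x <- x - mean(x)
    y <- 1.5 * x + rnorm(50)
  })
  d <- regression_dataset(matrix(x, dimnames = list(NULL, "x")), y)
  mle_slope <- fit_mle(d, "linear")$theta_hat["x"]
  for (prior_mean in c(-1, 0, 3)) {
    s <- prior_set("s", "custom", 1, list(x = prior_entry(prior_mean, 0.5)))
    mode <- laplace_posterior(d, "linear", s)$mode["x"]
    expect_gte(mode, min(prior_mean, mle_slope) - 1e-10)
    expect_lte(mode, max(prior_mean, mle_slope) + 1e-10)
  }
})

test_that("misaligned priors are rejected in fitting", {
  d <- toy_dataset(seed = 52, n = 40, p = 2, family = "linear")
  s <- prior_set("s", "custom", 1, list(x1 = prior_entry(0, 1)))
  expect_error(laplace_posterior(d, "linear", s), "missing variable")
})

test_that("credible intervals are central Gaussian intervals", {
  d <- toy_dataset(seed = 53, n = 100, p = 2, family = "linear")
  post <- laplace_posterior(d, "linear", uniform_prior_set(d, 0, 1))
  ci <- credible_interval(post, "x1", level = 0.9)
  g <- marginal(post, "x1")
  expect_equal(unname(ci), g$mean + c(-1, 1) * qnorm(0.95) * g$sd,
               tolerance = 1e-12)
})
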