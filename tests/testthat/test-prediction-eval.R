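test_that("classification metrics match their definitions and oracles", {
  y <- c(1, 0, 1, 1, 0)
  expect_equal(brier_score(y, y), 0)
  expect_equal(brier_score(rep(0.5, 5), y), 0.25)
  expect_error(brier_score(c(0.2, 1.4), c(0, 1)), "\\[0, 1\\]")
  expect_error(brier_score(0.5, c(0, 1)), "length")

  expect_equal(mean_neg_log_score(y, y), 0, tolerance = 1e-10)
  expect_equal(mean_neg_log_score(rep(0.5, 5), y), log(2))
  expect_lte(mean_neg_log_score(1 - y, y), -log(1e-15) + 1e-3)  # clipped, finite
  expect_equal(mean_neg_log_score(rep(2, 4), rep(2, 4), sd = 1),
               0.5 * log(2 * pi))

  withr::with_seed(71, {
    p <- runif(50); yy <- rbinom(50, 1, 0.5)
    expect_equal(brier_score(p, yy), mean((p - yy)^2), tolerance = 1e-12)
  })
})

test_that("AUC equals the brute-force pairwise probability with half ties", {
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(auc(1:4, rep(1, 4)), "both classes")

  withr::with_seed(72, {
    s <- sample(seq(0, 1, by = 0.05), 50, replace = TRUE)  # forces ties
    y <- rbinom(50, 1, 0.5)
  })
  pos <- s[y == 1]; neg <- s[y == 0]
  brute <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(auc(s, y), brute, tolerance = 1e-12)
  expect_equal(auc(qlogis(pmin(pmax(s, 1e-3), 1 - 1e-3)), y), auc(s, y),
               tolerance = 1e-12)  # invariant under increasing transforms
})

test_that("regression metrics match their formulas", {
  withr::with_seed(73, {
    pred <- rnorm(40); obs <- rnorm(40)
  })
  expect_equal(rmse(obs, obs), 0)
  expect_equal(mae(obs, obs), 0)
  expect_equal(rmse(obs + 1.3, obs), 1.3, tolerance = 1e-12)
  expect_equal(mae(obs - 2.5, obs), 2.5, tolerance = 1e-12)
  expect_equal(rmse(pred, obs), sqrt(mean((pred - obs)^2)), tolerance = 1e-12)
  expect_equal(mae(pred, obs), mean(abs(pred - obs)), tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("the corrected t-test matches a direct formula evaluation", {
  d <- c(0.01, 0.02, 0.00, 0.03, 0.01)
  res <- nb_corrected_ttest(d, n_train = 242, n_test = 61)
  K <- 5
  t_direct <- mean(d) / sqrt((1 / K + 61 / 242) * var(d))
  expect_equal(res$t, t_direct, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, 1 - pt(t_direct, 4), tolerance = 1e-10)
})

test_that("the correction deflates the naive paired statistic by the overlap factor", {
  withr::with_seed(74, d <- rnorm(5, 0.01, 0.02))
  K <- length(d)
  n_train <- 160; n_test <- 40
  corrected <- nb_corrected_ttest(d, n_train, n_test)$t
  naive <- mean(d) / sqrt(var(d) / K)
  expect_equal(abs(corrected) / abs(naive),
               sqrt((1 / K) / (1 / K + n_test / n_train)), tolerance = 1e-12)
  # the corrected one-sided p can never undercut the naive one
  expect_gte(nb_corrected_ttest(abs(d), n_train, n_test)$p,
             1 - pt(abs(mean(abs(d))) / sqrt(var(abs(d)) / K), K - 1))
})

test_that("degenerate fold differences are handled explicitly", {
  expect_warning(res <- nb_corrected_ttest(rep(0, 5), 80, 20), "zero")
  expect_equal(res$t, 0)
  expect_equal(res$p, 0.5)
  expect_error(nb_corrected_ttest(rep(0.01, 5), 80, 20), "degenerate")
  expect_error(nb_corrected_ttest(0.01, 80, 20), "at least 2")
})

test_that("BH adjustment matches the hand-coded step-up and is monotone", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # a fully tied input is a fixed point of the adjustment
  expect_equal(bh_adjust(rep(0.04, 4)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(75, {
    for (i in 1:10) {
      p <- runif(sample(3:25, 1))
      adj <- bh_adjust(p)
      expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
      expect_true(all(adj >= p - 1e-15))
      expect_true(all(adj <= 1))
      # order preservation: adjustment is monotone in the raw p-values
      expect_true(all(diff(adj[order(p)]) >= -1e-15))
    }
  })
})

test_that("cross-validation folds are deterministic, stratified and exhaustive", {
  d <- toy_dataset(seed = 81, n = 200, p = 2, family = "logistic")
  models <- list(Frequentist = cv_model_frequentist())
  cv1 <- kfold_cv(d, models, "logistic", K = 5, seed = 7)
  cv2 <- kfold_cv(d, models, "logistic", K = 5, seed = 7)
  expect_identical(cv1$fold, cv2$fold)
  expect_identical(cv1$scores, cv2$scores)
  expect_identical(sort(unique(cv1$fold)), 1:5)
  expect_equal(sum(cv1$n_test), 200)

  # per-fold class counts deviate from proportionality by at most one sample
  pos_per_fold <- tabulate(cv1$fold[d$y == 1], 5)
  expect_lte(diff(range(pos_per_fold)), 1)
  neg_per_fold <- tabulate(cv1$fold[d$y == 0], 5)
  expect_lte(diff(range(neg_per_fold)), 1)

  dl <- toy_dataset(seed = 82, n = 10, p = 1, family = "linear")
  loo <- kfold_cv(dl, models, "linear", K = 10, seed = 1)
  expect_equal(unname(loo$n_test), rep(1, 10))
  expect_error(kfold_cv(dl, models, "linear", K = 11, seed = 1), "exceed")
})

test_that("model comparison reports one corrected, adjusted test per model and metric", {
  d <- toy_dataset(seed = 83, n = 200, p = 3, family = "logistic")
  doc <- prior_document("toy", list(
    uniform_prior_set(d, 0.1, 0.8, label = "SetA", weight = 0.5),
    uniform_prior_set(d, 0, 2.5, label = "SetB", weight = 0.5)))
  models <- c(list(Frequentist = cv_model_frequentist()),
              cv_models_from_document(doc))
  cv <- kfold_cv(d, models, "logistic", K = 5, seed = 11)
  rep <- compare_models(cv, baseline = "Frequentist")
  expect_equal(nrow(rep), 2 * 3)
  expect_true(all(rep$p_adjusted >= rep$p - 1e-15))
  expect_true(all(rep$p_adjusted <= 1))
  expect_identical(attr(rep, "baseline"), "Frequentist")

  stem <- file.path(withr::local_tempdir(), "cmp")
  write_comparison_report(rep, stem)
  tab <- read.delim(paste0(stem, ".tsv"), check.names = FALSE)
  expect_equal(nrow(tab), 3)  # baseline + 2 models
  expect_identical(names(tab), c("Model", "brier", "mnls", "auc"))
  expect_match(tab[2, "brier"], "\\(p = ")
})

test_that("under a realistic cross-validation null the corrected test is conservative", {
  # two equally irrelevant extra covariates: neither model should "win"
  reject <- 0L
  reps <- 200L
  for (r in seq_len(reps)) {
    withr::with_seed(2000 + r, {
      X <- matrix(rnorm(100 * 3), 100, 3, dimnames = list(NULL, c("s", "a", "b")))
      y <- X[, "s"] + rnorm(100)
    })
    dA <- regression_dataset(X[, c("s", "a")], y)
    dB <- regression_dataset(X[, c("s", "b")], y)
    fold <- rep_len(1:5, 100)[withr::with_seed(3000 + r, sample.int(100))]
    diffs <- vapply(1:5, function(k) {
      tr <- fold != k
      fa <- fit_mle(regression_dataset(X[tr, c("s", "a")], y[tr]), "linear")
      fb <- fit_mle(regression_dataset(X[tr, c("s", "b")], y[tr]), "linear")
      pa <- drop(cbind(1, X[!tr, c("s", "a")]) %*% fa$theta_hat)
      pb <- drop(cbind(1, X[!tr, c("s", "b")]) %*% fb$theta_hat)
      rmse(pb, y[!tr]) - rmse(pa, y[!tr])
    }, numeric(1))
    p <- nb_corrected_ttest(diffs, n_train = 80, n_test = 20)$p
    if (p < 0.05) reject <- reject + 1L
  }
  expect_lte(reject / reps, 0.08)
})
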