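# Cross-validated predictive comparison of Bayesian models under different
# prior sets against the frequentist fit: shared folds, proper scoring
# metrics, Nadeau-Bengio corrected t-tests, Benjamini-Hochberg adjustment.

#' Brier score
#'
#' Mean squared difference between predicted probabilities and 0/1 outcomes;
#' lower is better.
#'
#' @param probabilities predicted probabilities in `[0, 1]`.
#' @param outcomes 0/1 outcomes of the same length.
#' @return score in `[0, 1]`.
#' @export
brier_score <- function(probabilities, outcomes) {
  if (length(probabilities) != length(outcomes)) {
    pe_stop("brier_score: length mismatch")
  }
  if (any(probabilities < 0 | probabilities > 1)) {
    pe_stop("brier_score: probabilities must lie in [0, 1]")
  }
  mean((probabilities - outcomes)^2)
}

PROB_CLIP <- 1e-15

#' Mean negative log score
#'
#' Classification: mean of `-log` predictive probability of the realized
#' class, with probabilities clipped to `[1e-15, 1 - 1e-15]`. Regression:
#' mean of `-log` Gaussian predictive density of the realized outcome, with
#' predictive mean `predictions` and predictive standard deviation `sd`
#' (recycled if scalar). Lower is better.
#'
#' @param predictions predicted probabilities (classification) or predictive
#'   means (regression).
#' @param outcomes realized outcomes.
#' @param sd predictive standard deviations for regression; `NULL` selects
#'   the classification path.
#' @return the mean negative log score.
#' @export
mean_neg_log_score <- function(predictions, outcomes, sd = NULL) {
  if (length(predictions) != length(outcomes)) {
    pe_stop("mean_neg_log_score: length mismatch")
  }
  if (is.null(sd)) {
    if (any(predictions < 0 | predictions > 1)) {
      pe_stop("mean_neg_log_score: probabilities must lie in [0, 1]")
    }
    if (!all(outcomes %in% c(0, 1))) {
      pe_stop("mean_neg_log_score: classification outcomes must be 0/1")
    }
    p <- pmin(pmax(predictions, PROB_CLIP), 1 - PROB_CLIP)
    -mean(outcomes * log(p) + (1 - outcomes) * log(1 - p))
  } else {
    if (any(sd <= 0)) pe_stop("mean_neg_log_score: predictive sd must be positive")
    -mean(stats::dnorm(outcomes, mean = predictions, sd = sd, log = TRUE))
  }
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' outscores a randomly chosen negative, ties counting one half.
#'
#' @param scores real-valued scores (higher means more positive).
#' @param outcomes 0/1 outcomes; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, outcomes) {
  if (length(scores) != length(outcomes)) pe_stop("auc: length mismatch")
  if (!all(outcomes %in% c(0, 1))) pe_stop("auc: outcomes must be 0/1")
  n1 <- sum(outcomes == 1); n0 <- sum(outcomes == 0)
  if (n1 == 0L || n0 == 0L) pe_stop("auc: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Root mean squared error
#' @param predictions,outcomes numeric vectors of equal length.
#' @return non-negative RMSE.
#' @export
rmse <- function(predictions, outcomes) {
  if (length(predictions) != length(outcomes)) pe_stop("rmse: length mismatch")
  sqrt(mean((predictions - outcomes)^2))
}

#' Mean absolute error
#' @param predictions,outcomes numeric vectors of equal length.
#' @return non-negative MAE.
#' @export
mae <- function(predictions, outcomes) {
  if (length(predictions) != length(outcomes)) pe_stop("mae: length mismatch")
  mean(abs(predictions - outcomes))
}

#' Nadeau-Bengio corrected resampled t-test
#'
#' Paired t-test on per-fold performance differences with the variance
#' inflated by the train/test overlap factor: the statistic is
#' `mean(d) / sqrt((1/K + n_test/n_train) * var(d))` on `K - 1` degrees of
#' freedom. The correction compensates for the optimism of the naive paired
#' test caused by overlapping training sets. The p-value is one-sided in the
#' improvement direction: orient `fold_differences` so that positive values
#' mean the candidate model improved (negate lower-is-better metrics first).
#'
#' @param fold_differences per-fold differences, length `K >= 2`.
#' @param n_train,n_test (average) training and test fold sizes.
#' @param alternative only `"better"` (one-sided improvement) is supported.
#' @return list with elements `t`, `df` and `p`.
#' @export
nb_corrected_ttest <- function(fold_differences, n_train, n_test,
                               alternative = c("better")) {
  alternative <- match.arg(alternative)
  d <- as.numeric(fold_differences)
  K <- length(d)
  if (K < 2L) pe_stop("nb_corrected_ttest: need at least 2 fold differences")
  if (!is_scalar_number(n_train) || !is_scalar_number(n_test) ||
      n_train <= 0 || n_test <= 0) {
    pe_stop("nb_corrected_ttest: fold sizes must be positive")
  }
  s2 <- stats::var(d)
  if (s2 == 0) {
    if (mean(d) != 0) {
      pe_stop("nb_corrected_ttest: zero variance with non-zero mean difference (degenerate)")
    }
    warning("nb_corrected_ttest: all fold differences are zero; returning t = 0, p = 0.5",
            call. = FALSE)
    return(list(t = 0, df = K - 1, p = 0.5))
  }
  t_stat <- mean(d) / sqrt((1 / K + n_test / n_train) * s2)
  list(t = t_stat, df = K - 1,
       p = stats::pt(t_stat, df = K - 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]):
#' monotone in the raw p-values, capped at 1, idempotent. Apply jointly
#' across all model-by-metric tests of one experiment.
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    pe_stop("bh_adjust: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

# ---- models ----------------------------------------------------------------

#' Cross-validation model: frequentist maximum likelihood
#'
#' @param label row label in reports.
#' @return a model constructor for [kfold_cv()].
#' @export
cv_model_frequentist <- function(label = "Frequentist") {
  structure(list(label = label, fit = function(train, family) {
    m <- suppressWarnings(fit_mle(train, family))
    list(coef = m$theta_hat, cov = m$cov, sigma2 = m$sigma2)
  }), class = "cv_model")
}

#' Cross-validation model: Bayesian posterior under a prior set
#'
#' Predictions are plug-in at the posterior mode; for linear problems the
#' Gaussian predictive variance is `sigma2 + x' cov x`.
#'
#' @param priors a [prior_set()].
#' @param intercept_prior prior on the intercept.
#' @param label row label in reports (defaults to the set label).
#' @return a model constructor for [kfold_cv()].
#' @export
cv_model_bayes <- function(priors, intercept_prior = default_intercept_prior(),
                           label = priors$label) {
  stopifnot(inherits(priors, "prior_set"))
  structure(list(label = label, fit = function(train, family) {
    post <- laplace_posterior(train, family, priors, intercept_prior)
    list(coef = post$mode, cov = post$cov, sigma2 = post$sigma2)
  }), class = "cv_model")
}

#' Bayesian CV models for every set of a prior document
#' @param doc a [prior_document()].
#' @param intercept_prior prior on the intercept.
#' @return named list of model constructors, one per set.
#' @export
cv_models_from_document <- function(doc, intercept_prior = default_intercept_prior()) {
  stopifnot(inherits(doc, "prior_document"))
  models <- lapply(doc$sets, cv_model_bayes, intercept_prior = intercept_prior)
  names(models) <- set_labels(doc)
  models
}

# deterministic fold assignment; stratified = round-robin within class
make_folds <- function(y, K, seed, stratified) {
  n <- length(y)
  fold <- integer(n)
  withr::with_seed(as.integer(seed), {
    if (stratified) {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- rep_len(sample.int(K), length(idx))
      }
    } else {
      fold <- rep_len(seq_len(K), n)[sample.int(n)]
    }
  })
  fold
}

metric_direction <- function(metric) {
  switch(metric, auc = "higher", brier = , mnls = , rmse = , mae = "lower",
         pe_stop("unknown metric '%s'", metric))
}

default_metrics <- function(family) {
  if (family == "logistic") c("brier", "mnls", "auc") else c("mnls", "rmse", "mae")
}

evaluate_predictions <- function(metric, family, fit, X1_test, y_test) {
  eta <- drop(X1_test %*% fit$coef)
  if (family == "logistic") {
    prob <- stats::plogis(eta)
    switch(metric,
           brier = brier_score(prob, y_test),
           mnls = mean_neg_log_score(prob, y_test),
           auc = auc(prob, y_test))
  } else {
    switch(metric,
           mnls = {
             pred_var <- fit$sigma2 + rowSums((X1_test %*% fit$cov) * X1_test)
             mean_neg_log_score(eta, y_test, sd = sqrt(pred_var))
           },
           rmse = rmse(eta, y_test),
           mae = mae(eta, y_test))
  }
}

#' K-fold cross-validation over a set of models
#'
#' Evaluates every model on the identical fold partition (stratified by class
#' for binary responses by default, plain shuffled otherwise), deterministic
#' given the seed. Bayesian models predict with their posterior-mode
#' coefficients.
#'
#' @param data a [regression_dataset()].
#' @param models named list of model constructors ([cv_model_frequentist()],
#'   [cv_model_bayes()], [cv_models_from_document()]).
#' @param family `"logistic"` or `"linear"`.
#' @param K number of folds (>= 2; `K = n` gives leave-one-out).
#' @param seed integer seed for the fold assignment.
#' @param stratified stratify folds by class; defaults to `TRUE` for a binary
#'   response, `FALSE` otherwise. AUC requires stratification so every test
#'   fold holds both classes.
#' @param metrics metric names; defaults to brier/mnls/auc (logistic) or
#'   mnls/rmse/mae (linear).
#' @return an object of class `cv_result`: fold assignment, per-fold sizes,
#'   and a metric -> (model x fold) score matrix list.
#' @export
kfold_cv <- function(data, models, family = c("logistic", "linear"), K = 5,
                     seed = 1, stratified = NULL, metrics = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(data, "regression_dataset"))
  if (!is_scalar_number(K) || K < 2) pe_stop("kfold_cv: K must be at least 2")
  K <- as.integer(K)
  n <- length(data$y)
  if (K > n) pe_stop("kfold_cv: K cannot exceed the number of samples")
  binary <- all(data$y %in% c(0, 1))
  if (is.null(stratified)) stratified <- binary
  if (stratified && !binary) pe_stop("kfold_cv: stratification needs a binary response")
  if (is.null(metrics)) metrics <- default_metrics(family)
  for (m in metrics) metric_direction(m)  # validates names
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- vapply(models, `[[`, character(1), "label")
  }
  fold <- make_folds(data$y, K, seed, stratified)
  n_test <- tabulate(fold, nbins = K)
  n_train <- n - n_test
  scores <- lapply(metrics, function(m) {
    matrix(NA_real_, length(models), K, dimnames = list(names(models), NULL))
  })
  names(scores) <- metrics
  for (k in seq_len(K)) {
    tr <- fold != k
    train <- tryCatch(
      regression_dataset(data$X[tr, , drop = FALSE], data$y[tr],
                         variable_names = data$variable_names),
      error = function(e) pe_stop("kfold_cv: fold %d untrainable: %s", k,
                                  conditionMessage(e)))
    X1_test <- cbind(`(Intercept)` = 1, data$X[!tr, , drop = FALSE])
    y_test <- data$y[!tr]
    for (mn in names(models)) {
      fit <- tryCatch(models[[mn]]$fit(train, family), error = function(e) {
        pe_stop("kfold_cv: model '%s' failed on fold %d: %s", mn, k,
                conditionMessage(e))
      })
      for (metric in metrics) {
        scores[[metric]][mn, k] <- evaluate_predictions(metric, family, fit,
                                                        X1_test, y_test)
      }
    }
  }
  structure(list(fold = fold, K = K, models = names(models), metrics = metrics,
                 scores = scores, n_train = n_train, n_test = n_test,
                 seed = as.integer(seed), family = family,
                 stratified = stratified),
            class = "cv_result")
}

#' Compare models against a baseline with corrected one-sided tests
#'
#' For every non-baseline model and metric, forms the per-fold improvement
#' over the baseline (oriented by the metric's direction), applies the
#' Nadeau-Bengio corrected one-sided t-test of "the candidate performs
#' better", and adjusts all resulting p-values jointly with
#' Benjamini-Hochberg.
#'
#' @param cv a `cv_result` from [kfold_cv()].
#' @param baseline name of the baseline model (default `"Frequentist"`).
#' @return an object of class `comparison_report`: a data frame of per
#'   (model, metric) mean scores, mean differences, t statistics, degrees of
#'   freedom, raw and adjusted p-values, plus the baseline's mean scores as
#'   an attribute.
#' @export
compare_models <- function(cv, baseline = "Frequentist") {
  stopifnot(inherits(cv, "cv_result"))
  if (!baseline %in% cv$models) {
    pe_stop("compare_models: baseline '%s' was not cross-validated", baseline)
  }
  others <- setdiff(cv$models, baseline)
  if (length(others) == 0L) pe_stop("compare_models: nothing to compare")
  nb_train <- mean(cv$n_train)
  nb_test <- mean(cv$n_test)
  rows <- list()
  for (mn in others) {
    for (metric in cv$metrics) {
      base_scores <- cv$scores[[metric]][baseline, ]
      mod_scores <- cv$scores[[metric]][mn, ]
      d <- if (metric_direction(metric) == "lower") base_scores - mod_scores
           else mod_scores - base_scores
      test <- withCallingHandlers(
        nb_corrected_ttest(d, n_train = nb_train, n_test = nb_test),
        warning = function(w) invokeRestart("muffleWarning"))
      rows[[length(rows) + 1L]] <- data.frame(
        model = mn, metric = metric,
        metric_mean = mean(mod_scores),
        baseline_mean = mean(base_scores),
        mean_difference = mean(d),
        t = test$t, df = test$df, p = test$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p)
  attr(out, "baseline") <- baseline
  attr(out, "K") <- cv$K
  attr(out, "seed") <- cv$seed
  class(out) <- c("comparison_report", class(out))
  out
}

#' Write a comparison report as a delimited table plus a JSON twin
#'
#' The text table uses the reference layout: models as rows, metrics as
#' columns, each cell "mean (p = adjusted)"; the JSON twin carries full
#' precision.
#'
#' @param report a `comparison_report`.
#' @param stem output path without extension; writes `<stem>.tsv` and
#'   `<stem>.json`.
#' @return paths of the two files, invisibly.
#' @export
write_comparison_report <- function(report, stem) {
  stopifnot(inherits(report, "comparison_report"))
  baseline <- attr(report, "baseline")
  metrics <- unique(report$metric)
  models <- unique(report$model)
  tab <- matrix("", length(models) + 1L, length(metrics),
                dimnames = list(c(baseline, models), metrics))
  for (metric in metrics) {
    sub <- report[report$metric == metric, ]
    tab[baseline, metric] <- sprintf("%.4f", sub$baseline_mean[1])
    for (i in seq_len(nrow(sub))) {
      tab[sub$model[i], metric] <- sprintf("%.4f (p = %.3f)",
                                           sub$metric_mean[i],
                                           sub$p_adjusted[i])
    }
  }
  tsv <- paste0(stem, ".tsv")
  out <- data.frame(Model = rownames(tab), tab, check.names = FALSE)
  utils::write.table(out, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  json <- paste0(stem, ".json")
  payload <- list(baseline = baseline, K = attr(report, "K"),
                  seed = attr(report, "seed"),
                  tests = lapply(seq_len(nrow(report)), function(i) {
                    as.list(report[i, , drop = FALSE])
                  }))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), json)
  invisible(c(tsv, json))
}
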