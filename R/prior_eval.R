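# Prior-data agreement scoring: closed-form Gaussian KL divergence with the
# MLE distribution as reference measure, aggregated into per-variable tables
# with column means and tie-aware average ranks; plus prior predictive checks.

#' Kullback-Leibler divergence from the MLE distribution to a prior
#'
#' Closed form for two univariate Gaussians, with the MLE sampling
#' distribution as the reference measure:
#' `log(sd_prior / sd_mle) + (sd_mle^2 + (mean_mle - mean_prior)^2) /
#' (2 sd_prior^2) - 1/2`.
#' A prior that places little mass where the MLE distribution is concentrated
#' scores a large divergence ("the data surprise the prior"); the asymmetry
#' is deliberate -- priors in conflict with the data are penalized much more
#' than priors that are merely wide.
#'
#' @param mle_marginal [gaussian1d()] marginal of the MLE distribution.
#' @param prior [gaussian1d()] prior for the same coefficient.
#' @return non-negative divergence in nats; 0 iff the two Gaussians coincide.
#' @export
#' @examples
#' gaussian_kl(gaussian1d(0, 1), gaussian1d(1, 1))  # 0.5
gaussian_kl <- function(mle_marginal, prior) {
  if (!inherits(mle_marginal, "gaussian1d") || !inherits(prior, "gaussian1d")) {
    pe_stop("gaussian_kl: both arguments must be gaussian1d objects")
  }
  log(prior$sd / mle_marginal$sd) +
    (mle_marginal$sd^2 + (mle_marginal$mean - prior$mean)^2) / (2 * prior$sd^2) -
    0.5
}

#' Tie-aware average ranks of prior sets
#'
#' Within each variable (row), sets are ranked ascending by divergence (lower
#' is better); tied values all receive the minimum ("competition") rank of
#' their block. Per-set ranks are then averaged over variables. The minimum
#' rule is the only standard tie rule consistent with the reference rank
#' tables this package reproduces.
#'
#' @param m numeric matrix, variables in rows, prior sets in columns.
#' @param tie_rule tie handling; only `"min"` is supported.
#' @return named numeric vector of per-set average ranks, in `[1, ncol(m)]`.
#' @export
average_rank <- function(m, tie_rule = c("min")) {
  tie_rule <- match.arg(tie_rule)
  m <- as.matrix(m)
  if (length(m) == 0L) pe_stop("average_rank: empty matrix")
  if (!all(is.finite(m))) pe_stop("average_rank: matrix must be finite")
  ranks <- t(apply(m, 1, rank, ties.method = tie_rule))
  if (ncol(m) == 1L) ranks <- matrix(1, nrow(m), 1)  # apply() drops dims
  out <- colMeans(ranks)
  names(out) <- colnames(m)
  out
}

new_kl_report <- function(kl, rounding = 2) {
  kl <- as.matrix(kl)
  if (length(kl) == 0L) pe_stop("kl_report: empty matrix")
  if (any(!is.finite(kl)) || any(kl < 0)) {
    pe_stop("kl_report: KL entries must be finite and non-negative")
  }
  structure(list(variables = rownames(kl),
                 set_labels = colnames(kl),
                 kl = kl,
                 column_means = colMeans(kl),
                 avg_ranks = average_rank(kl),
                 rounding = rounding),
            class = "kl_report")
}

#' Build a KL report from a precomputed per-variable divergence matrix
#'
#' Use this to aggregate externally computed (e.g. published) per-variable KL
#' values into column means and average ranks with the same rules as
#' [kl_table()].
#'
#' @param kl numeric matrix of non-negative divergences, variables in rows
#'   (rownames) and prior sets in columns (colnames).
#' @param rounding display decimals (default 2); internal values keep full
#'   precision.
#' @return an object of class `kl_report`.
#' @export
kl_report_from_matrix <- function(kl, rounding = 2) {
  new_kl_report(kl, rounding = rounding)
}

#' Score every prior set of a document against the fitted MLE distribution
#'
#' Computes the per-variable KL divergence between the Gaussian marginal of
#' the MLE distribution (from the full-model covariance diagonal;
#' correlations ignored) and each set's prior, for every covariate. The
#' intercept is excluded. Column means and minimum-rank average ranks give
#' the per-set summary rows.
#'
#' @param mle an `mle_approx` from [fit_mle()] or [bootstrap_mle()].
#' @param doc a [prior_document()] whose sets cover exactly the fitted
#'   variables.
#' @param rounding display decimals (default 2).
#' @return a `kl_report`.
#' @export
kl_table <- function(mle, doc, rounding = 2) {
  stopifnot(inherits(mle, "mle_approx"), inherits(doc, "prior_document"))
  vars <- coef_variables(mle)
  if (length(vars) == 0L) pe_stop("kl_table: the fit has no covariates")
  labels <- set_labels(doc)
  kl <- matrix(NA_real_, length(vars), length(labels),
               dimnames = list(vars, labels))
  for (s in doc$sets) {
    check_alignment(names(s$entries), vars, s$label)
    for (v in vars) {
      kl[v, s$label] <- gaussian_kl(marginal(mle, v), s$entries[[v]]$prior)
    }
  }
  new_kl_report(kl, rounding = rounding)
}

kl_report_display <- function(x) {
  body <- apply(x$kl, 2, function(col) {
    formatC(round_display(col, x$rounding), format = "f", digits = x$rounding)
  })
  body <- matrix(body, nrow = length(x$variables),
                 dimnames = list(x$variables, x$set_labels))
  footer <- rbind(
    `Avg KL Div.` = formatC(round_display(x$column_means, x$rounding),
                            format = "f", digits = x$rounding),
    `Avg Rank` = formatC(round_display(x$avg_ranks, x$rounding),
                         format = "f", digits = x$rounding)
  )
  rbind(body, footer)
}

#' @export
print.kl_report <- function(x, ...) {
  cat(sprintf("<kl_report> %d variable(s) x %d prior set(s)\n",
              length(x$variables), length(x$set_labels)))
  print(kl_report_display(x), quote = FALSE, right = TRUE)
  invisible(x)
}

#' Write a KL report as a delimited table plus a JSON twin
#'
#' The text table mirrors the reference layout (variables as rows, sets as
#' columns, "Avg KL Div." and "Avg Rank" footer rows) at display rounding;
#' the JSON twin carries full precision.
#'
#' @param report a `kl_report`.
#' @param stem output path without extension; writes `<stem>.tsv` and
#'   `<stem>.json`.
#' @return paths of the two files, invisibly.
#' @export
write_kl_report <- function(report, stem) {
  stopifnot(inherits(report, "kl_report"))
  tsv <- paste0(stem, ".tsv")
  disp <- kl_report_display(report)
  tab <- data.frame(Variable = rownames(disp), disp, check.names = FALSE)
  utils::write.table(tab, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  json <- paste0(stem, ".json")
  payload <- list(variables = report$variables,
                  set_labels = report$set_labels,
                  kl = apply(report$kl, 1, as.list),
                  column_means = as.list(stats::setNames(report$column_means,
                                                         report$set_labels)),
                  avg_ranks = as.list(stats::setNames(report$avg_ranks,
                                                      report$set_labels)),
                  rounding = report$rounding)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), json)
  invisible(c(tsv, json))
}

#' Read a per-variable KL matrix from delimited text
#'
#' Expects a header row of set labels and a first column of variable names
#' (the layout [write_kl_report()] emits, without the footer rows).
#'
#' @param path delimited text file (tab separated).
#' @return numeric matrix with variable rownames and set-label colnames.
#' @export
read_kl_matrix <- function(path) {
  if (!file.exists(path)) pe_stop("KL matrix file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

# ---- prior predictive checks ----------------------------------------------

#' Sample from the prior predictive distribution
#'
#' Each draw samples a coefficient vector from the (independent Gaussian)
#' prior and then responses from the likelihood at the observed design
#' points: Bernoulli(inverse-logit(eta)) for logistic problems, Gaussian with
#' variance `sigma2` for linear ones.
#'
#' @param data a [regression_dataset()] supplying the design points.
#' @param family `"logistic"` or `"linear"`.
#' @param priors a [prior_set()] aligned to the data.
#' @param intercept_prior prior on the intercept.
#' @param n_draws number of simulated response sets (>= 1).
#' @param seed integer seed.
#' @param sigma2 residual variance for linear problems.
#' @return numeric matrix, `n_draws` rows by `n` observations; rows are
#'   simulated response sets.
#' @export
prior_predictive_sample <- function(data, family = c("logistic", "linear"),
                                    priors,
                                    intercept_prior = default_intercept_prior(),
                                    n_draws = 1000, seed = 1, sigma2 = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(data, "regression_dataset"))
  if (!is_scalar_number(n_draws) || n_draws < 1) {
    pe_stop("prior_predictive_sample: n_draws must be >= 1")
  }
  if (family == "linear") {
    if (!is_scalar_number(sigma2) || sigma2 <= 0) {
      pe_stop("prior_predictive_sample: linear family needs sigma2 > 0")
    }
  }
  pv <- prior_vectors(priors, intercept_prior, data$variable_names)
  X1 <- design_with_intercept(data)
  n <- nrow(X1); p1 <- ncol(X1)
  n_draws <- as.integer(n_draws)
  withr::with_seed(as.integer(seed), {
    theta <- matrix(stats::rnorm(n_draws * p1, mean = rep(pv$mean, each = n_draws),
                                 sd = rep(pv$sd, each = n_draws)),
                    n_draws, p1)
    eta <- theta %*% t(X1)
    y_star <- if (family == "logistic") {
      matrix(stats::rbinom(length(eta), 1, stats::plogis(eta)), n_draws, n)
    } else {
      eta + matrix(stats::rnorm(length(eta), 0, sqrt(sigma2)), n_draws, n)
    }
    structure(y_star, family = family, seed = as.integer(seed))
  })
}

ppc_statistics <- function() {
  list(mean = mean,
       sd = stats::sd,
       median = stats::median,
       q10 = function(x) unname(stats::quantile(x, 0.10)),
       q90 = function(x) unname(stats::quantile(x, 0.90)))
}

#' Summarize a prior predictive check
#'
#' Compares summary statistics (mean, sd, median, 10%/90% quantiles) of the
#' observed response with their distributions over the simulated response
#' sets. The tail proportion is `min(P(sim <= obs), P(sim >= obs))`: about
#' 0.5 when the observed statistic sits at the simulated median, near 0 when
#' it lies outside the simulated range.
#'
#' @param simulated matrix of simulated response sets from
#'   [prior_predictive_sample()] (>= 100 draws).
#' @param observed observed response vector.
#' @return a data frame of class `ppc_summary` with one row per statistic:
#'   observed value, simulated mean/sd, simulated 2.5% and 97.5% quantiles,
#'   and the tail proportion.
#' @export
summarize_ppc <- function(simulated, observed) {
  simulated <- as.matrix(simulated)
  if (nrow(simulated) < 100L) {
    pe_stop("summarize_ppc: at least 100 draws are required (got %d)", nrow(simulated))
  }
  if (ncol(simulated) != length(observed)) {
    pe_stop("summarize_ppc: simulated sets and observed response differ in length")
  }
  stats_list <- ppc_statistics()
  rows <- lapply(names(stats_list), function(sname) {
    f <- stats_list[[sname]]
    obs <- f(observed)
    sim <- apply(simulated, 1, f)
    tail_prop <- min(mean(sim <= obs), mean(sim >= obs))
    data.frame(statistic = sname, observed = obs,
               sim_mean = mean(sim), sim_sd = stats::sd(sim),
               sim_q2.5 = unname(stats::quantile(sim, 0.025)),
               sim_q97.5 = unname(stats::quantile(sim, 0.975)),
               tail_prop = tail_prop,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ppc_summary", class(out))
  out
}
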