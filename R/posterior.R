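# Gaussian posterior approximations under independent Gaussian coefficient
# priors: Laplace (logistic) and exact conjugacy with plug-in residual
# variance (linear).

new_posterior_approx <- function(mode, cov, family, method, sigma2 = NULL) {
  cov <- (cov + t(cov)) / 2
  ok <- tryCatch({chol(cov); TRUE}, error = function(e) FALSE)
  if (!ok) pe_stop("posterior_approx: covariance is not positive definite")
  structure(list(mode = mode, cov = cov, family = family, method = method,
                 sigma2 = sigma2),
            class = "posterior_approx")
}

#' @export
print.posterior_approx <- function(x, ...) {
  cat(sprintf("<posterior_approx> %s family, %s method\n", x$family, x$method))
  tab <- data.frame(mode = x$mode, sd = sqrt(diag(x$cov)))
  print(round(tab, 4))
  invisible(x)
}

#' @export
marginal.posterior_approx <- function(x, variable) {
  marginal_impl(x$mode, x$cov, variable, "posterior_approx")
}

# prior mean / sd vectors (intercept first) aligned to the data's variables
prior_vectors <- function(priors, intercept_prior, variable_names) {
  stopifnot(inherits(priors, "prior_set"), inherits(intercept_prior, "gaussian1d"))
  if (length(variable_names) > 0) {
    check_alignment(names(priors$entries), variable_names, priors$label)
  }
  m <- c(intercept_prior$mean,
         vapply(variable_names, function(v) priors$entries[[v]]$prior$mean, numeric(1)))
  s <- c(intercept_prior$sd,
         vapply(variable_names, function(v) priors$entries[[v]]$prior$sd, numeric(1)))
  names(m) <- names(s) <- c("(Intercept)", variable_names)
  list(mean = m, sd = s)
}

#' Default prior for the intercept
#'
#' Elicited prior sets cover the covariate coefficients only; the intercept
#' gets this wide default, N(0, 10^2), unless the caller overrides it. The
#' intercept is excluded from all KL reports.
#'
#' @return a [gaussian1d()].
#' @export
default_intercept_prior <- function() gaussian1d(0, 10)

#' Exact conjugate posterior for the linear model
#'
#' With a Gaussian likelihood of known residual variance `sigma2` and
#' independent Gaussian coefficient priors (mean vector m, diagonal covariance
#' S), the posterior is Gaussian with covariance
#' `(S^-1 + X'X / sigma2)^-1` and mean `cov (S^-1 m + X'y / sigma2)`:
#' posterior precision is prior precision plus data precision.
#'
#' @param data a [regression_dataset()].
#' @param priors a [prior_set()] aligned to the data's variables.
#' @param intercept_prior prior on the intercept (default
#'   [default_intercept_prior()]).
#' @param sigma2 residual variance, strictly positive; typically the plug-in
#'   `RSS / (n - p - 1)` from [fit_mle()].
#' @return a `posterior_approx` with `method = "conjugate"`.
#' @export
conjugate_linear_posterior <- function(data, priors,
                                       intercept_prior = default_intercept_prior(),
                                       sigma2) {
  stopifnot(inherits(data, "regression_dataset"))
  if (!is_scalar_number(sigma2) || sigma2 <= 0) {
    pe_stop("conjugate_linear_posterior: sigma2 must be strictly positive")
  }
  pv <- prior_vectors(priors, intercept_prior, data$variable_names)
  X1 <- design_with_intercept(data)
  prec <- diag(1 / pv$sd^2, ncol(X1)) + crossprod(X1) / sigma2
  R <- tryCatch(chol(prec), error = function(e) {
    pe_stop("conjugate_linear_posterior: combined precision is singular")
  })
  cov <- chol2inv(R)
  dimnames(cov) <- list(colnames(X1), colnames(X1))
  b <- pv$mean / pv$sd^2 + drop(crossprod(X1, data$y)) / sigma2
  mode <- drop(cov %*% b)
  names(mode) <- colnames(X1)
  new_posterior_approx(mode, cov, "linear", "conjugate", sigma2 = sigma2)
}

#' Gaussian posterior approximation under a prior set
#'
#' Combines likelihood and prior per Bayes' rule and returns a Gaussian
#' approximation of the posterior. Logistic family: Laplace approximation --
#' the mode maximizes log-likelihood plus log-prior (Newton with step
#' halving) and the covariance is the inverse negative Hessian of the
#' log-posterior at the mode. Linear family: the exact conjugate closed form
#' with the plug-in residual variance from the maximum-likelihood fit.
#'
#' @inheritParams conjugate_linear_posterior
#' @param family `"logistic"` or `"linear"`.
#' @return a `posterior_approx` (`method` `"laplace"` or `"conjugate"`).
#' @export
laplace_posterior <- function(data, family = c("logistic", "linear"), priors,
                              intercept_prior = default_intercept_prior()) {
  family <- match.arg(family)
  stopifnot(inherits(data, "regression_dataset"))
  if (family == "linear") {
    mle <- suppressWarnings(fit_mle(data, "linear"))
    if (mle$sigma2 <= 0) {
      pe_stop("laplace_posterior: zero residual variance; supply sigma2 via conjugate_linear_posterior()")
    }
    return(conjugate_linear_posterior(data, priors, intercept_prior,
                                      sigma2 = mle$sigma2))
  }
  pv <- prior_vectors(priors, intercept_prior, data$variable_names)
  X1 <- design_with_intercept(data)
  fit <- logistic_newton(X1, data$y, prior_prec = 1 / pv$sd^2,
                         prior_mean = pv$mean)
  mode <- fit$beta
  names(mode) <- colnames(X1)
  cov <- tryCatch(solve(fit$hessian), error = function(e) {
    pe_stop("laplace_posterior: Hessian not positive definite at the mode")
  })
  dimnames(cov) <- list(colnames(X1), colnames(X1))
  new_posterior_approx(mode, cov, "logistic", "laplace")
}

#' Central credible interval for one coefficient
#'
#' @param posterior a `posterior_approx`.
#' @param variable coefficient name.
#' @param level interval mass (default 0.90).
#' @return length-2 vector, lower and upper bound.
#' @export
credible_interval <- function(posterior, variable, level = 0.90) {
  g <- marginal(posterior, variable)
  half <- stats::qnorm(1 - (1 - level) / 2) * g$sd
  c(lower = g$mean - half, upper = g$mean + half)
}
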