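# Gaussian approximations of the MLE sampling distribution ("data
# distribution"): asymptotic inverse observed Fisher information, or a
# case-resampling bootstrap.

new_mle_approx <- function(theta_hat, cov, family, sigma2 = NULL, n, method,
                           degenerate = FALSE, iterations = NA_integer_,
                           n_failed = NA_integer_) {
  cov <- (cov + t(cov)) / 2  # numerically symmetric by construction; enforce
  if (max(abs(cov - t(cov))) > 1e-10) {
    pe_stop("mle_approx: covariance not symmetric")
  }
  if (!degenerate && any(diag(cov) <= 0)) {
    pe_stop("mle_approx: covariance diagonal must be strictly positive")
  }
  structure(list(theta_hat = theta_hat, cov = cov, family = family,
                 sigma2 = sigma2, n = n, method = method,
                 degenerate = degenerate, iterations = iterations,
                 n_failed = n_failed),
            class = "mle_approx")
}

#' @export
print.mle_approx <- function(x, ...) {
  cat(sprintf("<mle_approx> %s fit (%s), n = %d%s\n", x$family, x$method, x$n,
              if (x$degenerate) " [degenerate: zero residual variance]" else ""))
  tab <- data.frame(estimate = x$theta_hat, sd = sqrt(pmax(diag(x$cov), 0)))
  print(round(tab, 4))
  invisible(x)
}

#' Gaussian marginal of one coefficient
#'
#' Extracts the univariate Gaussian marginal for one variable from a fitted
#' approximation (MLE or posterior): mean from the estimate vector, sd from
#' the square root of the corresponding covariance diagonal entry.
#' Off-diagonal covariance is deliberately ignored, matching the
#' per-variable reporting convention.
#'
#' @param x an `mle_approx` or `posterior_approx`.
#' @param variable variable name (`"(Intercept)"` for the intercept).
#' @return a [gaussian1d()].
#' @export
marginal <- function(x, variable) UseMethod("marginal")

marginal_impl <- function(theta, cov, variable, what) {
  if (!variable %in% names(theta)) {
    pe_stop("%s: unknown variable '%s'", what, variable)
  }
  v <- cov[variable, variable]
  if (v <= 0) pe_stop("%s: zero variance for '%s' (degenerate fit)", what, variable)
  gaussian1d(unname(theta[variable]), sqrt(v))
}

#' @export
marginal.mle_approx <- function(x, variable) {
  marginal_impl(x$theta_hat, x$cov, variable, "mle_approx")
}

# names of the non-intercept coefficients
coef_variables <- function(x) setdiff(names(x$theta_hat), "(Intercept)")

logistic_loglik <- function(beta, X1, y) {
  eta <- drop(X1 %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

# Newton solver shared by the MLE fit (prior_prec = 0) and the Laplace
# posterior (prior_prec > 0). Step halving (up to 20 times) guards against
# overshooting; convergence is declared on the gradient max-norm.
logistic_newton <- function(X1, y, prior_prec = NULL, prior_mean = NULL,
                            tol = 1e-8, max_iter = 100L, max_halvings = 20L) {
  p1 <- ncol(X1)
  beta <- numeric(p1)
  penalized <- !is.null(prior_prec)
  objective <- function(b) {
    ll <- logistic_loglik(b, X1, y)
    if (penalized) ll <- ll - 0.5 * sum(prior_prec * (b - prior_mean)^2)
    ll
  }
  obj <- objective(beta)
  grad_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X1, y - mu))
    if (penalized) grad <- grad - prior_prec * (beta - prior_mean)
    gnorm <- max(abs(grad))
    grad_trace <- c(grad_trace, gnorm)
    if (gnorm <= tol) {
      w <- mu * (1 - mu)
      H <- crossprod(X1 * w, X1)
      if (penalized) H <- H + diag(prior_prec, p1)
      return(list(beta = beta, hessian = H, converged = TRUE, iterations = iter,
                  eta = eta, grad_trace = grad_trace))
    }
    w <- mu * (1 - mu)
    H <- crossprod(X1 * w, X1)
    if (penalized) H <- H + diag(prior_prec, p1)
    step <- tryCatch(solve(H, grad), error = function(e) {
      pe_stop("logistic fit: singular Hessian at iteration %d (%s)", iter,
              conditionMessage(e))
    })
    # with very strong priors the gradient tolerance can be unreachable in
    # floating point; a Newton step below machine resolution of beta means
    # the mode is located as precisely as the arithmetic allows
    if (max(abs(step)) <= 1e-12 * (1 + max(abs(beta)))) {
      return(list(beta = beta, hessian = H, converged = TRUE, iterations = iter,
                  eta = eta, grad_trace = grad_trace))
    }
    lambda <- 1
    for (h in seq_len(max_halvings + 1L)) {
      cand <- beta + lambda * step
      cand_obj <- objective(cand)
      if (is.finite(cand_obj) && cand_obj >= obj - 1e-12) break
      lambda <- lambda / 2
      if (h == max_halvings + 1L) {
        pe_stop("logistic fit: step halving failed after %d halvings at iteration %d",
                max_halvings, iter)
      }
    }
    beta <- beta + lambda * step
    obj <- objective(beta)
    # unpenalized fits can diverge under (quasi-)separation: the linear
    # predictor runs away while the gradient stalls above tolerance
    if (!penalized && max(abs(drop(X1 %*% beta))) > 30) {
      sds <- apply(X1[, -1, drop = FALSE], 2, stats::sd)
      score <- abs(beta[-1]) * ifelse(sds > 0, sds, 1)
      suspects <- names(sort(score, decreasing = TRUE))
      pe_stop("logistic fit: complete or quasi-separation suspected (diverging coefficients); suspect variable(s): %s",
              paste(utils::head(suspects, 2), collapse = ", "))
    }
  }
  pe_stop("logistic fit: no convergence in %d iterations (gradient max-norm trace: %s)",
          max_iter, paste(signif(utils::tail(grad_trace, 5), 3), collapse = ", "))
}

#' Maximum-likelihood fit with Gaussian sampling-distribution approximation
#'
#' Fits the regression by maximum likelihood and returns the asymptotic
#' Gaussian approximation of the estimator's sampling distribution: the point
#' estimate together with the inverse observed Fisher information as
#' covariance. Logistic fits use Newton iterations with step halving to a
#' gradient max-norm of 1e-8 (at most 100 iterations); linear fits use the
#' normal equations with covariance `sigma2_hat * (X'X)^-1`,
#' `sigma2_hat = RSS / (n - p - 1)`.
#'
#' @param data a [regression_dataset()].
#' @param family `"logistic"` or `"linear"`.
#' @return an object of class `mle_approx` with elements `theta_hat` (named,
#'   intercept first), `cov`, and for linear fits the plug-in residual
#'   variance `sigma2`.
#' @export
fit_mle <- function(data, family = c("logistic", "linear")) {
  family <- match.arg(family)
  stopifnot(inherits(data, "regression_dataset"))
  X1 <- design_with_intercept(data)
  n <- nrow(X1); p1 <- ncol(X1)
  if (qr(X1)$rank < p1) {
    pe_stop("fit_mle: rank-deficient design matrix (collinear or constant covariates)")
  }
  if (family == "linear") {
    XtX <- crossprod(X1)
    R <- chol(XtX)
    beta <- drop(chol2inv(R) %*% crossprod(X1, data$y))
    names(beta) <- colnames(X1)
    resid <- data$y - drop(X1 %*% beta)
    rss <- sum(resid^2)
    sigma2 <- rss / (n - p1)
    degenerate <- sigma2 < 1e-12
    if (degenerate) {
      warning("fit_mle: exact fit (zero residual variance); sampling covariance is degenerate",
              call. = FALSE)
      sigma2 <- 0
    }
    cov <- sigma2 * chol2inv(R)
    dimnames(cov) <- list(colnames(X1), colnames(X1))
    new_mle_approx(beta, cov, family, sigma2 = sigma2, n = n,
                   method = "asymptotic", degenerate = degenerate)
  } else {
    if (!all(data$y %in% c(0, 1))) {
      pe_stop("fit_mle: logistic family needs a 0/1 response")
    }
    fit <- logistic_newton(X1, data$y)
    beta <- fit$beta
    names(beta) <- colnames(X1)
    cov <- solve(fit$hessian)
    dimnames(cov) <- list(colnames(X1), colnames(X1))
    new_mle_approx(beta, cov, family, n = n, method = "asymptotic",
                   iterations = fit$iterations)
  }
}

#' Bootstrap approximation of the MLE distribution
#'
#' Case-resampling bootstrap: rows are resampled with replacement `B` times,
#' the model refitted on each resample, and a Gaussian is fitted to the `B`
#' replicate estimates (their sample mean and covariance). Resamples on which
#' the fit fails (separation, rank deficiency, a single-class resample) are
#' redrawn and counted; more than 10% failures aborts.
#'
#' @param data a [regression_dataset()].
#' @param family `"logistic"` or `"linear"`.
#' @param B number of bootstrap replicates (at least 100).
#' @param seed integer seed; the same seed reproduces the result exactly.
#' @return an `mle_approx` with `method = "bootstrap"`; the number of redrawn
#'   resamples is in `$n_failed`.
#' @export
bootstrap_mle <- function(data, family = c("logistic", "linear"), B = 1000,
                          seed = 1) {
  family <- match.arg(family)
  stopifnot(inherits(data, "regression_dataset"))
  if (!is_scalar_number(B) || B < 100) {
    pe_stop("bootstrap_mle: B must be at least 100")
  }
  B <- as.integer(B)
  n <- nrow(data$X)
  max_failures <- floor(0.1 * B)
  withr::with_seed(as.integer(seed), {
    theta <- NULL
    n_failed <- 0L
    b <- 0L
    while (b < B) {
      idx <- sample.int(n, n, replace = TRUE)
      rep_fit <- tryCatch({
        d <- regression_dataset(data$X[idx, , drop = FALSE], data$y[idx],
                                variable_names = data$variable_names)
        suppressWarnings(fit_mle(d, family))
      }, error = function(e) NULL)
      if (is.null(rep_fit)) {
        n_failed <- n_failed + 1L
        if (n_failed > max_failures) {
          pe_stop("bootstrap_mle: more than 10%% of resamples failed to fit (%d failures)",
                  n_failed)
        }
        next
      }
      if (is.null(theta)) theta <- matrix(NA_real_, B, length(rep_fit$theta_hat),
                                          dimnames = list(NULL, names(rep_fit$theta_hat)))
      b <- b + 1L
      theta[b, ] <- rep_fit$theta_hat
    }
    est <- colMeans(theta)
    cov <- stats::cov(theta)
    new_mle_approx(est, cov, family, n = n, method = "bootstrap",
                   degenerate = any(diag(cov) < 1e-24), n_failed = n_failed)
  })
}
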