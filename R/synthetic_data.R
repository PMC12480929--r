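# Seeded synthetic datasets with the structure of the two case studies, so
# the whole pipeline is exercisable without downloads. Covariates are drawn
# independently from simple marginals: the evaluation machinery, not data
# realism, is what these datasets exercise.

#' Marginal description of one synthetic covariate
#'
#' @param name variable name.
#' @param dist `"gaussian"`, `"bernoulli"` or `"uniform"`.
#' @param mean,sd Gaussian parameters.
#' @param prob Bernoulli success probability.
#' @param min,max Uniform bounds.
#' @return a list describing the marginal.
#' @export
variable_marginal <- function(name, dist = c("gaussian", "bernoulli", "uniform"),
                              mean = 0, sd = 1, prob = 0.5, min = 0, max = 1) {
  dist <- match.arg(dist)
  if (dist == "gaussian" && sd <= 0) pe_stop("variable_marginal: sd must be > 0")
  if (dist == "bernoulli" && (prob <= 0 || prob >= 1)) {
    pe_stop("variable_marginal: prob must lie in (0, 1)")
  }
  if (dist == "uniform" && max <= min) pe_stop("variable_marginal: max must exceed min")
  list(name = name, dist = dist, mean = mean, sd = sd, prob = prob,
       min = min, max = max)
}

#' Specification for a synthetic regression dataset
#'
#' @param family `"logistic"` or `"linear"`.
#' @param n number of samples.
#' @param variables list of [variable_marginal()] descriptions.
#' @param true_coefficients generating coefficient vector, one per variable.
#' @param intercept numeric intercept, or `"calibrate"` (logistic only) to
#'   solve for the intercept that matches `target_prevalence` over the drawn
#'   design.
#' @param target_prevalence expected response prevalence in `(0, 1)`
#'   (logistic with calibrated intercept).
#' @param noise_sd residual standard deviation (> 0, linear only).
#' @param seed integer master seed; all randomness flows from it.
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(family = c("logistic", "linear"), n, variables,
                           true_coefficients, intercept = 0,
                           target_prevalence = NULL, noise_sd = NULL,
                           seed = 1) {
  family <- match.arg(family)
  if (!is_scalar_number(n) || n < 3) pe_stop("generator_spec: n must be >= 3")
  if (length(variables) < 1L) pe_stop("generator_spec: at least one variable")
  if (length(true_coefficients) != length(variables)) {
    pe_stop("generator_spec: true_coefficients length (%d) must equal variable count (%d)",
            length(true_coefficients), length(variables))
  }
  calibrate <- identical(intercept, "calibrate")
  if (calibrate) {
    if (family != "logistic") pe_stop("generator_spec: calibration is logistic-only")
    if (!is_scalar_number(target_prevalence) ||
        target_prevalence <= 0 || target_prevalence >= 1) {
      pe_stop("generator_spec: target_prevalence must lie in (0, 1)")
    }
  } else if (!is_scalar_number(intercept)) {
    pe_stop("generator_spec: intercept must be a number or \"calibrate\"")
  }
  if (family == "linear") {
    if (!is_scalar_number(noise_sd) || noise_sd <= 0) {
      pe_stop("generator_spec: linear family needs noise_sd > 0")
    }
  }
  structure(list(family = family, n = as.integer(n), variables = variables,
                 true_coefficients = as.numeric(true_coefficients),
                 intercept = intercept,
                 target_prevalence = target_prevalence,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "generator_spec")
}

draw_marginal <- function(v, n) {
  switch(v$dist,
         gaussian = stats::rnorm(n, v$mean, v$sd),
         bernoulli = stats::rbinom(n, 1, v$prob),
         uniform = stats::runif(n, v$min, v$max))
}

# monotone root-finding for the intercept that hits the target expected
# prevalence over the drawn design
calibrate_intercept <- function(xb, target) {
  f <- function(c) mean(stats::plogis(c + xb)) - target
  lo <- -1; hi <- 1
  while (f(lo) > 0) lo <- lo * 2
  while (f(hi) < 0) hi <- hi * 2
  root <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.5)$root
  if (abs(f(root)) > 1e-6) {
    pe_stop("generate: intercept calibration did not reach the target prevalence")
  }
  root
}

#' Generate a synthetic dataset from a specification
#'
#' Covariates are drawn independently from their stated marginals; linear
#' responses are `intercept + X beta + Gaussian noise`, logistic responses
#' are `Bernoulli(inverse-logit(intercept + X beta))`. With
#' `intercept = "calibrate"` the intercept is solved by monotone
#' root-finding so the expected prevalence over the drawn design matches the
#' target within 1e-6. The same seed yields the byte-identical dataset.
#'
#' @param spec a [generator_spec()].
#' @return a [regression_dataset()] with attributes `spec` and
#'   `intercept_used`.
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  withr::with_seed(spec$seed, {
    X <- vapply(spec$variables, draw_marginal, numeric(spec$n), n = spec$n)
    colnames(X) <- vapply(spec$variables, `[[`, character(1), "name")
    xb <- drop(X %*% spec$true_coefficients)
    if (spec$family == "logistic") {
      a <- if (identical(spec$intercept, "calibrate")) {
        calibrate_intercept(xb, spec$target_prevalence)
      } else spec$intercept
      y <- stats::rbinom(spec$n, 1, stats::plogis(a + xb))
    } else {
      a <- spec$intercept
      y <- a + xb + stats::rnorm(spec$n, 0, spec$noise_sd)
    }
    out <- regression_dataset(X, y)
    attr(out, "spec") <- spec
    attr(out, "intercept_used") <- a
    out
  })
}

#' Heart-disease-like synthetic specification
#'
#' Six covariates named and unit-scaled like the coronary-artery-disease case
#' study (age, sex, trestbps, chol, thalach, oldpeak), binary response with
#' target prevalence 0.46 over n = 303 samples and a calibrated intercept.
#' Marginal parameters and generating coefficients are fixture-invented
#' plausible values, not estimates from the real dataset.
#'
#' @param n sample size (default 303).
#' @param seed master seed.
#' @return a [generator_spec()].
#' @export
heart_like_spec <- function(n = 303, seed = 101) {
  generator_spec(
    family = "logistic", n = n,
    variables = list(
      variable_marginal("age", "gaussian", mean = 54, sd = 9),
      variable_marginal("sex", "bernoulli", prob = 0.68),
      variable_marginal("trestbps", "gaussian", mean = 131, sd = 17),
      variable_marginal("chol", "gaussian", mean = 246, sd = 52),
      variable_marginal("thalach", "gaussian", mean = 150, sd = 23),
      variable_marginal("oldpeak", "uniform", min = 0, max = 4)
    ),
    # fixture-invented generating coefficients on the natural log-odds scale
    true_coefficients = c(age = 0.05, sex = 1.2, trestbps = 0.02,
                          chol = 0.004, thalach = -0.035, oldpeak = 0.7),
    intercept = "calibrate", target_prevalence = 0.46, seed = seed
  )
}

#' Concrete-strength-like synthetic specification
#'
#' Eight covariates named and unit-scaled like the concrete compressive
#' strength case study, continuous response (MPa-like scale) over n = 1030
#' samples. Marginal parameters and generating coefficients are
#' fixture-invented plausible values, not estimates from the real dataset.
#'
#' @param n sample size (default 1030).
#' @param seed master seed.
#' @return a [generator_spec()].
#' @export
concrete_like_spec <- function(n = 1030, seed = 202) {
  generator_spec(
    family = "linear", n = n,
    variables = list(
      variable_marginal("Age", "uniform", min = 1, max = 365),
      variable_marginal("Cement", "gaussian", mean = 281, sd = 104),
      variable_marginal("Blast Furnace Slag", "uniform", min = 0, max = 359),
      variable_marginal("Fly Ash", "uniform", min = 0, max = 200),
      variable_marginal("Water", "gaussian", mean = 182, sd = 21),
      variable_marginal("Superplasticizer", "uniform", min = 0, max = 32),
      variable_marginal("Coarse Aggregate", "gaussian", mean = 972, sd = 78),
      variable_marginal("Fine Aggregate", "gaussian", mean = 774, sd = 80)
    ),
    # fixture-invented generating coefficients (MPa per unit of component)
    true_coefficients = c(Age = 0.06, Cement = 0.11, `Blast Furnace Slag` = 0.09,
                          `Fly Ash` = 0.08, Water = -0.18,
                          Superplasticizer = 0.25, `Coarse Aggregate` = 0.015,
                          `Fine Aggregate` = 0.018),
    intercept = -20, noise_sd = 10, seed = seed
  )
}
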