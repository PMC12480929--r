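# Shared fixtures, built in code at test time.

# a two-set prior document aligned with the heart-like synthetic problem
heart_doc_fixture <- function() {
  vars <- c("age", "sex", "trestbps", "chol", "thalach", "oldpeak")
  mod_means <- c(0.05, 1.0, 0.02, 0.004, -0.03, 0.6)
  mod_sds <- c(0.02, 0.4, 0.01, 0.003, 0.012, 0.25)
  mk <- function(means, sds) {
    entries <- Map(function(m, s) prior_entry(m, s), means, sds)
    names(entries) <- vars
    entries
  }
  prior_document(
    "heart-disease",
    list(prior_set("Mod", "moderate", 0.6, mk(mod_means, mod_sds)),
         prior_set("Weak", "weak", 0.4, mk(mod_means * 0.8, mod_sds * 3))),
    provenance = "test fixture"
  )
}

# small seeded dataset for fitting tests
toy_dataset <- function(seed = 1, n = 200, p = 3,
                        family = c("logistic", "linear"),
                        beta = NULL, intercept = 0.2, noise_sd = 1) {
  family <- match.arg(family)
  if (is.null(beta)) beta <- seq(0.5, by = -0.3, length.out = p)
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    eta <- intercept + drop(X %*% beta)
    y <- if (family == "logistic") rbinom(n, 1, plogis(eta))
         else eta + rnorm(n, 0, noise_sd)
    regression_dataset(X, y)
  })
}

# flat/tight prior sets over a dataset's variables
uniform_prior_set <- function(data, mean = 0, sd = 1, label = "set",
                              informativeness = "custom", weight = 1) {
  entries <- lapply(data$variable_names, function(v) prior_entry(mean, sd))
  names(entries) <- data$variable_names
  prior_set(label, informativeness, weight, entries)
}

# independent numerical-quadrature oracle for the Gaussian KL integrand
quadrature_kl <- function(mle, prior) {
  f <- function(x) {
    dnorm(x, mle$mean, mle$sd) *
      (dnorm(x, mle$mean, mle$sd, log = TRUE) - dnorm(x, prior$mean, prior$sd, log = TRUE))
  }
  integrate(f, mle$mean - 12 * mle$sd, mle$mean + 12 * mle$sd,
            rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# hand-coded Benjamini-Hochberg step-up, used as the independent oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

shipped_kl_matrix <- function(which = c("heart", "concrete")) {
  which <- match.arg(which)
  read_kl_matrix(system.file("extdata", paste0("kl_reference_", which, ".tsv"),
                             package = "priorelicit", mustWork = TRUE))
}
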