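---
title: "Eliciting and auditing Gaussian regression priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eliciting and auditing Gaussian regression priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priorelicit)
```

## The problem

Bayesian regression lets pre-existing knowledge enter an analysis through
the prior, but writing an informative prior is hard: the knowledge is
scattered, and translating "males have roughly twice the odds" into a
coefficient-scale distribution invites mistakes. `priorelicit` treats a
large language model as a knowledge source to be *interrogated in a
structured way and then audited against the data*, never trusted blindly.
The package covers the full loop: prompt construction, a strict
machine-readable response contract, model fitting, prior–data agreement
scoring, posterior computation, prior predictive checks, and cross-validated
predictive comparison.

## The elicitation contract

`build_prompt()` assembles five sections — role/context, data description,
model statement, instructions, and a required output format — and is a pure
function of its inputs: identical problems give byte-identical prompts. The
instruction block demands per-hyperparameter justifications, cited sources,
at least two prior sets (moderately and weakly informative) with confidence
scores summing to one, and a final verification/reflection pass. The
response must contain exactly one fenced JSON block conforming to the schema
shipped at `prior_document_schema_path()`; free-prose answers are rejected
by design, because downstream analysis only consumes hyperparameter values
and prose parsing is a reliability trap.

Responses travel through a transport. The replay transport is a directory of
recorded responses keyed by prompt hash, fully deterministic and suitable
for tests and reproducible pipelines; a live transport wraps any
`send(text) -> text` function and surfaces failures without retry magic. The
bundled recordings are *synthetic stand-ins* for real transcripts: their
confidence weights (0.65/0.35 and 0.60/0.40) and the heart-disease sex prior
N(0.7, 0.3) match reported elicitation outcomes, and every other number in
them is flagged fixture-invented.

Priors are expressed on the natural covariate scale (log-odds per year, per
mmHg, per kg/m³). This matches how printed effect sizes are reported and is
what makes an elicited sex prior like N(0.7, 0.3) directly comparable to the
fitted coefficient. Covariates are therefore not standardized internally; a
user who wants standardized scales can transform the data before fitting.
Elicited sets never include an intercept prior: the intercept gets a wide
default, N(0, 10²) (`default_intercept_prior()`), is always estimated, and
is excluded from every KL report. Confidence weights are carried and
reported but deliberately not used in computation — mixing sets into a
single prior would change the model class, and the evidence for doing so is
thin; the weights are metadata about the source's self-assessment.

## Scoring priors against the data

The sampling distribution of the MLE ("the data distribution") is
approximated as Gaussian per coefficient, using the inverse observed Fisher
information at the estimate, or a case-resampling bootstrap
(`bootstrap_mle()`, which redraws failed resamples and aborts if more than
10% fail). Each prior is scored with the closed-form Gaussian
Kullback–Leibler divergence **with the MLE distribution as the reference
measure**:

$$\mathrm{KL}\big(\hat p_{\mathrm{MLE}} \,\|\, p\big) =
\log\frac{\sigma_p}{\sigma_m} +
\frac{\sigma_m^2 + (\mu_m - \mu_p)^2}{2\sigma_p^2} - \frac12 .$$

The orientation is the substantive choice: it integrates the surprise of the
prior in regions where the data concentrate, so a narrow prior far from the
estimate is penalized heavily while a merely wide prior pays only its
log-width. That asymmetry matches how practitioners reason about prior–data
conflict. (The reverse orientation would forgive overconfident priors —
exactly the failure mode this diagnostic exists to expose.) Marginal sds
come from the full-model covariance diagonal; between-coefficient
correlations are ignored, consistent with per-variable reporting.

`kl_table()` aggregates per-variable divergences into a variable × set
matrix with two footer rows: per-set column means, and average ranks
computed with the **minimum (competition) tie rule** — tied divergences all
receive the smallest rank of their block. The minimum rule is the only
standard tie rule that reproduces the reference rank rows this package
ships, which contain several exactly tied pairs.

Two numerical display choices matter for reproducing reference tables.
Internal values always carry full precision; `round_display()` rounds for
display by first snapping to eight decimals (stripping float-accumulation
noise so an exact decimal half is treated as one) and then rounding half to
even. Half-up rounding is *not* used: an average rank of 9/8 = 1.125 must
display as 1.12 to match the reference tables, which half-up cannot do. A
caveat discovered while validating: reference mean rows can contain exact
half-cases rounded in opposite directions (2.385 printed 2.38, 4.185 printed
4.19), proving they were computed from full-precision divergences rather
than the printed two-decimal entries; tests therefore compare recomputed
means to printed values within half a printed unit.

`prior_predictive_sample()` and `summarize_ppc()` provide the complementary
check on the data scale: draw coefficients from the prior, responses from
the likelihood at the observed design points, and compare observed summary
statistics (mean, sd, median, 10%/90% quantiles) to their simulated
distributions. The reported tail proportion is min(P(sim ≤ obs),
P(sim ≥ obs)): ≈ 0.5 when the observed statistic is typical, near 0 under
gross prior–data conflict.

## Posteriors

For linear models the Gaussian prior is conjugate given the residual
variance; the package plugs in $\hat\sigma^2 = \mathrm{RSS}/(n-p-1)$ from
the MLE fit, keeping the posterior exactly Gaussian and cheap (a hyperprior
on the residual precision is out of scope — at the sample sizes targeted
here it changes little, and plug-in keeps every posterior quantity
closed-form and testable). For logistic models the posterior is a Laplace
approximation: Newton maximization of log-likelihood plus log-prior, with
covariance the inverse negative Hessian at the mode — a standard, adequate
approximation at n in the hundreds, used here in place of heavier
integrated-nested-Laplace machinery.

Newton iterations (shared by the MLE fit and the Laplace mode search)
converge on a gradient max-norm of 1e-8 within 100 iterations, halving the
step up to 20 times when a step would decrease the objective. One numerical
guard: a Newton step below `1e-12 * (1 + |beta|)` also counts as converged,
because with extremely concentrated priors (sd near 1e-6, precision 1e12)
the 1e-8 gradient tolerance is unreachable in double precision — the
implied coefficient update underflows the resolution of the iterate itself.
Unpenalized logistic fits additionally watch for complete or
quasi-separation (a diverging linear predictor with a stalled gradient) and
fail naming the suspect variables rather than returning garbage. Degenerate
exact-fit linear data (zero residual variance) is flagged and returns a
degenerate covariance with a warning.

## Predictive comparison

`kfold_cv()` evaluates all models on one shared fold partition (stratified
by class for binary responses, so every fold holds both classes and AUC is
always defined; per-class fold counts differ by at most one). Bayesian
models predict with plug-in posterior-mode coefficients; full
posterior-predictive averaging changes little at these sample sizes and is
deliberately not the default. Linear predictive densities for the log score
use variance $\hat\sigma^2 + x^\top \Sigma x$.

`compare_models()` forms per-fold improvements over the baseline (oriented
per metric: lower-is-better metrics are differenced baseline − model) and
applies the Nadeau–Bengio corrected t-test,

$$t = \frac{\bar d}{\sqrt{\left(\tfrac1K + \tfrac{n_{\text{test}}}{n_{\text{train}}}\right) s_d^2}},
\qquad df = K - 1,$$

one-sided in the improvement direction, with fold sizes averaged when folds
are unequal and df = K − 1 (the standard choice for the K-fold variant).
All raw p-values of one experiment are adjusted jointly with
Benjamini–Hochberg — e.g. 18 tests when six prior sets are compared on
three metrics.

Calibration of this test deserves honesty. The correction replaces the naive
1/K variance factor with 1/K + n_test/n_train to compensate for training-set
overlap; it is built for fold-difference vectors whose pairwise correlation
is about n_test/n_train. Simulating exactly that null (compound-symmetric
Gaussian differences, K = 5, ρ = 1/4) gives a rejection rate near 6% at the
5% level — approximately calibrated, slightly liberal through the
$s_d^2$-underestimation and t-tail interplay. Under *realistic* k-fold CV
nulls (two equally irrelevant feature sets, measured over many seeded
repetitions) the test is conservative, rejecting well below nominal — the
price the correction pays to kill the naive test's optimism. The test suite
pins both behaviours: near-nominal rejection under the assumed correlation
structure, conservatism under an actual CV null.

## The synthetic generators

`heart_like_spec()` and `concrete_like_spec()` reproduce the *shape* of the
two case studies: six covariates with the heart-study names and unit scales
feeding a logistic response calibrated by monotone root-finding to 46%
expected prevalence over the drawn design (matching the cohort's reported
prevalence) at n = 303; eight concrete-mixture covariates feeding a linear
response with noise sd 10 (an RMSE-like scale in MPa) at n = 1030. Marginal
parameters (age ~ N(54, 9²), sex ~ Bernoulli(0.68), …) and generating
coefficients are fixture-invented plausible values chosen once, flagged as
such in code and documentation. Covariates are drawn independently — no
empirical copula, no missingness, no non-linear age effect. Passing tests on
these generators therefore validate the *evaluation machinery* (fitting, KL
scoring, ranking, CV testing), not claims about the real datasets; anyone
auditing real elicited priors should run the same functions on the real
data. All randomness flows from a single integer seed; identical seeds give
byte-identical datasets.

Problem sizes used in the shipped tests were likewise chosen once: 100
seeded parameter pairs for the KL-vs-quadrature check, 1000 simulations for
the 90% interval-coverage check (60 × 3 linear-Gaussian problems with
coefficients drawn from the prior; conjugate posteriors with the true noise
variance make 90% the exact target), and 5000 draws for the corrected-test
calibration check (enough to make its Monte-Carlo sd ≈ 0.3 percentage
points).

## Known limitations

- Gaussian priors only; no mixtures, no heavy tails, no use of confidence
  weights in computation.
- Plug-in residual variance and plug-in predictive coefficients; no MCMC,
  no hierarchical variance priors, no generalized families beyond
  logistic/linear.
- KL scoring is per-marginal; joint (correlated) prior–data conflict is not
  measured.
- The replay transport only answers prompts it has recorded (keyed by
  prompt hash), so editing prompt wording invalidates recorded fixtures by
  design.
- How a real study binarized its outcome or transformed covariates is an
  input decision; the package exposes the choices but cannot certify
  someone else's.
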