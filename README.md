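# priorelicit

Formulating informative prior distributions for Bayesian regression is
resource-demanding and hard to do objectively: the relevant knowledge is
scattered across studies, registries and textbooks, and translating it onto
the coefficient scale is error-prone. `priorelicit` implements a structured
workflow for eliciting Gaussian coefficient priors from large language
models and — crucially — for *auditing* how well the elicited priors agree
with observed data before trusting them.

It is aimed at applied statisticians and epidemiologists fitting logistic or
linear regressions who want informative priors with a quantified
prior–data-conflict check, and at methodologists studying what language
models actually know about effect sizes.

## What it computes

**Model.** For data $\mathcal{D}$ with coefficients
$\theta = (\theta_0, \theta_1, \dots, \theta_p)$, the posterior is

$$p(\theta \mid \mathcal{D}) \propto p(\mathcal{D} \mid \theta)\, p(\theta),$$

with an independent Gaussian prior $\theta_j \sim N(\mu_j, \sigma_j^2)$ per
coefficient on the **natural covariate scale** (log-odds per year, per mmHg,
…). Posteriors are Gaussian approximations: a Laplace approximation for
logistic models, the exact conjugate closed form (with plug-in residual
variance $\hat\sigma^2 = \mathrm{RSS}/(n-p-1)$) for linear models.

**Prior–data agreement.** The sampling distribution of the maximum
likelihood estimator is approximated as Gaussian,
$\hat p_{\mathrm{MLE}}(\theta_j) = N(\hat\theta_j, \widehat{se}_j^2)$ (inverse
observed Fisher information, or a case-resampling bootstrap). Each prior is
scored by the Kullback–Leibler divergence with the MLE distribution as
reference measure,

$$\mathrm{KL} = \int \hat p_{\mathrm{MLE}}(\theta)\,
\log \frac{\hat p_{\mathrm{MLE}}(\theta)}{p(\theta)}\, d\theta
= \log\frac{\sigma_p}{\sigma_m} +
\frac{\sigma_m^2 + (\mu_m-\mu_p)^2}{2\sigma_p^2} - \frac12,$$

which is large exactly when the prior puts little mass where the data say
the coefficient lives. Per-variable divergences are aggregated into tables
with per-set means and tie-aware (minimum-rank) average ranks.

**Predictive comparison.** Prior sets are compared against the plain
frequentist fit by K-fold cross-validation (Brier score, mean negative log
score and AUC for classification; MNLS, RMSE, MAE for regression), with
one-sided Nadeau–Bengio corrected t-tests on the fold differences and
Benjamini–Hochberg adjustment across all model × metric tests.

## Worked example

```r
library(priorelicit)

# a synthetic heart-disease-shaped study and its MLE distribution
data <- generate(heart_like_spec(seed = 1))
mle  <- fit_mle(data, "logistic")

# elicit priors: build the structured prompt, replay a recorded transcript
prompt <- build_prompt(heart_disease_problem(),
                       elicitation_options(provider = "claude-opus"))
doc <- extract_prior_document(elicit(prompt, replay_transport(bundled_replay_dir())))
doc <- align_to_problem(doc, heart_disease_problem())

# score the prior sets against the data
kl_table(mle, doc)
```

```
<kl_report> 6 variable(s) x 2 prior set(s)
            Claude_Mod Claude_Weak
age               0.03        0.84
sex               0.20        0.56
trestbps          0.07        0.89
chol              0.48        0.85
thalach           0.34        1.38
oldpeak           1.00        1.28
Avg KL Div.       0.36        0.97
Avg Rank          1.00        2.00
```

Each cell is the KL divergence (nats) from the fitted coefficient's MLE
distribution to that set's prior: near 0 means the prior already agrees with
the data; values of about 1 or more signal meaningful prior–data conflict.
The footer rows are the per-set mean divergence and the average
(minimum-rank) placement across variables — here the moderately informative
set wins every variable, as expected since the replayed transcript's priors
point in the generating directions.

`or_to_log_odds(2)` returns `0.6931…` (≈ 0.7), the log-odds step used when a
transcript reasons in odds ratios. `laplace_posterior(data, "logistic",
doc$sets[[1]])` then yields the posterior mode and covariance, and
`plot_overlay_grid(mle, doc$sets[[1]], posterior = ...)` draws the
prior/MLE/posterior overlays. `kfold_cv()` + `compare_models()` run the
predictive comparison. A thin CLI over the same functions ships in
`inst/cli/priorelicit` (subcommands `elicit-prompt`, `parse-response`,
`evaluate-priors`, `fit-posterior`, `compare`, `simulate`).

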