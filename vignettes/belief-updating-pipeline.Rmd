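---
title: "Modelling belief priors and belief updating: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling belief priors and belief updating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beliefsim)
```

## The problem

In self-referential feedback tasks, a participant repeatedly reports the
probability of a binary proposition about themselves (here: "I am in the
more popular half of my peers") while receiving a sequence of binary
feedback events. Two distinct mechanisms can produce negatively skewed
reports: a negative *prior* belief held before any feedback, and a
*negatively biased update* that weighs bad news more than good news.
`beliefsim` implements a modelling pipeline that separates the two and
relates them to orthogonal latent dimensions of internalizing
symptomatology (general negative affect, anxiety-specific, and
depression-specific affect).

## The observation architecture

All models represent the belief on trial $t$ as a Beta distribution
$B(\alpha_t, \beta_t)$, and each probability report $\hat q_t$ is a single
sample from the current belief:

$$\hat q_t \sim B(\alpha_t, \beta_t), \qquad t = 0, 1, \dots, 20.$$

This gives report variability for free: confident participants (large
$\alpha_t + \beta_t$) report tightly, uncertain ones noisily. Four update
rules are registered:

| id | name | update | free parameters |
|----|------|--------|-----------------|
| 1 | biased Bayesian | $\alpha_t = \alpha_{t-1} + \omega X_t$; $\beta_t = \beta_{t-1} + \tfrac1\omega (1 - X_t)$ | $\alpha_0 \in [2,100]$, $\beta_0 \in [2,100]$, $\omega \in [0,5]$ |
| 2 | Bayesian | model 1 with $\omega = 1$ | $\alpha_0, \beta_0$ |
| 3 | biased RW | $\mu_t = \min(\mu_{t-1} + \eta(bX_t - \mu_{t-1}),\, 1)$, $\alpha_t = \nu\mu_t$, $\beta_t = \nu(1-\mu_t)$ | $\mu_0 \in [0,1]$, $\nu \in [2,1000]$, $\eta \in [0,1]$, $b \in [0,5]$ |
| 4 | RW | model 3 with $b = 1$ | $\mu_0, \nu, \eta$ |

$X_t \in \{0,1\}$ is the feedback event. In the Rescorla–Wagner (RW)
models precision is constant ($\alpha_t + \beta_t = \nu$ on every trial),
so update sizes do not shrink over time, whereas Bayesian evidence
accumulation makes later updates progressively smaller. The bias
parameters act multiplicatively: $b > 1$ (or $\omega > 1$) weighs positive
feedback more heavily, $b < 1$ less.

### Numerical choices

* **Report boundaries.** A slider report of exactly 0 or 1 has zero or
  infinite Beta density. Reports are clipped into
  $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-4}$
  (configurable) before density evaluation, so the log-likelihood is
  always finite. The slider's true granularity is unknown; $10^{-4}$ is
  far below any plausible step size.
* **Degenerate RW mean.** The clamp in the RW rule can drive $\mu_t$ to
  exactly 1 (and constant negative feedback can approach 0), where
  $\beta_t = 0$ is not a valid Beta parameter. The *dynamics* follow the
  update rule exactly; only for density evaluation and sampling is
  $\mu_t$ clipped into $[\varepsilon, 1-\varepsilon]$.
* **$\omega$'s lower bound.** The documented range $[0, 5]$ includes
  $\omega = 0$, where the negative-feedback increment $1/\omega$ is
  undefined. The optimiser's box therefore starts at $10^{-3}$.
* **Framing.** Runs elicited under the "bottom half" framing are flipped
  ($q \to 1-q$) at CSV ingest so that all modelling happens on one
  canonical scale; the writer inverts the flip, so files round-trip.
* **The $t=0$ report.** All 21 reports (the pre-feedback one included)
  enter the likelihood, since the prior state is as much a Beta belief as
  any later state. The BIC penalty nevertheless uses $n = 20$ by default,
  matching the reporting convention for this task; `bic(n =)` makes the
  choice explicit and configurable. Model *ordering* is insensitive to
  this choice whenever competing models see the same $n$.

## Fitting

Each participant × referent run is fitted independently by maximum a
posteriori (MAP) estimation: bounded L-BFGS-B on the log posterior, with
the documented priors — $\alpha_0, \beta_0 \sim \text{HalfNormal}(50)$,
$\omega \sim N(1, 0.5)$, $\mu_0 \sim N(0.5, 0.5)$,
$\nu \sim \text{HalfNormal}(500)$, $\eta \sim \text{HalfNormal}(0.5)$,
$b \sim \text{HalfNormal}(2)$ — evaluated in their untruncated form and
the ranges enforced as hard box constraints. Truncation renormalisation
is omitted deliberately: inside the box it adds a constant and cannot
move the mode. Optimisation restarts from one fixed bounds-midpoint start
plus `n_restarts` draws from the (bound-truncated) priors; ties are broken
by the lexicographically smallest parameter vector so fits are
deterministic given a seed. Fits at a bound are flagged (`at_bound`).
The fit's correctness contract is agreement with a dense grid-search
argmax, which the test suite enforces on 2- and 3-parameter toys.

## Model comparison

Log model evidence is approximated by $-\mathrm{BIC}/2$. Population-level
comparison uses a random-effects scheme: model frequencies $r$ get a
Dirichlet prior (pseudo-count $\alpha_0 = 1$ per model, the conventional
default; the method's settings are otherwise unreported, so tolerance
$10^{-6}$ and $10^5$ Monte-Carlo draws are package choices), participant
assignments are integrated out variationally, and the *exceedance
probability* of a model — the posterior probability that it is the most
prevalent — is the Monte-Carlo argmax frequency over Dirichlet draws.
The implementation is validated against brute-force numerical integration
of the exact posterior in the two-model case.

Two diagnostics close the loop:

* `model_recovery()` simulates runs from each model and tallies which
  model wins on BIC (a confusion matrix with rows summing to 100%).
* `posterior_predictive_updates()` simulates replicate runs at the MAP
  and compares the distribution of trial-to-trial report changes after
  positive and negative feedback with the observed one
  (two-sample Kolmogorov–Smirnov).

### A structural note on recoverability

With parameters drawn from the truncated MAP priors, the biased Bayesian
model's row of the confusion matrix is *not* dominated by its diagonal:
the $\omega \sim N(1, 0.5)$ prior concentrates draws near the unbiased
value, where models 1 and 2 are nested and the BIC penalty
($\log 20 \approx 3$) correctly awards the simpler model. Parameter
sweeps show model 1 is recovered reliably once $\omega \lesssim 0.5$ or
$\gtrsim 2$, or when prior counts are small — so this is a property of
the simulation design, not of the fitting machinery, and estimate-informed
samplers inherit it whenever fitted biases cluster near 1. The biased RW
model, the substantive winner, is distinguishable from all three
alternatives. The acceptance suite keeps the strict all-diagonals
criterion and leaves the model-1 row visibly red rather than switching to
a sampler chosen to pass.

## The synthetic cohort

`sample_cohort()` generates the world the downstream statistics assume,
so the whole pipeline is testable without any data download. Defaults are
chosen once, from the cohort the pipeline targets, and are not tuned:

* **n = 66** analysed participants; two counterbalanced length-20
  feedback sequences with 10 positive / 10 negative events each. The real
  sequences are unpublished beyond their constraints (positive-first
  begins 1,1; six positives among the first ten trials; the other
  sequence is the complement), so one canonical pair satisfying every
  constraint is fixed for bit-stable tests.
* **Latent structure.** Three orthogonal factor scores and the
  unconstrained parameter scales (logit $\mu_0$, log $b$) are drawn from
  one Gaussian copula planting: depression ↔ logit $\mu_0$ at $-0.33$,
  anxiety ↔ log $b$ at $-0.32$, the confirmation-bias coupling
  $\mathrm{cor}(\text{logit}\,\mu_0, \log b) = 0.5$, and a weak
  depression ↔ popularity association of $-0.17$ with popularity
  essentially uncorrelated with $\mu_0$ (the "poor insight" structure).
  An infeasible (non-positive-definite) combination raises a config
  error.
* **Parameter scales.** $\mu_0$ centred at 0.5 (logit SD 0.9), $b$ at 1
  (log SD 0.4, matching the observed SD ≈ 0.44), $\eta$ at 0.098, $\nu$
  at 320 — the population values reported for this task. Other-referent
  runs get independent draws with mildly optimistic means
  ($\mu_0 \approx 0.55$, $b \approx 1.16$) and no planted factor effects,
  since none were observed for other-referent judgements.
* **Careless responders** (default 4%) report a feedback-blind clipped
  random walk, guaranteeing directional errors for the exclusion filter
  to catch.
* **Item responses.** A fixed synthetic 95 × 3 bifactor loadings matrix
  (all items load 0.3–0.6 on the general factor; worry items 0.4–0.7 on
  the anxiety-specific factor, anhedonia items on the depression-specific
  factor) generates Likert responses through the linear factor model with
  uniqueness-consistent noise. It is a labelled stand-in: real loadings
  can be supplied through the same CSV interface.

What the generator does *not* emulate: primacy effects, drifting
attention, response anchoring, item-level non-normality beyond Likert
discretisation, and any session-level dynamics. A green end-to-end test
therefore establishes that the pipeline detects the planted structure
under the model's own assumptions — not that the model is true of people.
One concrete consequence: under delta-rule recency weighting, runs
receiving the positive-first sequence (six of its ten positives in the
first half) end *lower* than negative-first runs, whereas real
participants have been observed to do the opposite; the generator
reproduces the model-implied direction.

## Factor scores

`anderson_rubin_scores()` computes Anderson–Rubin scores from a fixed
loadings matrix $\Lambda$: items are z-scored (with the current sample's
moments — whether the original analysis used reference-sample moments is
unknowable, and in-sample standardisation keeps the estimator
self-contained), $\Psi = \mathrm{diag}(1 - \mathrm{diag}(\Lambda\Lambda^\top))$, and

$$W = \Psi^{-1}\Lambda\,(\Lambda^\top\Psi^{-1} R\,\Psi^{-1}\Lambda)^{-1/2},
\qquad S = Z W,$$

with $R$ the sample item correlation matrix and the symmetric
(eigendecomposition) inverse square root. Because the sample $R$ sits
inside the whitening term, $\mathrm{cov}(S) = I$ holds *exactly*
in-sample — the orthogonality-preservation that motivates the estimator.
The exact variant inside any particular software routine is not
reproducible bit-for-bit; the contract here is the orthogonality
invariant, plus invariance checks (reduced item subsets and repeated
administrations, concatenated or averaged, give near-identical scores).
Items missing from a battery are handled by row-subsetting $\Lambda$.

## Downstream statistics

* **Exclusions.** A directional error is a report moving strictly against
  the feedback just received; leaving the report unchanged is rational
  and not an error. Nine or more errors excludes the run.
* **Permutation correlations.** Pearson $r$ with a two-tailed permutation
  test (default 10,000 samples). The p-value uses the add-one correction
  $p = (1 + \#\{|r^\ast| \ge |r|\})/(n_{\text{perm}} + 1)$, which avoids
  $p = 0$ and differs from the raw proportion by $\le 10^{-4}$ at the
  default sample count; for $n \le 7$ full enumeration is available and
  exact. Multiplicity over the 12-test family (3 factors × 4 model-3
  parameters) is controlled by Benjamini–Hochberg.
* **Joint regressions.** Per factor, OLS of the factor score on $\mu_0$
  and $b$ together; the difference of a coefficient between two factors'
  models is referred to a null built by permuting whole factor-score rows
  against parameter rows — jointly, so the $\mu_0$–$b$ dependence is
  preserved under the null. The $\mu_0 \times b$ interaction is assessed
  by a likelihood-ratio test of the nested linear models.
* **Mediation.** A linear product-of-coefficients ACME with a
  nonparametric percentile bootstrap, reporting direct and total effects
  (which decompose exactly in the linear case). This deliberately
  substitutes for heavier quasi-Bayesian mediation machinery; the two
  agree in the linear setting, which is the only one exercised here.

## Known limitations

* Only the four main models ship; the registry accepts further models
  (`register_model()`) but none are defined.
* No hierarchical shrinkage across participants and no full posterior
  sampling; MAP per run is the estimation contract.
* The mediation module is linear-only by design.
* Real-cohort headline numbers (specific exceedance probabilities,
  specific $r$ values) are not reproducible without the original raw
  data; the pipeline's tests assert the *structure* those numbers
  exhibit, on synthetic cohorts where the truth is known.
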