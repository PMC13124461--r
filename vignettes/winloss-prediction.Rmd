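---
title: "Predicting win-loss probabilities for prioritized composite outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting win-loss probabilities for prioritized composite outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Composite time-to-event endpoints that prioritize death over a nonfatal
event (say, hospitalization) are often analysed through pairwise
comparisons: subject $i$ *wins* against subject $j$ by time $t$ if $i$
survives $j$'s death within their shared follow-up window, or, if neither
dies in the window, if $j$ experiences the first nonfatal event earlier.
The *win ratio* summarizes such comparisons on a relative scale, but a
ratio alone hides the third outcome — the *tie*, in which neither subject
has any event — and therefore says nothing about the absolute size of the
win and loss probabilities, which shrink as event rates fall and ties
accumulate. A 20% vs 10% contrast and a 0.2% vs 0.1% contrast have the
same win ratio and very different clinical content.

`winpred` couples two parsimonious regression models to recover the full
trinomial:

1. **The proportional win-fractions (PW) model.** For covariate vectors
   $Z_i$, $Z_j$, the win and loss probabilities are assumed proportional
   over time with
   $$ \frac{w(t \mid Z_i, Z_j)}{w(t \mid Z_j, Z_i)} = \exp\{\beta^\top (Z_i - Z_j)\}, $$
   so each coefficient is a log win ratio per unit covariate. $\beta$ is
   estimated by solving the U-statistic estimating equation
   $\sum_{i<j} (Z_i - Z_j) M_{ij}(\infty; \beta) = 0$, where
   $M_{ij} = \delta_{ij} - R_{ij}\,\mu(Z_i, Z_j; \beta)$ is the pairwise
   win residual built from the observed win indicator $\delta_{ij}$, the
   comparability indicator $R_{ij} = \delta_{ij} + \delta_{ji}$, and the
   model win probability
   $\mu = \operatorname{expit}\{\beta^\top(Z_i - Z_j)\}$.

2. **A Cox model for the time to first event (TFE).** A tie at $t$ means
   both subjects are free of *any* component event, so the tie
   probability factorizes into TFE survival functions,
   $\nu(t \mid z, z^*) = S(t \mid z)\, S(t \mid z^*)$. We model
   $S(t \mid z) = \exp\{-e^{\gamma^\top z} \Lambda_0(t)\}$ with the
   partial-likelihood estimate of $\gamma$ and the Breslow baseline.

Combining the two,
$$ \hat w(t \mid z, z^*) = \{1 - \hat S(t \mid z) \hat S(t \mid z^*)\}\,
   \operatorname{expit}\{\hat\beta^\top (z - z^*)\}, $$
with the loss probability obtained by exchanging $z$ and $z^*$. The
construction enforces $w + l + \nu = 1$ exactly and a time-constant
$\hat w/\hat l$ equal to the model win ratio.

## Uncertainty quantification

The delicate part is the standard error: $\hat w$ mixes parameters from
two different models fitted to overlapping aspects of the same data. We
use the estimated influence-function expansion of $\hat w(t \mid z, z^*)$.
Each subject contributes

* a Cox-model term, which propagates the subject's partial-likelihood
  score integral $\int \{Z_i - \hat{\mathcal E}(u)\}\, d\hat M_i(u)$ and
  Breslow-baseline integral $\int_0^t \hat s^{(0)}(u)^{-1} d\hat M_i(u)$
  through the gradient of the tie probability (the weights involve
  $\hat H(t;z) = e^{\hat\gamma^\top z}\int_0^t \{z - \hat{\mathcal E}(u)\}\,
  d\hat\Lambda_0(u)$ and the inverse information matrix), and
* a PW-model term,
  $-2 \hat w (1 - \hat\mu)(z - z^*)^\top \hat A^{-1} \hat\kappa_i$, where
  $\hat A$ is the (negative semidefinite) limiting Jacobian of the
  estimating function and
  $\hat\kappa_i = (n-1)^{-1} \sum_{j \ne i} (Z_i - Z_j) M_{ij}$.

The pointwise variance is the empirical second moment of these
contributions, $n^{-2} \sum_i \widehat{\mathrm{IF}}_i^2$ — the standard
robust plug-in, with no finite-sample degrees-of-freedom correction. The
same contributions, computed for the win and the loss probability, give
the win-loss covariance needed for contrasts. We validate this estimator
two ways in the test suite: against the empirical standard deviation over
simulation replicates, and against a nonparametric bootstrap on a single
dataset.

Confidence intervals are transformed to respect ranges: logit for
probabilities, $\operatorname{arctanh}$ for the net benefit
$\mathrm{NB} = w - l \in [-1, 1]$, and
$\mathrm{WO} = (1 + \mathrm{NB})/(1 - \mathrm{NB})$ inherits
$\exp\{2 \cdot \operatorname{arctanh}\ \text{interval}\}$, so the NB and
WO intervals are monotone images of each other and cover jointly. The win
ratio itself uses a lognormal interval from the sandwich variance of
$\hat\beta$, $(4/n)\, \hat A^{-1} \{n^{-1} \sum_i \hat\kappa_i
\hat\kappa_i^\top\} \hat A^{-1}$.

## A worked example

```{r, eval = FALSE}
library(winpred)

cfg <- sim_config(n = 500)
cohort <- simulate_cohort(cfg, seed = 11)
pw <- fit_pw(cohort)
cox <- fit_cox_tfe(cohort)
curve <- predict_winloss(pw, cox, z = c(1, 0, 0), z_star = c(0, 0, 0),
                         times = c(0.1, 0.5, 1, 2, 4))
curve
contrast_curves(curve)
```

## Tunable parameters and conventions

* **Win rule.** Death is compared first over the *shared* window
  $[0,\ t \wedge X_i \wedge X_j]$; the window is closed (an event at
  exactly the boundary counts) because a decedent's follow-up ends at the
  death time, which always sits on the boundary — with an open window no
  death could ever produce a win. Exact ties in the deciding event time
  (both die, or both have their first nonfatal event, at the same
  instant) are mutual ties; event times are ideally continuous, and this
  convention degrades gracefully on discrete data. Only the first
  nonfatal event enters the rule; later recurrences are stored but
  unused.
* **Estimation.** Newton-Raphson from $\beta = 0$ with the exact
  Jacobian; the score is the gradient of a concave pairwise
  pseudo-likelihood, so this is globally stable. Convergence is declared
  when the per-pair-normalized score max-norm falls below `1e-8`
  (default), followed by one polishing step so the estimating-equation
  identities hold to near machine precision; 50 iterations maximum.
  Evaluation at "$t = \infty$" means no time cap: all observed events up
  to the maximum follow-up count.
* **Cox side.** Breslow tie handling throughout, for internal consistency
  with the Breslow baseline inside the influence terms (Efron weights are
  deliberately not offered). A subject with TFE time $u$ is in the risk
  set at $u$. The point estimate of $\gamma$ comes from
  `survival::coxph()`; all risk-set aggregates, the baseline, and the
  residual integrals are recomputed internally at the observed event
  times.
* **Prediction grid.** Defaults to the observed TFE event times. Beyond
  the last observed time the baseline is carried forward and the output
  flagged `extrapolated`. Probabilities of exactly 0 or 1 make the logit
  (or arctanh) transform degenerate; those rows keep the point estimate,
  collapse the interval, and are flagged `degenerate`.
* **Stratification.** Pairs from different strata are treated as
  non-comparable, which reduces the stratified PW score, $\hat A$,
  $\hat\kappa$ and sandwich to the unstratified formulas restricted to
  within-stratum pairs; $\beta$ and $\gamma$ are shared while baselines
  are stratum-specific. For prediction variance, each subject's
  martingale-type integrals use its own stratum's baseline and risk sets,
  with a stratum-size rescaling $n/n_l$ on the Breslow part so the
  stratum-local Breslow influence aggregates correctly; only the
  requested stratum's baseline enters the tie-probability gradient. This
  stratified variance should be considered experimental — it is
  corroborated by a stratified bootstrap in the test suite rather than by
  a printed derivation.

## Model diagnostics

`subject_win_residuals()` returns
$\hat M_i = (n-1)^{-1}\sum_{j\neq i} M_{ij}(\infty;\hat\beta)$, the
observed minus model-predicted win proportion per subject; plotted
against a quantitative covariate it reveals misspecified functional
forms (a ceiling effect fitted linearly drags the residuals negative
beyond the plateau). `score_process()` returns
$\hat U(t) = \binom{n}{2}^{-1} \sum_{i<j}(Z_i - Z_j) M_{ij}(t;\hat\beta)$,
anchored at zero at $t = 0$ and at the maximum follow-up; a systematic
excursion indicates a time-varying win ratio, i.e. a violation of the
proportionality assumption. The standardized version divides each raw
component by $\{\sum_{i<j}(Z_i - Z_j)_k^2 M_{ij}(\infty)^2\}^{1/2}$; this
scaling is a pragmatic choice for visual trend detection — it is not a
pivotal standardization, so the plots support qualitative reading only,
and all formal invariants are stated on the unstandardized process.
`schoenfeld_residuals()` and `martingale_residuals()` provide the
matching checks for the Cox TFE model.

## The simulation design

`sim_config()` encodes a Gumbel-Hougaard copula design: given
$Z_1 \sim N(0,1)$, $Z_2 \sim N(-1,1)$, $Z_3 \sim \mathrm{Bernoulli}(0.5)$,
$$ \Pr(D > s, T > t \mid Z) = \exp\left[ -\left\{
   (e^{-\beta_D^\top Z} \lambda_D s)^\kappa +
   (e^{-\beta_T^\top Z} \lambda_H t)^\kappa \right\}^{1/\kappa} \right], $$
sampled exactly through the positive-stable shared-frailty
representation (Kanter / Chambers-Mallows-Stuck; a stable variate with
index $1/\kappa$ shared by both margins), which we prefer over
conditional-CDF inversion for exactness and speed. With
$\beta_D = \beta_T = \beta$ the design satisfies the PW model with
parameter $\beta$ *and* the Cox TFE model with $\gamma = -\beta$ and
$\Lambda_0(t) = (\lambda_D^\kappa + \lambda_H^\kappa)^{1/\kappa} t$, so
every true win-loss quantity has a closed form
(`true_win_prob()`); Kendall's $\tau$ between $D$ and $T$ is
$1 - 1/\kappa$. The defaults — $\beta = (0.5, 0, -0.5)$,
$\lambda_D = 0.1$, $\lambda_H = 1$, $\kappa = 2$, censoring
$C \sim \mathrm{Unif}[0.2, 4] \wedge \mathrm{Exp}(0.02)$, maximum
follow-up $\tau = 4$ — give roughly a 25% death rate and a 75%
nonfatal-event rate. Setting the death coefficient of $Z_1$ to 0.5 but
the nonfatal coefficient to 0.1 produces the misspecified variant in
which the true win ratio increases over time; there `true_win_prob()`
refuses (no closed form) and the Monte-Carlo oracle
`mc_true_win_prob()` — independent uncensored outcome pairs pushed
through the win rule directly — takes its place.

Nonfatal events occurring after death are never recorded: death
terminates follow-up (the semi-competing-risks convention implied by the
prioritized win rule). A subject's first covariate draw is reused for
both margins, and each replicate of `operating_characteristics()` is
driven by an independent sub-seed spawned from the master seed, so any
replicate can be reproduced in isolation.

## What the simulator does and does not emulate

The generator produces proportional win fractions and proportional TFE
hazards *by construction*. Passing recovery and coverage tests under it
therefore demonstrates correctness of the estimators and their variance
under the models' assumptions — not robustness to real-data features such
as covariate-dependent censoring, discrete or clustered event times,
time-varying covariates, or multiple nonfatal event layers, none of which
the generator produces. The misspecification scenario probes exactly one
departure (a time-varying win ratio) and shows visible bias in the
predicted curves; the residual tools exist to detect such departures in
practice before the predictions are trusted.

## Problem sizes used in the checks

The packaged statistical checks run a 500-replicate study at $n = 200$
(with the first 200 replicates reused for the parameter-recovery check),
a 500-draw nonparametric bootstrap on one $n = 200$ dataset, and
Monte-Carlo oracles of $10^5$ draws; these sizes give binomial /
Monte-Carlo error small enough to resolve the reference values while
keeping a full test run in the low minutes. The reference tables' own
2000-replicate design is available by calling
`operating_characteristics()` with `reps = 2000`.

## Known limitations

* Influence-function variances are implemented for the Cox TFE model
  only; any other survival provider would need its own
  influence-function derivation (the point-prediction formula itself
  only needs a survival function).
* One nonfatal event layer; no left truncation, interval censoring, or
  time-varying covariates; subjects with zero follow-up are rejected.
* Pairwise tables are materialized ($O(n^2)$ memory in the number of
  pairs); cohorts up to a few thousand subjects are comfortable, far
  beyond that a streaming implementation would be needed.
* No uniform-in-time confidence bands; intervals are pointwise.
* No formal goodness-of-fit p-value accompanies the score process; it is
  a graphical diagnostic.
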