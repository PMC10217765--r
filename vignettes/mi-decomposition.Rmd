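---
title: "Mutual information decomposition for contingency table modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutual information decomposition for contingency table modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midecomp)
library(dplyr)
```

## The model

`midecomp` analyses multi-way contingency tables of categorical variables
under the multinomial sampling model: with cell counts $n$ over the joint
levels of factors and total $N$, the plug-in cell probabilities are
$\hat f = n / N$. All association measures are reported on the
$2N\hat I$ scale — the likelihood-ratio ($G^2$) statistic, in natural
logarithms — so that every quantity printed by the package is directly a
chi-square test statistic.

The central tool is the orthogonal *mutual information identity*. For a
three-way table $(X, Y, Z)$,

$$I(X, Y, Z) \;=\; I(X, Z) + I(Y, Z) + I(X, Y \mid Z),$$

and more generally, for a target $T$ and predictors $X_1, \dots, X_m$,

$$I(\{X_1 \dots X_m\}, T) \;=\; I(X_1, T) + I(X_2, T \mid X_1) + \cdots
  + I(X_m, T \mid X_1, \dots, X_{m-1}).$$

Because the plug-in estimators satisfy these identities *exactly*, the
components returned by `chain_decompose()` sum to the joint statistic to
machine precision, and their degrees of freedom sum to the joint df. The
asymptotic reference distribution of a (C)MI term with nominal level
counts $I$, $J$ and conditioning cells $K$ is chi-square with
$(I-1)(J-1)K$ df.

Each conditional term obeys a Pythagorean law,

$$I(X, Y \mid Z) \;=\; \mathrm{Int}(X, Y, Z) + \mathrm{Par}(X, Y \mid Z),$$

splitting the conditional-independence statistic into the *interaction*
(heterogeneity of the $X$–$Y$ association across the strata of $Z$;
estimated by `pythagorean_split()` as the deviance of the
no-three-factor-interaction model, fitted by iterative proportional
fitting) and the *partial association* (the homogeneous component,
obtained by subtraction). The corresponding two-step likelihood-ratio
test runs the interaction test at size $\alpha_1$ and the partial test at
size $\alpha_2$ with the exact size identity
$\alpha = \alpha_1 + \alpha_2 - \alpha_1\alpha_2$; `alpha_split()`
defaults to the equal solution $\alpha_1 = \alpha_2 = 1 - \sqrt{1-\alpha}$
because no canonical unequal split exists, and both are configurable.

## Parameters that matter

* **`alpha`** (default 0.05): the overall size used for entering and
  keeping predictors, and the validity threshold for model deviances
  (a model is *valid* when its deviance p-value is at least `alpha`).
* **`alpha1`, `alpha2`**: the split sizes for the Int/Par sub-tests;
  default is the equal split of `alpha` (≈ 0.0253 each at 0.05).
* **IPF controls**: tolerance `1e-8` on the maximum margin discrepancy
  (relative to the observed margin, floored at 1) and 1000 cycles.
  Non-convergence is always flagged, never silent. The cycle order is
  the generator declaration order, so fits are deterministic.
* **Degrees of freedom** use *nominal* level counts everywhere — empty
  strata and sampling zeros do not shrink the df. This is the convention
  that matches standard log-linear practice for tables specified by
  their level sets; `df_observed = TRUE` (for CMI terms) and
  `class_count = "populated"` (for grouped logistic deviances) give the
  support-adjusted alternative for sparse tables.

## Variable selection and model construction

`mi_select()` chains four steps:

1. **Forward selection.** The first predictor maximizes the MI ratio
   (MIR = statistic / df) among candidates whose MI with the target is
   significant at `alpha`; later steps score each unselected candidate
   by its CMI given the current set, stopping when none is significant.
   The default criterion is minimum p-value (it handles unequal dfs more
   gracefully than the raw ratio); `criterion = "mir"` scores by the
   joint-MI ratio instead. Ties break deterministically by
   (smaller p, larger MIR, name).
2. **Backward deletion.** Repeatedly deletes the predictor whose
   leave-one-out CMI has the largest insignificant p-value; runs after
   the forward pass.
3. **Rearrangement.** The chain order is chosen greedily from the
   outermost position inward so that the top-order interaction component
   is least significant — the rearranged identity isolates diffuse
   high-order heterogeneity in terms that can be dropped.
4. **Construction.** Significant Par components become main effects,
   significant Int components become interactions. A retained
   interaction with a composite conditioning group may be *replaced* by
   its single-conditioner sub-interactions when each is significant,
   their statistics sum higher, and their combined df is no larger; the
   replacement prefers several sharp low-order effects over one diffuse
   high-order one and can be disabled
   (`replace_interactions = FALSE`).

Steps 1–2 default to running sequentially (forward to exhaustion, then
backward); the greedy step-3 search is exhaustive for two predictors and
a reasonable heuristic above that.

The constructed terms translate directly into a grouped-binomial
logistic model via `as_logit_spec()` and `fit_logit()`. Crossed terms
can enter either as a *compound* factor (Cartesian levels, $L_1L_2 - 1$
parameters) or as an interaction added to the component mains
($(L_1-1)(L_2-1)$ extra parameters); both are exact reparameterizations
of the same class probabilities when the mains are present, and the
deviance is identical. The logistic deviance is computed against the
saturated grouped model, and equals the IPF deviance of the matched
log-linear model (for mains $T \sim X + Y$, the model
$\{XY, TX, TY\}$) — a cross-check the test suite exercises.

## A worked example

```{r credit}
g <- german_credit()
x <- crosstab(g, A1, A3, A12, A21)

chain_decompose(x, "A21", c("A1", "A3", "A12"))

pythagorean_split(x, "A3", "A21", "A1")

glance(fit_logit(g, "A21 ~ A1 + A3 + A12"))
```

`german_credit()` reconstructs the 1000 Statlog banking-credit records in
their original attribute coding from the one-hot encoded copy shipped
with the `caret` package, so the benchmark runs without any download.

## What the synthetic generator emulates — and what it does not

`simulate_table()` draws cell counts from a single multinomial with a
probability tensor given directly or through log-linear $\lambda$ terms
(normalized $\exp$ of the summed effects — equivalent to Poisson
sampling conditioned on $N$). `simulate_logistic_records()` draws
independent categorical predictors and a Bernoulli target from a
reference-coded linear predictor. Both take an explicit seed and restore
the caller's RNG state.

The generator reproduces the sampling model the inference assumes:
complete records, independent subjects, fixed $N$, and (for the logistic
mechanism) independent predictors. Real epidemiological data violate
several of these — predictors are correlated, tables may be sparse with
structural zeros, and records go missing informatively. Passing the
simulation-based checks therefore validates the *estimators and the
selection logic under the stated model*, not robustness to those
violations; the nominal-df defaults in particular are known to be
conservative on very sparse tables.

Study conditions used by the automated checks (chosen once, as the
conditions the checks are meant to probe): identity exactness on 500
random tables of 2–4 factors with 2–4 levels and $N$ between 100 and
5000; interaction-oracle equivalence on 200 small 2×2×2 tables;
test-size calibration with $N = 2000$ over 2000 replicates under a
conditional-independence tensor whose margins keep every expected cell
count well above 5; and selection recovery over 200 replicates at
$N = 2000$ with two active predictors at $|\beta| = 1.5$ plus one noise
candidate. With $k$ noise candidates, exact-set recovery is bounded by
$(1-\alpha)^k$, which is why the recovery scenario uses a single noise
predictor; larger candidate sets trade exactness for discovery in the
usual stepwise way.

## Numerical choices and degenerate inputs

* $0 \log 0 = 0$ throughout; cells with zero observed count contribute
  nothing to any statistic.
* Tiny negative statistics from round-off (within $10^{-8}$, or
  $10^{-6}$ for the Par subtraction) are clamped to zero; anything more
  negative raises an error, since it signals a failed fit rather than
  round-off.
* A saturated model reports deviance 0 on 0 df with p-value 1.
* Empty record sets, missing values, overlapping factor groups, unknown
  names and unsorted cutpoints are errors with the offending item named
  — never silently repaired.
* CMI is computed by the exact chain-rule difference of joint MI terms,
  which makes every decomposition telescope to machine precision and is
  algebraically identical to the stratum-weighted within-stratum
  $G^2$ sum (also verified in the tests).

## Known limitations

* Asymptotic chi-square p-values only; no exact or permutation tests.
* No bias-corrected MI estimators; plug-in estimates are biased upward
  on tables with many cells relative to $N$.
* IPF only (no Newton–Raphson), and no structural-zero /
  quasi-independence models.
* The logistic side targets binary responses and categorical predictors;
  numeric covariates must be discretized first (`discretize()`), which
  is the intended workflow.
* The step-3 rearrangement is greedy beyond two predictors; with many
  correlated predictors, competitive orders with similar outer
  interaction p-values can exist, and the trace records the scores so
  rivals can be inspected.
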