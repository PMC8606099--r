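---
title: "Product-method mediation: models, estimators, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Product-method mediation: models, estimators, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prodmed)
```

## The estimand and its identification

For an outcome $Y$, exposure $X$, mediator $M$ and pre-exposure covariates
$W$, the package estimates the natural indirect effect (NIE), natural
direct effect (NDE), total effect (TE) and mediation proportion (MP) for an
exposure change $x^* \to x$, conditional on $W = w$, defined on the
$g$-scale of the outcome model as contrasts of potential-outcome means:

$$\mathrm{NIE} = g\!\left(E[Y_{x,M_x}\mid w]\right) - g\!\left(E[Y_{x,M_{x^*}}\mid w]\right),
\qquad
\mathrm{NDE} = g\!\left(E[Y_{x,M_{x^*}}\mid w]\right) - g\!\left(E[Y_{x^*,M_{x^*}}\mid w]\right),$$

with $\mathrm{TE} = \mathrm{NIE} + \mathrm{NDE}$ and
$\mathrm{MP} = \mathrm{NIE}/\mathrm{TE}$. Identification requires the usual
consistency and composition assumptions plus no unmeasured confounding of
the exposure–outcome, mediator–outcome and exposure–mediator relationships
given $W$, and the cross-world condition that no mediator–outcome
confounder is affected by exposure. These are assumptions about the design,
not testable from the data; the package computes the estimands *given*
them.

Two working models are fitted:
$g(E[Y\mid X,M,W]) = \beta_0+\beta_1X+\beta_2M+\beta_3^TW$ and
$h(E[M\mid X,W]) = \gamma_0+\gamma_1X+\gamma_2^TW$, identity links for
continuous variables, logit links for binary ones. No exposure–mediator
interaction term is included (a deliberate scope restriction; see
Limitations).

## Expressions by data type

* **Case 1** (continuous/continuous): $\mathrm{NIE}=\beta_2\gamma_1\Delta x$,
  $\mathrm{NDE}=\beta_1\Delta x$, difference scale, covariate-free. Valid
  whenever the two conditional means are correct — normality or
  homoskedasticity of $M$ is *not* needed here.
* **Case 2** (continuous outcome, binary mediator):
  $\mathrm{NIE}=\beta_2\{\operatorname{expit}(\gamma_0+\gamma_1x+\gamma_2^Tw)-
  \operatorname{expit}(\gamma_0+\gamma_1x^*+\gamma_2^Tw)\}$; depends on $w$.
* **Case 3** (binary outcome, continuous mediator), log-odds-ratio scale.
  The *exact* expressions are ratios of one-dimensional logistic-normal
  integrals — expectations of $e^{\beta_2 M}/(1+e^{\beta_{\text{lin}}+\beta_2 M})$
  and $1/(1+e^{\beta_{\text{lin}}+\beta_2 M})$ under
  $M \sim N(\mu, \sigma^2)$ — which have no closed form and additionally
  assume the mediator is homoskedastic normal given $(X, W)$. The
  *approximate* expressions ($\beta_2\gamma_1\Delta x$, $\beta_1\Delta x$)
  rely on the rare-outcome assumption, under which the logistic link is
  close to a log link and the integrals collapse to log-normal moments. The
  *probit* variant replaces the logistic function inside the integral by
  $\Phi(s\,\cdot)$ with $s = 1/1.6$, giving closed forms; it degrades as
  the outcome prevalence moves away from 50%.
* **Case 4** (binary/binary), log-odds-ratio scale. The package computes the
  exact measures by direct enumeration of the binary mediator:
  $E[Y_{x,M_{x'}}\mid w] = P(Y{=}1\mid x, M{=}1, w)P(M_{x'}{=}1\mid w) +
  P(Y{=}1\mid x, M{=}0, w)P(M_{x'}{=}0\mid w)$, then takes logit contrasts.
  This is mathematically exact and is the canonical route. Closed forms in
  terms of $\kappa(x,w)=e^{\gamma_0+\gamma_1x+\gamma_2^Tw}$ and
  $\eta(x,w)=e^{\beta_0+\beta_1x+\beta_3^Tw}$ exist, but the NIE form as it
  commonly circulates fails the basic sanity check $\beta_2=0 \Rightarrow
  \mathrm{NIE}=0$; algebra from the enumeration shows the second log term
  must enter with the opposite sign. We verified the corrected arrangement
  numerically against the enumeration over randomized parameter draws
  (agreement to $10^{-10}$) and keep the closed form only as a run-time
  cross-check: any discrepancy beyond $10^{-8}$ raises a warning. The NDE
  closed form checks out as usually printed.

MP is never clamped to $[0,1]$: with sign-discordant NIE and NDE the ratio
legitimately falls outside the unit interval, and simulation summaries need
the raw values. When $|\mathrm{TE}|$ is numerically zero
($\le 10^{-12}$) MP is reported as undefined rather than as an arbitrary
number.

## Estimation and uncertainty

Coefficients solve the unweighted canonical estimating equations — exact
one-step least squares for identity links, Newton scoring for logit links
(maximum 100 iterations; convergence when the largest absolute *average*
per-subject score falls below $10^{-10}$, a sample-size-invariant
criterion). Any logit coefficient with $|\hat\beta| > 20$ flags probable
separation; the fit is marked failed rather than silently returned, so
replication studies can count and exclude it. For a continuous mediator,
$\hat\sigma^2 = n^{-1}\sum_i r_i^2$ is the exact root of its estimating
equation (divisor $n$, not $n-p$, because that is the equation's root), with
variance $n^{-2}\sum_i(\hat\sigma^2 - r_i^2)^2$.

Per-block covariances are robust sandwiches $A^{-1}BA^{-T}/n$ by default
(model-based inverse-information versions are kept alongside). The three
estimating equations are asymptotically uncorrelated, so the joint
covariance of $\theta = (\beta, \gamma, \sigma^2)$ is assembled strictly
block-diagonal — the cross-blocks are exactly zero, not merely small. This
is what makes the delta-method variance of the case-1 NIE reduce to the
familiar product-of-coefficients (Sobel-type) form with no $\beta$–$\gamma$
covariance term.

**Delta method.** Gradients are central finite differences with
per-coordinate step $10^{-6}\max(1, |\hat\theta_j|)$. Numeric
differentiation is used for every case — case-3 gradients pass through the
quadrature and are error-prone analytically — and the case-1 closed form
serves as the cross-check in the test suite. Variance is the quadratic form
against the block-diagonal covariance; tiny negative values from roundoff
(above $-10^{-12}$) are floored at zero, anything worse is an error.
Intervals are $\pm 1.96\sqrt{\widehat{\mathrm{Var}}}$.

**Percentile bootstrap.** Rows are resampled jointly (pairs bootstrap),
preserving the joint distribution of $(Y, X, M, W)$. Default $R = 1000$;
the interface exposes $R$ (CLI default 2000). Percentiles use linear
interpolation between order statistics (R's type 7) — a convention that had
to be fixed once for reproducibility. One user seed deterministically
spawns a sub-seed per resample, so results are independent of execution
order. Resamples with degenerate draws (constant exposure or mediator, or a
constant binary outcome) or failed refits are excluded from the percentile
computation and counted; more than 20% failures aborts the interval as
unreliable. This failure-handling rule is a package decision — surfaced in
the output — since no standard convention exists.

One boundary interaction is worth knowing: a mediator that is an *exact*
linear function of its design has $\hat\sigma^2 = 0$ and is rejected as
degenerate (the case-3 expressions divide by $\sigma^2$). Consequently a
fully noiseless dataset cannot be bootstrapped end to end; the
collapse-to-a-point behaviour of the percentile interval under a
deterministic estimator is exercised in the tests through a noiseless
*outcome* model instead.

## The simulation engine: what its defaults state

The generator's defaults describe the reference operating-characteristics
design, not tuning knobs: binary exposure with $P(X{=}1)=0.5$;
exposure–mediator correlation 0.2 (giving $\gamma_1 = 0.408$ for a
continuous mediator with unit error variance, and $\gamma_1 \approx 0.904$
for a binary mediator at baseline prevalence 0.2); mediator baseline
prevalence 0.2; baseline outcome prevalence 3% for binary outcomes
($\beta_0 = \operatorname{logit}(0.03) \approx -3.476$); mediator error
variance 1; total effects in $\{0.25, 0.5, 1\}$ (difference scale) or
$\{\log 1.2, \log 1.5, \log 2\}$ (log odds ratio); MP in
$\{0.05, 0.2, 0.5\}$; 5,000 replications at full scale. Outcome
coefficients are *solved* so the true exact measures hit the (TE, MP)
targets: closed form for continuous outcomes; for binary outcomes a damped
Newton iteration on the two exact equations, started at the rare-outcome
solution, with residuals required below $10^{-10}$.

Sensitivity generators: heteroskedastic mediator errors
$\mathrm{Var}(M\mid X) = \eta_0 + \eta_1 X$ with $\eta_0$ chosen so the
average error variance is 1 (at $\eta_1 = 1$ the exposed/unexposed variance
ratio is 3); standardized gamma errors with shape $(2/s)^2$ and scale
$s/2$, centered and scaled to mean 0 and variance 1 so the skewness is $s$.
The binary-confounder option takes user-specified prevalence and
coefficients for the exposure, mediator and outcome models (the exposure
intercept is shifted by $-a_X \cdot P(C{=}1)$ to keep the marginal exposure
prevalence near its target); no authoritative reference parameterization
was available, so none is hard-coded.

What the generator does *not* emulate: continuous exposures, measurement
error in the mediator, clustered or longitudinal designs, informative
missingness, or covariate-rich confounding structures beyond a single
binary confounder. A green replication study therefore establishes the
estimators' behaviour under clean, correctly specified sampling — not
robustness to those features.

Summary metrics follow the standard operating-characteristic definitions:
median percent bias $\mathrm{median}\{(\hat p - p)/p\}\times 100$ (medians
blunt the influence of outlying small-sample estimates, but make the
summary itself a noisy quantity — with heavy-tailed percent-bias
distributions the Monte-Carlo standard error of a 5,000-replication median
can reach several percentage points at $n = 150$); empirical 95% CI
coverage, flagged when outside $95 \pm 1.96\sqrt{0.95\cdot 0.05/B}\times
100$; and the variance ratio, median estimated variance over empirical
variance of the point estimates. Failed replications are excluded with
counts reported; a run with more than 10% failures is flagged unreliable.
The variance ratio is reported raw — with unstable MP estimates the
empirical variance can explode and drive the ratio toward zero, which is
informative rather than a defect.

## Numerical choices

* **Gauss–Hermite quadrature**: 40 nodes by default, computed by the
  Golub–Welsch eigen-decomposition and cached. No authoritative node count
  exists for this problem; 40 nodes agree with adaptive quadrature to
  $10^{-8}$ across the tested parameter ranges, and node-doubling (40 vs
  80) stability is asserted in the tests. Integrands are evaluated in log
  space (log-sum-exp), so large $|\beta_2|$ or offsets do not overflow.
* **Overflow guards**: linear predictors are clipped at $\pm 700$ before
  exponentiation, with a warning — protection without silently altering
  well-scaled problems.
* **Conditioning values** for covariates default to zero; the analysis
  interface also accepts `"mode"` (the most frequent value of each
  covariate). No rule is provided for the mode of a truly continuous
  covariate — supply explicit values there.
* **Contrast defaults**: $x^* = 0 \to x = 1$.
* **Seeds**: every random routine (bootstrap, simulation) requires an
  explicit seed and derives per-replication sub-seeds from it by counter,
  so results are reproducible and order-independent.

## Limitations

No exposure–mediator interaction models; no marginal
(population-averaged) mediation measures; no odds-ratio-scale or log-link
variants of the binary-outcome measures; no clustered/stepped-wedge
variance corrections; no BCa or studentized bootstrap; categorical
covariates must be pre-expanded to indicators; missing values must be
resolved by the caller. The delta-method MP interval is computed on the raw
ratio scale and is known to undercover in small samples — the bootstrap is
the recommended interval there, and the replication engine quantifies
exactly when each method attains nominal coverage.
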