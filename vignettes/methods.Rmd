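---
title: "Models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irtnorms)
```

This vignette is the package's account of its statistical machinery: the
measurement and norming models, the parameters that matter and why their
defaults are what they are, what the synthetic-cohort generator does and
does not emulate, and the places where the design was genuinely open and a
choice had to be made.

## Measurement models

Dichotomous items follow the two-parameter logistic (2PL) model,
$P(x=1\mid\theta) = \mathrm{logit}^{-1}\!\big(a(\theta-b)\big)$, with
discrimination $a$ (unitless, logistic metric) and difficulty $b$ (in
latent-trait SD units). Ordered polytomous items follow Samejima's graded
response model (GRM): the cumulative probability of scoring at or above
category $k$ is $P^{*}_k(\theta) = \mathrm{logit}^{-1}\!\big(a(\theta -
b_k)\big)$ with ordered boundary locations $b_1 \le \dots \le b_{K-1}$,
and category probabilities are $P_k = P^{*}_k - P^{*}_{k+1}$ with
$P^{*}_0 = 1$, $P^{*}_K = 0$. A boundary is therefore the ability at
which a child has a 50% chance of reaching at least that category — for
the complex-figure rubric, $b_1$ corresponds to raw category 0.5.

**Logistic metric, no 1.702 constant.** The shipped parameter banks are
used exactly as printed, under the pure logistic form. This convention is
validated internally: the Token Test information function computed this
way from the shipped 36-item bank peaks at $\theta = -2.72$ with SEM
0.0756, matching the published precision profile to the printed digits.
Under a 1.702-scaled metric neither number reproduces.

**Information.** For a 2PL item $I(\theta) = a^2 P(1-P)$; for a GRM item
$I(\theta) = \sum_k (\partial P_k/\partial\theta)^2 / P_k$. Test
information is the plain sum over items — no prior-information term is
added — and $\mathrm{SEM}(\theta) = 1/\sqrt{I(\theta)}$, conditional
reliability $1 - \mathrm{SEM}^2$ under the unit-variance latent-trait
convention. The same validation pins these choices down: adding the +1
prior term would move the SVTT peak SEM off 0.076.

## Calibration

`irt_calibrate()` is Bock–Aitkin marginal maximum likelihood EM under a
standard-normal latent trait:

* **Quadrature**: 61 equally spaced nodes on $[-6, 6]$ with
  standard-normal weights renormalised to sum to one. 61 nodes make the
  grid step 0.2, ample for the smooth posteriors these items produce;
  widening or refining the grid changes EAP scores by less than $10^{-3}$.
* **E-step**: each person's posterior mass over the nodes, computed with
  per-category indicator-matrix products so the cost is a handful of
  BLAS calls per cycle rather than per-item loops.
* **M-step**: per item on the expected category counts at the nodes —
  damped Newton logistic regression for the 2PL (slope–intercept
  parameterisation), bounded L-BFGS-B for the GRM with boundaries
  parameterised as (first boundary, nonnegative gaps) so the ordering
  constraint is structural. The GRM M-step is capped at 30 inner
  iterations; this is a generalised EM step (any improvement of the
  expected complete-data log-likelihood suffices) and the marginal
  log-likelihood trace is recorded and checked to be nondecreasing.
* **Convergence**: maximum absolute parameter change below $10^{-4}$, at
  most 500 cycles — reproducibility is favoured over speed. Near-Guttman
  items (the shipped bank contains discriminations of 14.6) crawl toward
  the bound, which is why the cap matters.
* **Discrimination bounds** $[0.02, 25]$: the upper bound accommodates
  the printed 14.644 while preventing divergence; the lower keeps items
  from going exactly flat.
* **Degenerate items**: an item observed in fewer than two categories is
  unidentifiable and dropped with a message; a graded item with an
  unobserved interior or top category has its codes collapsed to the
  observed consecutive set (it is only identified on those).

Standard errors for 2PL parameters use the empirical Fisher
(score-cross-product) approximation via Fisher's identity — the
per-person marginal score is the posterior expectation of the
complete-data score. Recovery simulations in the test suite check that
±2 SE intervals cover the generating difficulties at nominal-ish rates.

**Scoring.** EAP (posterior mean, posterior-SD standard error) is the
default: it is defined for every response pattern, including all-correct
and all-wrong. ML is refused for those extreme patterns (it diverges) and
falls back to MAP with a flag. A person with no scorable responses gets
the prior mean with SE 1 and a `no_responses` flag.

## Dimensionality

Polychoric correlations are two-step pairwise ML: thresholds from the
marginal category proportions via $\Phi^{-1}$, then each pairwise latent
correlation maximises the bivariate-normal likelihood of the contingency
table. The bivariate normal rectangle probabilities use an internal
vectorised Gauss–Legendre evaluation of the single-integral reduction of
$\Phi_2$, cross-checked in the tests against `mvtnorm::pmvnorm` to
$10^{-8}$; perfect concordance returns $\rho = \pm 1$ exactly rather than
the optimiser's box bound.

The one-factor fit minimises $\sum_{i<j} w_{ij}(\rho_{ij} -
\lambda_i\lambda_j)^2$. For the diagonally weighted variant the weights
are $w_{ij} = (1-\rho_{ij}^2)^{-2}$ — the sample-size-free part of the
inverse asymptotic variance of a correlation — so that the test statistic
$T = (n-1)\hat F$ is approximately $\chi^2_{df}$ with $df = p(p-3)/2$
when the model holds. (Folding $n$ into the weights *and* multiplying by
$n-1$ would scale $T$ like $n^2$ and break the fit indices; the package
uses the conventional scaling.) CFI and TLI compare against the
independence baseline; RMSEA's 90% interval inverts the noncentral
$\chi^2$ at the 5th/95th tail probabilities; SRMR is the RMS residual
correlation. On data simulated from its own model ($\lambda = 0.7$,
$p = 18$, $n = 2000$) the fit attains CFI ≈ 1 and RMSEA ≈ 0, which is the
calibration standard this module is held to — the published fit indices
for the real cohort are functions of the raw data, which are not
available, and are not reproduction targets.

Ordinal alpha is the standardised coefficient on the polychoric matrix,
$\alpha = p\bar\rho / (1 + (p-1)\bar\rho)$.

## DIF screening

For each item, nested models are fitted with the matching ability as
anchor: M0 `response ~ θ`, M1 `+ group`, M2 `+ θ×group` — binary
logistic for dichotomous items, proportional odds for graded ones. The
effect size is $\Delta R^2 = R^2(\mathrm{M2}) - R^2(\mathrm{M0})$,
computed in all three common pseudo-$R^2$ flavours; the Nagelkerke
flavour drives flagging at the conventional moderate threshold 0.035
(0.07 large), with likelihood-ratio p-values for uniform and non-uniform
DIF reported alongside. The matching variable is the purified EAP score,
not a raw sum: `dif_purify()` re-estimates θ from the currently unflagged
anchors until the flagged set stabilises.

Two calibration facts worth knowing, both established by simulation in
the test suite: a null item's ΔR² shrinks toward zero as n grows and
essentially never crosses 0.035 at n = 600; and a one-boundary shift of
0.6 latent SDs — the order of magnitude the screen is meant to catch —
produces a mean Nagelkerke ΔR² of about 0.034, i.e. *at* the threshold,
so single-run power there is only moderate (≈ 40–50%). The power checks
in the tests therefore inject a 1.0-SD shift, where power is ≥ 90%. The
0.035 cutoff is an effect-size convention, deliberately conservative;
users hunting smaller DIF should rely on the reported LR tests.

Quasi-separation (perfect prediction, runaway slopes) triggers an
in-package ridge-penalised refit of the same likelihood (penalty
$10^{-3}\lVert\beta\rVert^2$ on the slopes) with a warning.

## Norm regressions and percentiles

Two model families are entertained, differing in the age transform: the
log family uses $\ln(\mathrm{age\ in\ years})$; the quadratic family uses
a centred, unit-norm orthogonal polynomial basis in age whose constants
are stored in the fitted recipe and reused verbatim when predicting for
new children. Candidate pools are {lnAge, MPE, Sex} or {Age, Age², MPE,
Sex} plus pairwise interactions, with hierarchy enforced (an interaction
requires its mains; Age² requires Age). `exhaustive_select()` enumerates
every hierarchy-respecting subset and scores $C_p = SSE_m/\hat\sigma^2_{full}
- n + 2p_m$ and the Gaussian BIC; `repeated_cv()` draws a fresh 80/20
split per repetition, runs 10-fold CV inside the 80% with common folds
across specifications, and scores each specification on the 20% holdout.
In the package's own simulations at the study size (n = 668, residual SD
0.702), BIC picks the generating subset in ≈ 90% of replicates and Cp in
≈ 70–85% — Cp's occasional extra term is the expected behaviour of an
AIC-like criterion, not a defect.

Diagnostics: VIF per predictor (computed from the auxiliary-regression
$R^2$), Cook's distance with the conventional > 1 flag, a Brown–Forsythe
test (median-centred Levene) of residual spread across fitted-value
quartiles — the grouping is a package choice; the quartile grouping is
merged to halves if any group falls under 8 observations — and a KS test
of standardised residuals against the standard normal. The KS p-value is
reported without the estimated-parameter (Lilliefors) correction and
should be read as approximate.

The percentile conversion is exact, not empirical:
$p = \Phi\big((\theta_{obs} - x^\top\hat\beta)/\hat\sigma\big)$ and
$PR = 100p$. Because this is a probability integral transform, PR/100 on
a cohort generated from the same model is uniform — a property the tests
verify end to end. Displayed ranks are clamped to [0.1, 99.9] (a report
should not print "0th percentile"); the raw probability is retained.
Ages outside [6, 18) are flagged as extrapolation. Scoring always uses
the fixed published bank — no re-calibration at scoring time — and the
SVTT scorer dichotomises half-credit responses before estimating θ, since
the published bank was calibrated on dichotomised data; scoring
half-credits as correct against that bank would silently miscalibrate.

## The synthetic-cohort generator

`simulate_cohort()` emulates the study conditions: age continuous-uniform
on [6, 17.99) (the inclusion range; its SD 3.46 is close to the reported
3.28), MPE normal (12.15, 3.62) truncated to [0, 22] by renormalised
inverse-CDF sampling (not clipping), sex Bernoulli(0.542), latent
abilities $\theta = x^\top\beta + N(0, \sigma^2)$ from the published norm
equations with their printed residual SDs, and item responses drawn from
the published banks at those abilities. Sex has no effect on θ by
default, matching the published final models, which contain no sex term.

What it does **not** emulate: local dependence between scoring units,
rater disagreement, item misfit, missingness mechanisms other than
completely-at-random, and correlation between the three tests' latent
traits (cohort θs are independent across tests). Passing recovery tests
on these cohorts therefore demonstrates the estimators' correctness under
the stated models, not robustness to their violation.

Two quirks are deliberate and documented rather than hidden:

* The published quadratic (copy) model sits on an orthogonal-polynomial
  basis whose centring constants were never printed, so that model
  **cannot be applied exactly to new raw ages**. The shipped copy fixture
  carries no basis and refuses to predict; the generator builds a basis
  from its own simulated ages and stores it in the cohort's provenance.
  Because the basis columns are unit-norm, the printed coefficients
  reproduce the intended age-effect magnitude at the study's n = 668 and
  scale with $\sqrt{n}$ otherwise — another reason the copy equation is
  shipped as documentation, not as a scoring tool.
* The 54.2% girls figure refers to the study's initial enrolment; the
  generator uses 0.542 throughout.

## Simulation sizes

The test suite and the acceptance script choose sizes that make
Monte-Carlo error small relative to the assertions while keeping a full
run in minutes on one CPU: 100 cohorts of n = 668 for norm-coefficient
recovery, 20 calibrations of n = 1500 for 2PL recovery, n = 1200–2000 for
GRM and factor-model recovery, and 10–20 seeded replicates for power and
null-calibration rates. Each stochastic routine takes an explicit seed;
nothing depends on global RNG state left by other code.

## Known limitations

* **One published information profile does not reproduce.** Computing the
  recall-scale GRM test information from the shipped 18-item recall
  parameters gives SEM(θ=1) = 0.413, a maximum at θ = −0.32, and mean
  information 6.69 over [−2, 0]; the published prose instead reports its
  peak at θ = 1 with SEM 0.315 and mean information 4.20. No standard
  convention (1.702 scaling, prior term, boundary-sum information,
  slope–intercept parameterisation) reconciles both numbers, and the
  published description of the copy-scale profile is likewise internally
  inconsistent (a "2PL" profile for polytomous items, with two peaks
  quoted at nearly the same location). The package computes and reports
  the standard quantities from the printed parameters; the corresponding
  acceptance entries report the computed values.
* CFA fit indices, DIF ΔR² values and norm-model R² for the real cohort
  depend on the unavailable raw data; the package holds those modules to
  property-based standards (calibration on well-specified synthetic data)
  instead.
* The norm model assumes homoscedastic Gaussian residuals across the
  demographic range; the percentile conversion inherits that assumption.
  Quantile-regression or location-scale norming is out of scope.
* Rasch, 3PL, bifactor and multidimensional models, MCMC calibration,
  plausible values, and DIF by age or parental education are out of
  scope.
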