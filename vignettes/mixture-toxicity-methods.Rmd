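---
title: "Methods: concentration-response and binary mixture toxicity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concentration-response and binary mixture toxicity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raytox)
```

## The problem

An acute aquatic bioassay exposes groups of animals (here ostracods,
*Heterocypris* sp., dosed with chromium and nickel salts) to a series of
concentrations and counts deaths at fixed census times. The quantities of
interest are the lethal concentrations LCx — the concentration killing a
fraction x of the population at a given exposure time — and, for binary
mixtures, whether the two toxicants act additively, antagonistically or
synergistically. `raytox` covers the full chain: curve fitting, LCx
estimation with intervals, mixture design, null-model prediction, and
interaction classification, with a binomial simulator standing in for raw
data.

## Concentration-response models

Three sigmoid families map concentration x (mg/L) to an expected mortality
fraction:

* **Weibull** $f(x) = 1 - \exp(-\exp(\alpha + \beta \log_{10} x))$ —
  asymmetric, approaches 1 slowly;
* **Box–Cox–Weibull (BCW)** $f(x) = 1 - \exp(-\exp(\alpha + \beta
  (x^\gamma - 1)/\gamma))$, $\gamma \ne 0$ — the Box–Cox exponent lets the
  concentration axis bend; for $\gamma < 0$ the transform is bounded above,
  so effects arbitrarily close to 1 may be unreachable (the inverse then
  reports "no solution");
* **Generalised logit (GL)** $f(x) = (1 + \exp(-\alpha - \beta \log_{10}
  x))^{-\gamma}$, $\gamma > 0$ — a logit with an asymmetry exponent.

The BCW limit $\gamma \to 0$ is a Weibull in $\ln x$, which is a
*reparameterisation* of the $\log_{10}$ Weibull above (the slope rescales
by $\ln 10$), not the same member; the package therefore rejects
$\gamma = 0$ rather than substituting silently. Closed-form inverses are
derived algebraically from the forward equations and are verified by the
round-trip property $|f(f^{-1}(Y)) - Y| < 10^{-9}$ across the effect range.

## Fitting

Observed deaths are pooled to one mortality proportion per concentration —
replicates contribute their mean proportion, which with equal group sizes
equals the pooled count — and the curve is fitted by unweighted least
squares on the proportion scale. This response scale is validated by the
reference data shipped with the package: the refitted chromium 96-h Weibull
parameters reproduce the published R² and MAE to two decimals.

Because the three-parameter families are ill-conditioned on 5–12 point
designs, optimisation is multi-start Levenberg–Marquardt: an 8 × 8 grid of
$(\alpha, \beta)$ over $[-12, 2] \times [0.5, 12]$ (crossed with a small
$\gamma$ grid for BCW/GL) plus a linearised complementary-log-log / logit
start, keeping the best sum of squared residuals. The same box also bounds
the optimiser, and for GL $\gamma$ is log-parameterised to stay positive.

The box matters for **family selection**. Left unconstrained, a
three-parameter family can always buy a little raw R² by drifting toward a
degenerate near-step curve (slopes of β ≈ 100 that interpolate the data but
have no biological meaning); even inside the box such solutions pin
themselves to the box edge. `select_best_family()` therefore excludes fits
flagged `on_boundary` whenever any family converged to an interior optimum,
then picks the highest R², breaking ties (R² within `tie_tol = 1e-4`) in
favour of fewer parameters and then lower MSE. On the shipped reference
data this rule selects the published family for both 96-h series (Weibull
for chromium, GL for nickel); on exact Weibull data it returns Weibull even
though GL matches it to within the tie tolerance.

Uncertainty uses the Gauss–Newton approximation: residual variance
$s^2 = SSR/(n - m)$ with $n$ the number of distinct concentrations and $m$
the parameter count, and parameter covariance $C = s^2 (J^T J)^{-1}$ from
the analytic Jacobian at the optimum (pseudo-inverse fallback if $J^T J$ is
singular).

## Effect concentrations and intervals

`effect_concentration()` inverts the fitted curve at the requested effect
fraction. The default interval intersects the level-p horizontal with the
95% **observation band**

$$\hat y \pm t_{n-m,\,\alpha/2} \sqrt{s^2 + v C v^T},$$

whose residual term makes it a band for a new observed proportion rather
than for the mean curve. The upper-band crossing gives the lower bound and
vice versa, located by bisection on the log-concentration scale inside
$[\mathrm{LCx}/1000,\ \mathrm{LCx} \times 1000]$ to $10^{-6}$ relative
tolerance. Because the band's half-width never drops below $t \cdot s$, the
horizontal at a small effect level (e.g. LC10 when $t \cdot s > 0.1$) may
never meet the upper band: the interval is then one-sided, returned with a
warning. A first-order delta-method interval on the concentration scale is
available as `ci_method = "delta"`. How the published intervals were
computed is not stated with the reference values; band inversion reproduces
their asymmetric shape but exact agreement is not claimed. A coverage
experiment included in the acceptance tests (200 seeds at the study design)
checks that the band-inversion interval covers the true LC50 at close to
the nominal 95% rate; coverage mildly above nominal is expected from the
$s^2$ term, which widens the band to observation (not mean-curve) scale.

## Mixture design

Given two components' effect concentrations:

* **EECR** rays mix the components in proportion to a common effect
  concentration (EECR 50 = LC50 : LC50, etc.); the defining top of the
  dilution series is the sum of the two values.
* **EquRay** rays place `n_rays` (default 5) equidistant points on the
  segment joining the LC50 axis intercepts; ray i combines
  $(n+1-i)/(n+1)$ of component a's LC50 with $i/(n+1)$ of component b's.
  The indexing convention is the one under which all five published mass
  ratios (0.53, 0.31, 0.19, 0.10, 0.04) reproduce to two decimals; the
  reversed numbering sometimes seen in prose descriptions is available as
  `index_from_text = TRUE`.
* **FRRD** serial dilution keeps each ray's component ratio fixed across
  `n_levels` (default 12) levels; the dilution factor between levels is not
  fixed by convention, so the package defaults to 2 (serial halving),
  configurable.

Two published EECR mass fractions (EECR 30 = 0.08, EECR 50 = 0.11) do not
reproduce from the tabulated LC30/LC50 values (the arithmetic gives 0.11
and 0.185); only the EECR 10 ratio, which does reproduce, is used as an
exact oracle in the tests. The discrepancy is documented, not resolved.

## Mixture prediction and interaction

* **Concentration addition** (Loewe). The implemented form is the standard
  toxic-unit formulation: the mixture LCp is the fraction-weighted harmonic
  mean $(\sum_i \pi_i / LC_{p,i})^{-1}$, and the CA effect at given
  component concentrations solves $\sum_i c_i / LC_{Y,i} = 1$ for Y. A
  sum-of-products form sometimes printed for CA is dimensionally
  inconsistent with the concept and is treated as a typesetting artefact.
* **Independent action** combines effects as $1 - \prod_i (1 - f_i(c_i))$;
  its LCp along a ray is found by root search, unique for increasing
  component curves.
* **Synergistic ratio** SR = LC50(single)/LC50(mixture). The strict
  published rule classes SR = 1 as additive; since equality never holds for
  estimated quantities, an additivity band $|SR - 1| \le \varepsilon$ with
  default $\varepsilon = 0.05$ is used ($\varepsilon = 0$ restores the
  strict rule).

`compare_models()` scores any set of predicted effect vectors against
observations with the same R²/MSE/MAE used for curve fits.

## Regression surrogate

The "QSAR" stage regresses mixture mortality on composition variables —
the two component concentrations, their total, and the first component's
mass fraction, which are the only descriptors a composition-only dataset
contains. Four families are fitted on a seeded 8:2 random train/test
split: ridge regression (penalty by internal cross-validation),
gradient-boosted trees (200 rounds, depth 3, learning rate 0.1), a
single-hidden-layer perceptron (32 units on standardised inputs), and
ordinary multilinear regression. The family with the highest test R² is
marked selected. Tree ensembles predict stepwise and occasionally
non-monotone dose-response slices, so `surrogate_effect_concentration()`
applies a running maximum along the ray before interpolating the crossing
of the target effect level. Everything is deterministic given the seed;
whether the original 8:2 split was random or ray-stratified is unknown, so
random is the default.

## Synthetic data

The simulator draws deaths per replicate group from
$\mathrm{Binomial}(n_{exposed}, f_{true})$ — matching how such experiments
are scored — with defaults of 10 animals × 3 replicates per level, 5-level
single-toxicant series and 12-level mixture series. Mixture truth comes
from either CA (Loewe inversion) or IA applied to the two true component
curves. The default truth curves are the published chromium/nickel fits, so
simulated data are "study-shaped" out of the box. No overdispersion is
simulated by default: real bioassays can show between-replicate
heterogeneity beyond binomial noise, tank effects, and time-correlated
deaths, none of which the generator emulates — passing recovery tests
therefore demonstrate correctness of the estimation chain under the stated
noise model, not robustness to every feature of real data.

Test problem sizes (chosen to probe the study design itself): LC50 recovery
uses all eight shipped truth curves × 25 seeds (median relative error
under 15%; the shallowest single curve, chromium 96 h with β = 1.21, is
individually harder at ≈ 18%); interval coverage uses 200 seeds; the CA-
versus-IA attribution experiment simulates the full 8-ray design (12 levels
× 3 replicates × 10 animals) for 100 seeds and requires CA to win the R²
comparison in at least 90 — a single ray carries too little CA/IA contrast
(≤ 0.06 in predicted effect) to separate the models against binomial noise
at n = 30 per level.

## Known limitations

* Proportion-scale least squares matches the reference analysis but is not
  a binomial likelihood; a probit/logit GLM would weight observations near
  0/1 differently. This is a deliberate scope decision.
* Printed reference parameters carry two decimals; quantities recomputed
  from them can differ from tabulated values in the last digit (the nickel
  72-h LC50 inverts to 7.66 vs the tabulated 7.65, and the BCW rows'
  LCx are very sensitive to the rounded γ).
* The observation-band interval is approximate (Gauss–Newton covariance,
  t quantile on $n - m$ degrees of freedom with n = 5 typical) and tends
  conservative.
* Concentrations are treated as-dosed (salt mass per litre); conversion to
  elemental metal is left to the user.
* Ternary and higher mixtures, time-to-event modelling, Bayesian fitting
  and isobologram/combination-index analyses are out of scope.
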