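---
title: "Detecting Heywood cases in IRT through Fisher information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting Heywood cases in IRT through Fisher information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heywoodIRT)
```

## The problem

An improper solution — a *Heywood case* — is a fitted parameter that
contradicts its own meaning: a negative unique variance in factor analysis, a
divergent discrimination in IRT (a *Guttman item*, whose response function
approaches a step). Scanning parameter estimates catches these only in models
whose parameters are interpretable. In asymmetric models (such as the
residual heteroscedasticity family) or the nominal response model, individual
parameters say little, and eyeballing response curves is subjective.

This package takes the information-function route. For a binary item with
response function $\pi(\theta)$, the Fisher information is

$$I(\theta) = \frac{(\partial_\theta \pi)^2}{\pi(1-\pi)},$$

and a Heywood case is the collapse of $I(\theta)$ toward a point mass: the
diagnostic object is the set of critical points
$\{\theta^* : \partial_\theta I(\theta) = 0,\ \partial^2_\theta I(\theta) \le 0\}$,
the local maxima of information, together with the heights $I(\theta^*)$.
Because everything is computed from curves — analytically where cheap,
by finite differences otherwise — the approach is parameterization-free.

Three flagging criteria are kept deliberately separate (no composite score):

* **slope**: under a standardized trait ($\mathrm{var}(\Theta) = 1$),
  $|\xi| > 5$ is suspect, by the usual logistic-regression separation
  heuristic;
* **information**: for a plain 2PL the same cut is exactly peak information
  $I(\theta^*) = \xi^2/4 > 6.25$, and *this* form transfers to families with
  no interpretable slope. Through $\mathrm{rel}(\theta) = I/(1+I)$, $I = 10$
  means local reliability $\approx 0.9$ — single items this reliable relative
  to their peers deserve suspicion;
* **IFTI**: the Item Fraction of Total Information
  $\mathrm{IFTI}_j(\theta) = I_j(\theta) / \sum_k I_k(\theta)$ is unitless
  (the $1/\theta^2$ units cancel), sums to 1 across items at every $\theta$,
  and plays the role leverage plays in regression: a share above $2/J$ is
  troublesome, above $4/J$ clearly problematic. Multiplying by $J$ re-reads
  it as an effective number of items.

## Model families and their exact derivatives

Five families are implemented with analytic first and second derivatives
(`irf()`, `irf_deriv()`), each cross-checked in the test suite against
central finite differences:

* **linear**: $Y = \eta + \xi\Theta + U$, $U \sim N(0, \psi^2)$; information
  is the constant $\xi^2/\psi^2$, or $(1-h^2)/h^2$ in the standardized
  solution where $\psi^2 = h^2$ and $\xi^2 = 1 - h^2$. The ten-item worked
  scenario (one weak item with $h^2 = 0.1$ among nine at $0.2$) gives total
  information $\sum 1/h^2 - V = 45$ with a 20% share for the weak item;
  lowering it to $h^2 = 0.05$ gives 55 and a 35% share — the `t1`–`t4`
  acceptance targets.
* **2PL/3PL/4PL**: $\pi = c + (d-c)\Lambda(\eta + \xi\theta)$ in
  slope-intercept form; the asymptote form is the standard one (the family is
  named but not written out in most treatments, and the general information
  formula with analytic derivatives avoids the notoriously unwieldy
  closed forms).
* **RH** (residual heteroscedasticity): see the design note below.
* **NRM**: $\pi_k \propto e^{\alpha_k + \gamma_k\theta}$ under sum-to-zero
  constraints (a converter re-centers baseline-category input). The
  derivatives have the clean mixture forms
  $\partial_\theta \pi_k = \pi_k(\gamma_k - \bar\gamma)$ and
  $\partial^2_\theta \pi_k = \pi_k[(\gamma_k - \bar\gamma)^2 -
  \mathrm{var}(\gamma)]$ with moments taken under $\pi(\theta)$.

## Design note: the RH scale function

The RH model divides the 2PL linear predictor by a residual-scale function
of $\theta$. Published renderings of the formula are typographically
ambiguous about whether the logistic scale term sits in the numerator or
denominator; both readings collapse to the 2PL at $\delta = 0$. We adopt

$$\pi(\theta) = \Lambda\!\left(\frac{\eta + \xi\theta}{2\Lambda(\delta\theta)}\right)
 = \Lambda\!\left((\eta+\xi\theta)\,\tfrac{1 + e^{-\delta\theta}}{2}\right),$$

i.e. residual scale $\sigma(\theta) = 2\Lambda(\delta\theta)$, because only
this reading reproduces the documented behavior of the bundled 16-item
calibration (`rh_calibration()`): under it the four mental-rotation items
with strongly negative $\delta$ produce information spikes of height 19.8
and 29.7 near $\theta \approx 1$ (clear Heywood cases, far above the 6.25
cut) while the reciprocal reading flattens all curves toward 0.5 in both
tails and yields peak information below 0.06 everywhere — no Heywood
behavior at all. The scale function is one small internal (`rh_scale`) so an
alternative algebraic reading can be swapped without touching derivatives,
information, or diagnostics. For parts of the parameter space the RH curve
is genuinely non-monotone; `irf_monotone()` reports sign changes of
$\partial_\theta\pi$ rather than hiding them.

## The category-information decomposition

For the NRM, the per-category information terms are implemented as
$I_{jk} = (\partial_\theta\pi_k)^2/\pi_k - \partial^2_\theta\pi_k$, which sum
over $k$ to the item information. Because
$\sum_k \partial^2_\theta \pi_k = 0$ under the normalization constraint, the
total must also equal $\sum_k (\partial_\theta\pi_k)^2 / \pi_k$; the test
suite asserts both computations agree to $10^{-10}$, which guards the chosen
reading of the decomposition against transcription error. The $K = 2$ NRM
with $\alpha = (\mp a/2)$, $\gamma = (\mp g/2)$ collapses algebraically to a
2PL with $\eta = a$, $\xi = g$, and its information matches the binary
formula to the same tolerance.

## Flagging rules on a discrete grid

* Curves live on a uniform grid, default $[-4, 4]$ in steps of 0.01 — wide
  enough for a standardized trait, fine enough that finite differences of
  smooth IRFs are accurate to well under $10^{-4}$ (first order; second
  differences are an order looser near the one-sided end stencils).
* A "critical point" is operationalized as an interior grid local maximum
  found by sign changes of the finite-difference slope; plateau runs report
  their midpoint; a maximum at the grid edge has no zero derivative and is
  reported as a `boundary` note, never as $\theta^*$. Constant curves (the
  linear family) report `plateau` and are not info-flagged: constant
  information has no critical point, however large.
* The IFTI cuts are applied **pointwise**: any exceedance inside
  `theta_window` triggers, and the exceedance interval is reported. The
  window defaults to the full grid but is a first-class argument because
  IFTI spikes at extreme $\theta$, where no examinee plausibly sits, are a
  known artifact of slope heterogeneity (weak items hold their information
  longest in the tails) and are often safe to ignore.
* Flag ordering is problematic > suspect > troublesome > none; an item
  reports its worst flag plus every triggering criterion.

## Scoring

EAP scores (`eap_scores()`) update a Gaussian prior by Bayes' rule and
report the posterior mean and SD, integrating with a fixed rectangular
quadrature: 61 equally spaced nodes on $[-6, 6]$. The rule and node count
are our choice (common software does not document one consistently); the
test suite holds the default against a 10,001-node dense-grid oracle and
sees agreement around $10^{-8}$, far inside the $10^{-4}$ contract, so the
default is not the accuracy bottleneck for any realistic item set. EAP is
finite for every pattern, including all-correct, and shrinks toward the
prior mean — the behaviors that make it the default over ML. Missing
responses are skipped in the likelihood, i.e. treated as ignorable.

Bartlett scores for the linear family implement the closed form
$\hat\theta = (\sum \xi^2/\psi^2)^{-1} \sum \xi y / \psi^2$ literally (no
centering by $\eta$); with tiny $\psi^2$ one item dominates the score —
the linear-model face of a Heywood case, and the reason
`linear_item(psi2 = 0)` is rejected outright with a diagnostic.

`score_volatility()` summarizes the scoring symptom: grouped by
number-correct, the spread of $\hat\theta$ (and of its SE) within groups.
With a near-Guttman item present, high-number-correct groups split on
*which* item was missed, and within-group ranges inflate several-fold; with
equal slopes, number-correct is sufficient and the within-group spread is
numerically zero. Both ends are asserted in the tests.

## Estimation and regularization

`fit_mml()` maximizes the quadrature-approximated marginal likelihood
(standard-normal trait, 41 equally spaced nodes on $[-6,6]$) directly by
BFGS with exact analytic gradients — the canonical-link cancellation
$\partial \log f / \partial \tau = (y - \pi)\,\partial g/\partial \tau$
keeps them cheap — rather than by EM: same estimand, simpler to verify
(the gradient is checked against numerical differentiation in the tests).
Starting values are $\eta$ from the inverse logit of proportion correct,
$\xi = 1$, $\delta = 0$; standard errors come from the numerically
differentiated observed information. A divergent slope estimate triggers a
separation warning.

A Gaussian prior on the RH asymmetry $\delta$ (via `prior_spec()`) adds a
log-prior penalty (MAP). The common "N(0, 0.25)" shorthand is ambiguous
between sd and variance; we read it as **variance** 0.25 (sd 0.5), since it
is conventionally ordered as stricter than N(0, 1) — and `prior_spec()`
takes an explicit sd, so either reading is available. `prior_sweep()`
tabulates the trade-off: as the prior tightens, max $|\hat\delta|$ is
nonincreasing, peak information and flags shrink, and the *unpenalized*
log-likelihood deteriorates; the 2PL is the $\delta \equiv 0$ limit of the
ladder. NRM fitting is deliberately out of scope — NRM diagnostics accept
externally fitted parameter tables.

## What the synthetic data does and does not emulate

`fixture_suite()` generates four deterministic scenarios (trait draws
$\Theta \sim N(0,1)$, locally independent responses, all randomness through
explicit seeds): a clean 16-item 2PL set with slopes confined to 0.7–1.4 —
narrow enough that not even the extreme-$\theta$ IFTI artifact reaches the
$4/J$ cut; the same set with a planted slope-8 item (information peak 16:
clearly past every cut, yet numerically tame); the bundled 16-item RH
calibration used as generating truth — a synthetic stand-in for the real
multi-type cognitive-ability data, which is out of scope; and a small
5-category NRM set. The generator does **not** emulate examinee mixtures or
non-ignorable skipping (speculated causes of the real data's behavior), so a
green test establishes that the diagnostics behave correctly under the
stated model, not that the model is right for any particular dataset.

## Numerical choices

* $\pi$ is clipped to $[10^{-12}, 1-10^{-12}]$ inside information and
  weight ratios; clipped grid points are recorded in a `clipped` attribute.
  In double precision the tails of a near-Guttman IRF genuinely underflow
  to 0/1 — the curves are computed as-is rather than masked.
* Zero total information leaves IFTI undefined: masked as `NA` and listed,
  never divided through.
* Quadrature for scoring and fitting is rectangular on equally spaced
  nodes; weights are normalized prior densities, so truncation at $\pm 6$
  costs only the $\sim 2\times10^{-9}$ prior mass outside.
* Parameter tables round-trip CSV/JSON at 17 significant digits
  (differences $< 10^{-12}$ asserted in the tests).

## Limitations

Univariate $\theta$ only (the multivariate gradient/Hessian version of the
critical-point definition is out of scope); logistic links only; no ML/WLE
scoring (EAP and Bartlett cover the use cases here, and the Heywood
pathologies appear under every scoring method); no model-fit statistics
(RMSEA-style misfit of heavily regularized fits is reported only through
the log-likelihood columns of `prior_sweep()`); no bootstrap standard
errors. The severity scale stops at three separate criteria by design — a
composite index would hide exactly the information the criteria disagree
about.
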