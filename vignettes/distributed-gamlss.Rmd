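---
title: "Distributed GAMLSS: model, protocol, and numerical design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed GAMLSS: model, protocol, and numerical design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedgamlss)
```

## The model

A GAMLSS family assigns each subject an outcome distribution with up to
four parameters — location $\mu$, scale $\sigma$, skewness $\nu$, kurtosis
$\tau$ — and models each parameter on its own link scale:

$$g_k(\theta_k) = \eta_k = X_k\beta_k + Z_k\gamma_k, \qquad k = 1,\dots,p.$$

Four families are registered. `NO` (normal; $\mu$ identity, $\sigma$ log)
is the sanity-check family with closed-form special cases. `BCPE` (Box–Cox
power exponential on $y>0$; identity/log/identity/log) adds parametric
skewness and kurtosis and reduces to the Box–Cox normal at $\tau = 2$; its
density carries the truncation constant $F_T(1/(\sigma|\nu|))$ of the
Box–Cox transform so it integrates to one exactly. `BEZI` is a
zero-inflated beta on $[0,1)$: a point mass $P(Y=0)=\nu$ mixed with
$(1-\nu)\,\mathrm{Beta}(y;\mu\phi,(1-\mu)\phi)$, with the unit-interval
dispersion parameterization $\phi = (1-\sigma^2)/\sigma^2$ so all three
links are logit. `GG` (generalized gamma; log/log/identity) reduces to the
gamma at $\nu = 1$ and is continued through the removable singularity at
$\nu = 0$ by its lognormal limit. Links are fixed per family rather than
user-chosen: algorithmic exactness across sites requires every site to use
the same link, and any consistent monotone choice gives the same fitted
distributions, so the conventional defaults are hard-wired.

## The fitting algorithm and its distributed form

Fitting follows the RS scheme: an outer cycle over the $p$ parameters and,
for each parameter, an inner Newton–Raphson cycle holding the other
parameters fixed. With per-subject score $u = \partial\ell/\partial\eta_k$
and weight $w = -\partial^2\ell/\partial\eta_k^2$, each Newton step is the
penalized weighted least squares solve
$(X^\top WX + \lambda\tilde P)b = X^\top Wz$ on the adjusted dependent
vector $z = \eta + u/w$. Both cross-products are sums over subjects, so
sums of the per-site matrices $M_{i1} = X_i^\top W_iX_i$ and
$M_{i2} = X_i^\top W_iz_i$ reproduce the pooled solve exactly: one
communication round per inner iteration, carrying only $q_k \times q_k$
aggregates. The pooled and distributed fitters share the cycle driver and
differ only in where the cross-products come from, so the distributed
iterate sequence is the pooled one by construction; the test suite verifies
the agreement per iteration over random partitions into 1–8 sites.

Convergence is declared per coefficient when the proportion change between
successive values falls below `c` (default **0.05**, balancing stability
against communication cost; the denominator falls back to an absolute
comparison at $10^{-8}$ when the old value is near zero). The inner cycle
stops when every coefficient of the current parameter passes; the outer
cycle stops when every coefficient of every parameter passes against the
previous outer cycle. Deviance-based stopping would need one extra round
per iteration, because the deviance at the new coefficients only arrives
with the next round's messages.

Initialization needs no dedicated round: sites include moment summaries
(count, sum, sum of squares, zero count, positive-part moments) in the
setup round, and each family maps them to starting values
($\mu$ from the outcome mean, $\sigma$ from a moment estimate, $\nu/\tau$
at the family's reduction values). Because a B-spline basis sums to one in
every row, setting all smooth coefficients to the linked initial value
reproduces an intercept-only start.

### Safeguards

Three deterministic safeguards run identically on both paths. (1)
*Delayed step halving*: each update round reports the deviance at the
currently broadcast coefficients; if the previous accepted step increased
it (beyond $10^{-7}(|D|+1)$, or left the likelihood's domain), that step is
halved and the round redone — up to 5 times, more if the deviance is not
finite. (2) *Inner-cycle damping*: updates after the fifth non-converged
inner iteration are damped by 0.5, curbing Newton overshoot in weakly
identified directions. (3) *Weight safeguarding*: observed weights that are
non-positive are replaced by the squared score and floored at $10^{-10}$,
keeping every WLS solve positive definite (the aggregate contributions
$wz = w\eta + u$ stay bounded under the floor).

### Derivatives

Analytic scores and observed weights are implemented where the classical
formulas are compact (normal; zero-inflated beta, including the trigamma
second derivatives of the beta component). BCPE and GG use central finite
differences of the log-likelihood on the linear-predictor scale. Two
numerical choices matter here and were set deliberately:

* **Split step sizes** — $h_1 = 10^{-4}\max(1,|\eta|)$ for the first
  difference and $h_2 = 5\times10^{-4}\max(1,|\eta|)$ for the second.
  The second difference divides rounding error by $h^2$, so it needs the
  larger step; the Newton fixed point solves $X^\top u = 0$ and is
  unaffected by the weight's discretization error.
* **Linear-predictor quantization** — sites snap $\eta$ to a grid of
  $2^{-30}$ relative precision before any likelihood or derivative
  evaluation (not in the post-fit Hessian, where grid noise would be
  divided by $h^2$). Without this, the last-bit differences between a
  pooled cross-product and the same cross-product summed site by site
  decorrelate the rounding inside the finite differences and get amplified
  by $1/h^2$, and the two iterate sequences drift apart. With it,
  arithmetically equivalent coefficient representations produce bitwise
  identical per-subject computations, and the observed pooled/distributed
  gap stays near machine precision for models the data can support.
  Severely ill-conditioned designs (nearly empty spline columns; condition
  numbers $\gtrsim 10^8$) amplify last-bit noise past any rounding scheme —
  there, agreement degrades to the square root of machine precision, which
  is also where the statistical meaning of those directions ends.

## Smooth terms

Smooths are penalized B-splines: `n_knots` equally spaced knots spanning
the *global* covariate range (established in the setup round as a min/max
exchange; the basis is broadcast so all sites evaluate identical columns),
cubic by default, boundary knots repeated `degree` times, giving
`n_knots + degree - 1` columns; the penalty is the order-2 difference
penalty $D^\top D$ on adjacent coefficients. Cubic degree and second-order
differences are the established P-spline defaults; neither is dictated by
the protocol. When a parameter has a smooth, the basis replaces the
intercept column (the partition of unity spans constants), which keeps the
design full rank without orthogonalization. Out-of-range covariates at
prediction time are clamped to the fitted range with a warning — reference
charts are only valid where data were observed. When per-site ranges leave
an interior gap, the fit proceeds with a warning that the basis is
unsupported there.

The effective degrees of freedom of a penalized parameter design is
$\mathrm{tr}[(X^\top WX + \lambda\tilde P)^{-1}X^\top WX]$, inclusive of
fixed-effect columns; it decreases continuously from the design rank at
$\lambda = 0$ to the penalty null-space dimension plus the unpenalized
column count. `lambda_for_edf()` inverts this map by root finding on
$\log\lambda$; the trace is only accurate to about $10^{-4}$ at extreme
penalties, so targets within that noise of the maximal-smoothing limit
return the search cap rather than failing.

Three smooth regimes are supported. *Fixed-effect* ($\lambda = 0$): the
knot count alone controls flexibility; cheapest in communication.
*Fixed-penalty*: $\lambda$ given directly, or solved per iteration from the
aggregated cross-product to hold a target EDF; `match_penalties()` inverts
a reference fit's EDFs into broadcastable $\lambda$ values, emulating the
workflow where a gold-standard model's degrees of freedom are known.
*Automated*: at each inner iteration the aggregator solves candidate
coefficients for every value of a broadcast grid (20 log-spaced values in
$[10^{-4}, 10^6]$), sites return the deviance at each candidate location in
one extra round, and the criterion — BIC
($D + \log(n)\,\mathrm{EDF}$) by default, GAIC($\kappa$) or GCV
optionally — picks the winner, ties toward the smallest $\lambda$. The EDF
of the other parameters is a constant shift across candidates, so it cannot
change the winner. If no candidate improves the current criterion the
previous penalty is retained and the stall logged.

## Inference

One post-fit round collects per-site numerical Hessians of the full stacked
coefficient vector (central differences, step
$10^{-4}\max(1,|b_j|)$) and site deviances. The covariance is the inverse
of the summed Hessians; Wald $t$ statistics use two-sided normal p-values
(the reference-distribution adjustment used by some pooled implementations
is not attempted). A non-positive-definite Hessian sum — expected when
extreme spline columns are nearly empty — falls back to a pseudo-inverse
with the affected coefficients flagged.

Smooth terms in the fixed-effect and fixed-penalty regimes can be tested by
a likelihood-ratio comparison against a reduced fit without the smooth,
with a $\chi^2_{df}$ null. The `df` is the EDF difference between the full
and reduced designs for that parameter: because the basis absorbs the
intercept, removing an $m$-column fixed-effect smooth frees $m - 1$ degrees
of freedom, and the fixed-penalty case gives the (non-integer) penalized
EDF difference. Other parameters keep their full smooths, preserving
nesting. The reduced model is fitted as a separate run here; a production
deployment would interleave its rounds with the full model's to keep the
round count down. For automated-penalty smooths the test is refused: the
null distribution does not account for the data-driven penalty choice and
the test would be liberal.

## The synthetic multi-site generator

Three presets emulate the statistical structure of typical applications,
with closed-form (logistic/Gaussian-bump) true parameter curves —
deliberately not splines, so recovery tests also probe basis approximation
error. `bmi_like`: BCPE outcome, 9 sites with very unequal sizes mirroring
ICU admission counts, ages 18–100, hump-shaped location with upper-tail
skew, default $n = 5000$. `microbiome_like`: zero-inflated beta relative
abundance, 11 sites of 8–89 subjects totalling 569, log-uniform ages
0.16–83, zero mass 2.66%. `brainvol_like`: generalized gamma volume,
15 sites with geometrically unbalanced sizes (smallest 5), log-uniform
ages 3.2–100, rise-then-decline location, default $n = 3000$ (kept modest
so the automated-penalty comparisons run in seconds). Site effects are
small additive shifts on the location linear predictor (defaults 0.15 BMI
units, 0.1 logits, 0.02 log units); sites also differ in their age
windows, with the first site pinned to the full range. Everything is
reproducible byte for byte from the scenario seed.

What the presets do *not* emulate: real site-level measurement shifts on
higher moments, longitudinal repeats, covariate missingness patterns, and
confounding between site and age beyond the window heterogeneity. Passing
tests on these scenarios therefore demonstrates protocol exactness and
parameter recovery under correct model specification, not robustness to
the data pathologies of any particular consortium.

## Numerical choices, collected

* WLS solves are Cholesky on the penalized normal equations; a ridge of
  $10^{-10}\,\overline{\mathrm{diag}}$ is added only if the factorization
  fails, and rank deficiency beyond that is an error naming the columns.
* Deviance comparisons in step control use tolerance $10^{-7}(|D|+1)$;
  candidate deviances that are not finite are treated as infinitely bad.
* The automated-penalty grid is fixed and broadcast; determinism across
  sites requires it.
* Treatment contrasts use the alphabetically first level as reference,
  via a level dictionary merged in the setup round, so design columns
  align across sites; unseen levels at prediction time are an error.
* All per-site sample sizes, moments, ranges and level sets travel as
  aggregates; the message types are the only objects that cross the
  site/aggregator boundary, and a test inspects their payloads.

## Limitations

One smooth per parameter (no backfitting: in the distributed setting each
extra smooth would cost at least two additional rounds per inner
iteration); no longitudinal or censored extensions; no differential
privacy — the aggregates are far smaller than the data but iterative
release is not formally private; synchronous rounds only, any site failure
aborts the fit (exactness over availability). Inference for
automated-penalty smooths is deliberately absent rather than approximate.
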