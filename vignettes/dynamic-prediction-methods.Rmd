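---
title: "Dynamic prediction of death risk from nonlinear PSA kinetics: models and methods"
author: "psadyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic prediction of death risk from nonlinear PSA kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psadyn)
```

## The joint model

`psadyn` couples a nonlinear mixed-effects model for prostate-specific
antigen (PSA) kinetics under first-line chemotherapy in metastatic
castration-resistant prostate cancer (mCRPC) with a PSA-dependent hazard of
death, and uses the coupled model to make *individual dynamic predictions*:
for a patient alive at a landmark time $s$, with PSA measurements
$\mathcal{Y}(s)$ collected up to $s$, it predicts the conditional
probability of death over a horizon $t$,
$$\pi(s+t \mid s) = \mathbf{P}(X < s+t \mid X > s, \mathcal{Y}(s)),$$
together with a 95% prediction interval.

### PSA kinetics

The true (noise-free) PSA concentration follows a biexponential
treatment-escape model. Prostatic cells proliferate at rate $r$
(day$^{-1}$) and die at rate $d$; chemotherapy reduces proliferation by a
factor $(1-\varepsilon)$ until the escape time $T_{esc}$ (days), after
which growth resumes at full rate. PSA is produced by the cells and
eliminated from blood at rate $\delta$. The resulting curve declines from
the baseline value $PSA_0$ toward a nadir and regrows after escape, with a
kink at $T_{esc}$. Only four of the parameters are identifiable from PSA
series, so $d = 0.046$ day$^{-1}$ (tumour-cell half-life of 15 days) and
$\delta = 0.23$ day$^{-1}$ (blood PSA half-life of about 3 days) are fixed
constants, never estimated. A subject is then characterised by
$\psi = (r, PSA_0, \varepsilon, T_{esc})$.

Observations are modelled on the $y = \log(\mathrm{PSA}+1)$ scale with
additive Gaussian error of standard deviation $\sigma$; raw PSA in ng/mL is
converted at I/O time. Subject-level parameters arise from population
values through log-normal transforms for $r$, $PSA_0$, $T_{esc}$ and a
logit-normal transform for $\varepsilon$, with independent Gaussian random
effects $\eta \sim N(0, \Omega)$, $\Omega$ diagonal. This makes any real
$\eta$ a valid parameter set and the map $\eta \mapsto \psi$ a bijection
(`transform_to_natural()` / `transform_to_eta()`).

### Hazard of death

The hazard is proportional,
$$h(t) = h_0(t)\, e^{\beta f(t, \psi)},$$
with a Weibull baseline $h_0(t) = (k/\lambda)(t/\lambda)^{k-1}$ and no
baseline covariates. The link $f$ is a feature of the *true* PSA
trajectory: nothing (`none`), the current $\log(\mathrm{PSA}+1)$
(`current`, the reference model), its time derivative (`slope`), or its
running integral (`auc`). Survival conditional on the random effects is
$S(t \mid \psi) = \exp(-\int_0^t h(u)\,du)$, and
$\pi(s+t\mid s) = [S(s) - S(s+t)]/S(s)$, computed from the
cumulative-hazard increment so the ratio never underflows first.

### Default parameters

The defaults of `pop_params()` are the reference estimates of the
current-PSA model fitted to a 400-patient training cohort:

```{r}
pop_params()
```

$\beta$ is stored signed and configurable; the default $+0.32$ (on the
$\log(\mathrm{PSA}+1)$ scale) encodes that higher PSA raises the hazard,
the only clinically coherent orientation.

## Numerical choices

**Cumulative hazard.** The integral $\int_0^t h(u)\,du$ uses Gauss-Legendre
quadrature with 8 nodes per panel for all posterior computations, after the
change of variable $u = t v^{1/k}$ which absorbs the Weibull factor: the
transformed integrand is $\,(t/\lambda)^k \int_0^1 e^{\beta f(t v^{1/k})}dv$,
so the baseline-only integral is exact at any node count and the graded
nodes never touch $u=0$ (where the baseline diverges for $k<1$). Because
$f$ has a kink at $T_{esc}$, the integral is split there when the interval
spans it; without the split the kink dominates the error (about $2\times
10^{-3}$ relative at reference parameters versus $\le 2\times 10^{-5}$ with
it). The simulator inverts the survival function on a 64-node version of the
same rule, so simulated truth is always more accurate than the 8-node
inference machinery being evaluated. For the `auc` link the inner area
integral uses the same family, split at $T_{esc}$.

**Removable singularities.** The closed-form curve has denominators
$r(1-\varepsilon)-d+\delta$ and $r-d+\delta$; random-effect draws can land
arbitrarily close to the zero set (with the fixed reference constants it is
unreachable, but the code must not rely on that). Below $10^{-10}$
day$^{-1}$ in absolute value the analytic limit
$\delta\,PSA_0\, t\, e^{-\delta t}$-type term is used; tests verify the
exact-singular and nearly-singular evaluations agree.

**Kink convention.** At $t = T_{esc}$ the trajectory is continuous but not
differentiable; `log_psa_slope()` returns the left derivative there. The
slope enters integrals only through a set of measure zero, so the choice is
inconsequential but fixed.

**Overflow guard.** The linear predictor $\beta f$ is clipped at 700 with a
warning, so one extreme posterior draw cannot overflow `exp()` and crash a
Monte Carlo loop; draws whose survival at the landmark underflows to zero
are dropped from risk prediction with a reported count.

## Posterior sampling of the random effects

Given data up to the landmark, the target is
$$p(\eta \mid X > s, \mathcal{Y}(s)) \propto
  \Big\{\prod_j p(y_j \mid \eta)\Big\}\, S(s \mid g(\mu,\eta))\, p(\eta),$$
the printed factorisation (survival probability to $s$, no event density),
with the population parameters $\theta$ treated as known constants — their
estimation uncertainty is deliberately not propagated, which is reasonable
when they come from a large training cohort with small standard errors.
Subjects with *no* PSA values at the landmark remain predictable: the
target degenerates gracefully to prior times survival.

The sampler is defined by a contract, not an implementation: it must
reproduce the prior when no data inform it, and match importance-sampling
posterior means on toy subjects. `sample_posterior()` fulfils the contract
with an adaptive random-walk Metropolis chain: during 1000 warmup
iterations the proposal covariance tracks the empirical draw covariance
(scaled by $2.38^2/4$) while a Robbins-Monro update tunes a global scale
toward 30% acceptance; the frozen chain is then thinned (default every
15th iteration) so that exactly $L$ draws are retained, $L = 200$ by
default. The thinning default matters for interval calibration: the 95%
band is the 2.5-97.5% range of the retained draws, and strongly
autocorrelated draws make those empirical percentiles noisy enough to
erode coverage by several percent. Chains whose post-warmup acceptance
rate leaves $[0.05, 0.60]$ are flagged, never silently returned.

Each retained draw $\eta^{(\ell)}$ is mapped to
$\psi^{(\ell)}$, a predicted curve $y^{(\ell)}(u)$ and a risk
$\pi^{(\ell)}(s+t\mid s)$; point predictions are Monte Carlo medians and
the bands are the 2.5/97.5% percentiles.

## The simulator

`simulate_cohort()` generates the study conditions of the simulation
experiments: random effects from $N(0,\Omega)$, death times by inverting
each subject's survival function (bracketed root finding to $10^{-6}$ in
survival probability, 64-node quadrature), PSA sampled every 21 days from
treatment start (the baseline visit is always measured) until death or 30
months — 913 days at 30.4375 days/month, rounded to whole days — with
administrative censoring there and no other dropout mechanism; a
measurement never postdates death. Observable tables carry nothing derived
from the simulation truth; the truth block ($\eta$, $\psi$, uncensored
death time) is stored separately and written to its own CSV, so prediction
code cannot silently leak it while coverage evaluation can opt in.

What the simulator does *not* emulate about real trials: visit-schedule
irregularity (in practice PSA is measured less often after treatment
cessation), PSA-informed dropout, accrual structure, and model
misspecification of any kind. Green simulation tests therefore demonstrate
internal consistency of model, sampler and metrics — not transportability
to real cohorts, where published experience shows discrimination stagnates
rather than improves with later landmarks.

## Predictive-accuracy metrics

Discrimination and calibration are assessed with the time-dependent,
cumulative/dynamic definitions: at $(s, t)$, cases die in $(s, s+t]$ and
controls are event-free beyond $s+t$. Right censoring is handled by
inverse-probability-of-censoring weights based on the Kaplan-Meier
estimator $\hat G$ of the censoring distribution;
$\widehat{AUC}(s,t)$ is the weighted proportion of case-control pairs
ranked concordantly by $\hat\pi(s+t\mid s)$ and $\widehat{BS}(s,t)$ the
weighted mean squared difference between window death status and
prediction, with the number at risk at $s$ (not the weight sum) as
denominator. The scaled Brier score
$sBS = (BS_{KM} - BS)/BS_{KM}$ measures improvement over the marginal
Kaplan-Meier prediction $1 - S_{KM}(s+t)/S_{KM}(s)$; in the simulation
experiments the reference curve is the simulated cohort's own KM curve.

Three conventions are fixed where the estimator definitions are silent:

* **Ties.** Tied predictions contribute $1/2$ to the AUC numerator. Under a
  strict inequality a constant predictor would score 0, contradicting the
  defining property that a dummy $\hat\pi \equiv 0.5$ scores exactly
  $AUC = 0.5$ and $BS = 0.25$; the $1/2$ rule reconciles the two, and both
  identities hold exactly in the test suite.
* **Left-continuous $\hat G$.** Weights evaluate $\hat G$ at $u^-$, the
  standard IPCW practice ensuring a subject's own censoring event does not
  deflate its weight. With purely administrative censoring all weights
  inside the follow-up window are then exactly 1.
* **Administrative boundary.** Landmark/horizon grids are laid out in whole
  days, so the longest horizons end exactly at the censoring date (e.g.
  $s = 18$ mo, $t = 12$ mo gives $548 + 365 = 913$ d). A subject censored
  at exactly $s+t$ is a control — their vital status at $s+t$ is known —
  otherwise no controls would exist at the boundary and the metric there
  would be undefined. Horizons extending *past* the administrative date are
  skipped: no observable controls can exist there.
* **Degenerate windows.** Windows without a weighted case or control yield
  an `NA` marker, never a number; subjects whose required $\hat G$ value is
  0 are dropped with a reported count.

**Coverage.** For simulated cohorts the truth is known, so calibration of
the prediction intervals themselves is measured: per horizon, the
proportion of at-risk subjects whose true noise-free curve value
$b(s+t, \psi_{true})$ and true risk $\pi(s+t\mid s; \psi_{true})$ (64-node
quadrature) fall inside their bands, with the exact binomial 95% envelope
around 0.95 given the number at risk. The "true PSA value" is read as the
noise-free curve, not a noisy re-measurement; with the reference $\sigma$
the two readings differ visibly, and the noise-free one is what the bands
(built from noise-free curves) target.

## Problem sizes and test design

The package's own test suite runs a half-size replicate of the simulation
study — 100 subjects, $L = 100$, landmarks $\{0, 6, 12, 18\}$ months,
horizons 2-18 months in half-month steps — with tolerances widened to
about two standard errors at that size ($\pm 0.13$ on AUC values around
0.8); `scripts/acceptance.R` runs the full 200-subject, $L = 200$ study.
Coverage is judged per landmark and quantity by requiring at least 80% of
per-horizon points inside the exact binomial envelope and the
across-horizon mean inside it: points along the horizon axis share
subjects and are strongly correlated, so occasional boundary excursions of
a single correlated cluster are expected even under perfect calibration.
One finite-sample fact matters here: a band built from the empirical
2.5-97.5% percentiles of $L$ draws has attainable mass
$0.95\,(L-1)/(L+1)$, about 0.931 at $L = 100$ and 0.941 at $L = 200$, by
the usual order-statistics argument. The half-size replicate therefore
centres its envelope on the $L = 100$ attainable nominal, while the
full-size study is reported against 95% itself.
At $s = 18$ months intervals are known to be anti-conservative in this
model class (posterior concentration outpaces its own calibration when
most of the trajectory is observed), which is why the coverage contract
applies to $s \in \{0, 6, 12\}$.

Independent oracles back every nontrivial computation: an ODE solve of the
underlying cell/PSA system for the closed-form curve, adaptive quadrature
for areas and cumulative hazards, Weibull closed forms for the no-link
limit, exhaustive pair enumeration for the IPCW estimators, a
million-particle importance sampler for posterior means, and Monte Carlo
survival curves for the event-time inversion.

## Known limitations

* The population parameters are inputs; the package does not estimate them
  (no SAEM), and their uncertainty is not propagated into predictions.
* $\Omega$ is diagonal by construction; correlated random effects are out
  of scope.
* The random-walk sampler trades gradient information for robustness at the
  $T_{esc}$ kink; it needs thinning to deliver nearly independent draws,
  and very informative landmarks (many observations) concentrate the
  target enough that warmup adaptation matters — the acceptance-rate flag
  should be monitored in bulk runs.
* Prediction-interval coverage degrades at late landmarks ($s = 18$
  months), consistent with the model class, not with a sampler defect.
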