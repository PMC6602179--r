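---
title: "Geostatistical Weibull survival models with spatially varying intervention coefficients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geostatistical Weibull survival models with spatially varying intervention coefficients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svcsurv)
```

## The model

svcsurv relates region-level coverage of a health intervention to under-five
mortality recorded by a georeferenced household survey. Child $j$ in survey
cluster $s_i$ contributes a right-censored survival time $t_j(s_i)$ in months
(time to death before age 60 months, or age at interview) with hazard

$$h(t_j(s_i)) = \delta\, t_j(s_i)^{\delta - 1}
  \exp\{\beta^\top X_j(s_i) + (a + w_{q(i)}) Z_{q(i)} + \phi(s_i)\},$$

where

* $\delta$ is the Weibull shape. Under-five mortality is concentrated in
  infancy, so $\delta < 1$ (declining hazard) is the typical regime.
* $X_j$ are child, maternal and household adjustment covariates (dummy-coded,
  with an intercept that carries the baseline hazard scale, since
  $h_0(t)=\delta t^{\delta-1}$ has none).
* $Z_q$ is the coverage of one intervention in region $q$, expressed in units
  of `coverage_unit` (default 0.10, i.e. ten percentage points). The
  coefficient is $a + w_q$: a national effect $a$ plus a regional deviation
  $w_q$, so $\exp(a)$ is the national hazard rate ratio (HRR) per coverage
  unit and $\exp(a + w_q)$ the regional one.
* $w \sim N(0, \sigma_q^2 (I - \gamma C)^{-1} D)$ is a proper conditional
  autoregressive (CAR) field on the region adjacency graph: $C$ is the
  row-normalised proximity matrix ($C_{kl} = \omega_{kl}/g_k$), $D$ is
  diagonal with $D_{kk} = 1/g_k$, and $\gamma$ measures spatial dependence,
  supported on $(1/\lambda_{\min}, 1/\lambda_{\max})$ of the symmetrised
  proximity $D^{-1/2} C D^{1/2}$ (upper bound 1 on a connected graph).
* $\phi \sim N(0, \sigma^2 R)$, $R_{kl} = \exp(-d_{kl}\rho)$, is a
  cluster-level Gaussian-process frailty in great-circle distance $d_{kl}$
  (haversine, mean Earth radius 6371.0 km). The *effective range*
  $-\log(0.05)/\rho$ is the distance at which the residual spatial
  correlation falls to 0.05.

Priors follow common practice for this model family:
$\sigma^2, \sigma_q^2 \sim \mathrm{IG}(2.01, 1.01)$ (mean 1, heavy tailed);
$\rho \sim U(a_\rho, b_\rho)$ with the bounds chosen so the effective range
lies between the smallest and largest observed inter-cluster distances
([rho_bounds()]); $\gamma$ uniform on its eigenvalue support;
$\delta \sim \mathrm{Exp}(0.01)$; and $\beta_l, a \sim N(0, 10^3)$.

One model is fitted per intervention: each fit reports its own national and
regional HRRs, effective range and variance parameters, which is how results
are tabulated downstream.

### Screening stage

Before the spatial fit, candidate adjustment covariates are screened with
univariable (non-spatial) Weibull proportional-hazards fits
(`fit_univariable()`, BFGS on $(\log\delta, \beta_0, \beta)$ with analytic
gradient); a covariate enters the spatial model when its Wald p-value is
strictly below 0.15 (`screen_covariates()`). For multi-level covariates the
minimum level-wise p decides — the most permissive reading, consistent with
covariate-level inclusion. Wald p-values are the default; a likelihood-ratio
variant is available (`p_method = "lr"`), and at survey sample sizes the two
agree closely.

## Estimation

`svc_sample()` is an adaptive Metropolis-within-Gibbs sampler whose target is
exactly the joint posterior defined by `log_posterior()`. The protocol
defaults mirror the estimation the model family is usually run with: two
chains of 300,000 iterations, 15,000 burn-in, convergence assessed by the
Gelman–Rubin potential scale reduction factor (the simplified form
$\sqrt{\hat V / W}$ with $\hat V = \frac{n-1}{n} W + (1 + \frac1m)\frac{B}{n}$,
degrees-of-freedom correction omitted). Thinning (default 30) and the
adaptation window (default: the burn-in) are implementation choices.

The update scheme matters in this model because the likelihood only
constrains certain combinations of parameters:

* the likelihood sees the *region slopes* $s_q = a + w_q$, not $a$ and $w$
  separately; the split is resolved purely by the CAR prior (centred at
  zero) against the vague prior on $a$;
* the intercept trades off against the frailty mean $\bar\phi$ and against
  a common shift of the slopes;
* the Weibull shape trades off against the baseline scale (the intercept).

The sampler therefore combines componentwise random-walk scans for $w$ and
$\phi$ (using the sparse CAR precision $(\mathrm{diag}(g)-\gamma\omega)/\sigma_q^2$
and the GP precision) with three dedicated ridge moves: an *exact Gibbs*
recentering of $a$ against $w$ (the conditional of the shift is Gaussian
because the move is likelihood-invariant), the analogous Gibbs recentering of
$\beta_0$ against $\phi$, and a Metropolis "level" move trading a common
slope shift against the intercept. The remaining covariate coefficients are
updated jointly with an adapted multivariate-normal proposal; the intercept
and $a$ are deliberately excluded from that adaptation because their
ridge marginals are heavy-tailed and would freeze the block. The shape
update walks along the direction $(\log\delta, \beta_0)$ that keeps the
hazard fixed at the typical death time. Variance/decay/dependence pairs
$(\sigma^2, \rho)$ and $(\sigma_q^2, \gamma)$ are updated jointly on log /
bounded-logit scales; neither touches the data likelihood, only the GP/CAR
densities. Scalar proposals adapt toward 44% acceptance and vector proposals
toward 23.4% with a diminishing Robbins–Monro gain, frozen after the
adaptation window.

Two consequences of the weak identification are worth knowing:

* the **intercept** and the **national effect $a$** have wide, heavy-tailed
  posteriors whenever $\gamma$ can approach 1 (a proper CAR degenerates
  towards the intrinsic CAR there, making common shifts of $w$ nearly free).
  This is a property of the model, not of the sampler; the ridge Gibbs moves
  make the chains traverse it so that the Gelman–Rubin diagnostic is honest.
* point estimates of $a$ inherit that spread: on synthetic surveys of 60
  clusters / 4,000 children its posterior median is typically within
  0.1–0.25 of the truth while the 95% interval is far wider. Regional HRRs
  $\exp(a + w_q)$, which the likelihood does constrain, are much better
  behaved.

`svc_sample(..., prior_only = TRUE)` drops the data term entirely, a standard
correctness check: each hyperparameter's marginal draws must then reproduce
its prior (the inverse-gamma variance prior has mean 1.0). `fix=` freezes
chosen blocks, which the tests use to compare a one-parameter reduction
against dense-grid numerical integration.

## The synthetic survey generator

`generate_survey()` draws a complete DHS-like survey from the model's own
generative process, with `truth.json` recording every parameter and latent
draw so downstream stages can be tested by parameter recovery. Defaults
emulate the Burkina Faso DHS 2010 study conditions: the shipped 13-region
adjacency graph (transcribed by hand from the administrative map; a
`grid_region_graph()` alternative exists so tests do not depend on one
topology), 541 clusters, 13,505 children, categorical covariate marginals
matching the published sample composition, and region-level coverage from
the shipped Table of the 16 interventions. Clusters are placed uniformly in
boxes around region centres compacted to span roughly 400 × 400 km, which
brackets the 8–71 km scale of the spatial-range estimates these surveys
produce. Censoring is at an interview age drawn Uniform(0, 60) months —
the real censoring-time distribution of such a survey is not published, so
this is a stand-in, not a claim about any particular survey.

Default spatial parameters: $\delta = 0.5$ (infant-concentrated mortality),
$\sigma^2 = 0.15$ with $\rho = 0.1$/km (effective range ≈ 30 km),
$\sigma_q^2 = 0.005$ per coverage unit with $\gamma = 0.5$. The CAR variance
looks small but multiplies a coverage covariate of 4–10 units, so it yields
regional log-hazard swings of roughly ±0.5 — the 2–3× spread of regional
under-five mortality these surveys report. The intercept −4.3 is the
calibration preset, tuned once by pilot simulation so the default survey
yields an observed death fraction near 9% (0.07–0.10 across seeds).

Simulated survival times are floored at $10^{-3}$ months, purely to keep
times strictly positive. A coarser floor (say a quarter month) would place
several percent of deaths in a boundary atom and bias the Weibull shape
estimate upward by about 0.05 at $\delta = 0.5$ — enough to defeat parameter
recovery. Real month-resolution data are different: deaths *recorded* at age
0 are shifted to 0.25 months by `read_children()` (with a logged count), the
conventional handling that keeps $\log t$ finite.

What the generator does **not** emulate: the two-stage cluster sampling
design and its weights (the model itself does not use them), household
structure below the cluster, month-resolution rounding of ages, recall bias
in retrospective birth histories, and missing-data patterns. Passing
recovery tests therefore show the estimation machinery is correct for data
from this model, not that the model is adequate for any particular survey.

## Reporting

`regional_hrr()` summarises $\exp(a)$ (national) and $\exp(a + w_q)$
(regional) draws as posterior medians with equal-tailed 95% credible
intervals (type-7 linear-interpolation quantiles; monotone transforms are
applied to draws first, which commutes with quantiles at order statistics).
An association is *important* when the interval excludes 1, and *protective*
when additionally the median is below 1. `count_protective()` counts, per
region, the interventions whose interval upper bound is strictly below 1 —
harmful-important entries (lower bound above 1) are reported but never
counted as effective. Applied to the shipped table of published HRR
intervals for the Burkina Faso DHS 2010 (16 interventions × 13 regions),
this reproduces the published spread: minimum 0 (Hauts Bassins), median 3,
maximum 11 (Centre-Est), with Sud-Ouest at 7. Two printed rows (ITN use in
Nord, family planning in Centre-Ouest) have interval upper bounds below 1
but no importance star; the counts treat them by the interval rule, and the
min/median/max are robust to either treatment. The published text credits
Sahel with eight effective interventions while its printed intervals give
nine; no counting rule reproduces eight, so the discrepancy is flagged
rather than resolved.

`km_5q0()` reports 1000·(1 − KM survival at 60 months) — a product-limit
proxy for under-five mortality per 1,000, distinct from both the raw death
fraction (`death_fraction()`, which censoring dilutes) and the survey-report
life-table statistic, which is out of scope. The two are labelled
distinctly and must not be compared directly.

## Numerical choices

* Distances: haversine on the 6371.0 km mean-radius sphere, in km.
* Effective range constant: the exact $-\log(0.05) \approx 2.9957$, used
  consistently in `rho_bounds()` and `effective_range()` so that the range
  evaluated at the bounds reproduces the extreme observed distances exactly.
* GP covariances get a $10^{-8}\sigma^2$ diagonal jitter; if a Cholesky
  factorisation still fails the jitter escalates by decades (with a warning)
  before erroring out.
* CAR densities use the sparse precision and the eigenvalues of the
  symmetrised proximity for the determinant, so no $Q \times Q$ inverse is
  formed during sampling.
* States outside the prior support evaluate to $-\infty$, never an error, so
  proposals can roam freely.
* Initialisation: $\delta = 1$, $\beta = a = 0$, $w = \phi = 0$,
  $\sigma^2 = \sigma_q^2 = 0.5$, $\rho$ at the middle of its support,
  $\gamma = 0$; the second chain jitters all components by $N(0, 0.1^2)$.
* Incremental caches of the linear predictor are refreshed from scratch
  every 2,000 iterations to stop floating-point drift.

## Problem sizes used by the tests

The test suite exercises every stage at sizes chosen to make the checks
statistically sound while completing in minutes: parameter recovery runs the
full model on surveys of 60 clusters / 4,000 children over the 13-region
graph with 20,000 iterations × 2 chains at three seeds (coverage of
$\delta$, $a$ and each $\beta$ in at least 2 of 3 seeds, PSRF ≤ 1.1);
generative-consistency checks compare empirical covariances of 20,000–100,000
simulator draws with the closed forms entrywise within 5%, on fixtures whose
correlations are moderate so the Monte-Carlo error sits well inside the
band; screening calibration uses 1,000 null replicates of n = 500. The
one-parameter sampler validation integrates the reduced posterior on a
4,000-point grid.

## Worked example

```{r example, eval = FALSE}
library(svcsurv)

# a survey at study-like scale, with known truth
survey <- generate_survey(sim_config(seed = 1))
death_fraction(survey$children)   # ~0.09
km_5q0(survey$children)           # ~130 per 1000

# screening
scr <- screen_covariates(survey$children, c("sex", "residence", "education"))
included_covariates(scr)

# one intervention model, scaled down for illustration
cfg   <- sim_config(n_clusters = 60, n_children = 4000, seed = 1)
small <- generate_survey(cfg)
model <- svc_model(small$children, small$frame, small$graph, small$coverage,
                   intervention = "dpt3_immunization",
                   adjust = c("sex", "residence"),
                   reference = default_references())
fit <- svc_sample(model, mcmc_config(n_iterations = 20000, burn_in = 2000,
                                     thin = 10, seed = 1, adapt = 10000))
tidy(fit, exponentiate = TRUE)
glance(fit)

hrr <- regional_hrr(fit)
plot_hrr_forest(hrr)
effective_range(fit)
count_protective(hrr)
```

## Known limitations

* The national effect $a$ is weakly identified (see above); its credible
  intervals are honest but wide, and its point estimate should be read with
  that in mind. The regional slopes are the better-identified quantities.
* No predictive kriging, spatio-temporal extension, or model comparison
  (DIC/WAIC) is provided.
* Survey design weights are not used, matching the model being reproduced.
* The coverage covariate's unit is a convention (`coverage_unit`); published
  HRR tables rarely state theirs, so cross-study comparisons of $\exp(a)$
  need care. Both per-unit conventions are supported; none is asserted as
  the published one.
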