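---
title: "Corrected likelihood-ratio tests under latent, error, and marginal non-normality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corrected likelihood-ratio tests under latent, error, and marginal non-normality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semlrt)
```

## The problem

The likelihood-ratio model test in structural equation modeling compares a
hypothesized covariance structure $\Sigma(\theta)$ against the saturated
model. With $p$ observed variables, sample covariance matrix $S$, and the
maximum-likelihood discrepancy

$$F_{ML} = \ln|\Sigma(\hat\theta)| - \ln|S| +
  \mathrm{tr}\,[S\,\Sigma(\hat\theta)^{-1}] - p,$$

the statistic $T_{ML} = \hat F_{ML}(N-1)$ follows a central chi-square with
$df = p(p+1)/2 - q$ degrees of freedom when the data are multivariate
normal and the model holds. Under non-normality the correct limit is a
weighted mixture $\sum_{j=1}^{df} w_j\,\chi^2_1$, where the $w_j$ are the
non-null eigenvalues of $U\Gamma$: $\Gamma$ is the asymptotic covariance of
$\sqrt{N-1}(s - \sigma_0)$ (estimated from centered fourth moments), and

$$U = W^{-1} - W^{-1}\Delta(\Delta'W^{-1}\Delta)^{-1}\Delta'W^{-1}$$

is the residual weight matrix built from the normal-theory weight matrix
$W$ (elements $\sigma_{ik}\sigma_{jl} + \sigma_{il}\sigma_{jk}$, evaluated
at $\Sigma(\hat\theta)$) and the model Jacobian
$\Delta = \partial\sigma/\partial\theta'$. When the weights disperse around
one, referring $T_{ML}$ to the unweighted chi-square misstates the p-value,
which motivates the corrections the package implements:

* $T_M = T_{ML}/c$ with $c = \mathrm{tr}(\hat U\hat\Gamma)/df$ (mean
  scaling);
* $T_{MB} = T_M\,[1 - (2p + 4h + 5)/(6(N-1))]$ (Bartlett small-sample
  factor, $h$ latent factors);
* $T_{MV1} = d\,T_{ML}/\mathrm{tr}(\hat U\hat\Gamma)$ referred to a
  fractional $d = [\mathrm{tr}(\hat U\hat\Gamma)]^2 /
  \mathrm{tr}[(\hat U\hat\Gamma)^2]$ (mean and variance);
* $T_{MV2}$, the scale-and-shift variant with reference $df$;
* $T_{MS} = v\,T_{ML}/\mathrm{tr}(\hat U\hat\Gamma)$ with
  $v = \mathrm{tr}[(\hat U\hat\Gamma)^2]^3 /
  \mathrm{tr}[(\hat U\hat\Gamma)^3]^2$ (mean and skewness);
* $T_{mix}$: the uncorrected value referred directly to the estimated
  weighted mixture.

A single `analyze_sample()` call computes all seven p-values plus the
derived RMSEA and CFI for each statistic, with the same correction applied
to the independence null model that the CFI requires.

One algebraic remark: because $d \le df$ (Cauchy–Schwarz on the weights),
the shift term of $T_{MV2}$ is nonnegative and the statistic never drops
below zero; small $T_{ML}$ simply yields a p-value near one.

## Population model

The package ships a three-factor model with fifteen standardized
indicators, six secondary loadings, factor correlations 0.3/0.2/0.3, and
unit marginal variances, both as matrix literals (`default_loadings()`)
and as delimited text under `inst/extdata/`. Fitting the
no-secondary-loadings specification to $\Sigma_0$ gives the population
misfit:

```{r population}
pop <- population_model()
spec <- model_spec("misspecified")
F0 <- population_minimum(spec, pop$sigma0)
F_nm <- population_minimum(model_spec("null"), pop$sigma0)
c(F0 = F0, rmsea0 = rmsea0(F0, spec$df), cfi0 = cfi0(F0, F_nm),
  power_200 = expected_power(F0, spec$df, 200, .05))
```

Degrees of freedom are always computed from the specification (81 for the
full pattern, 87 without secondary loadings, 105 for the independence
model), never hard-coded. Expected power uses a noncentral chi-square with
noncentrality $F_0(N-1)$, matching the Wishart statistic; using $N$
instead of $N-1$ moves the third decimal only.

## Estimation engine

`fit_cfa()` minimizes $F_{ML}$ by `nlminb` with analytic gradients, then
polishes with damped Newton steps on the interior parameters until the
projected gradient infinity-norm falls below $10^{-10}$ (or stalls; the
convergence flag requires $10^{-6}$). Choices that matter:

* **Parameterization.** Factor variances fixed to one; free parameters
  ordered loadings, factor correlations, residual variances; all matrix
  bases share one column-major lower-triangle (vech) convention.
* **Starting values.** Primary loadings 0.5, secondary loadings 0, factor
  correlations 0.2, residual variances 0.5 — neutral and reproducible, so
  refits of the same matrix are bit-identical.
* **Bounds.** Residual variances are bounded below at $10^{-6}$; an active
  bound is flagged as a Heywood case and the Monte Carlo harness discards
  and redraws such samples, as it does non-convergent ones.
* **Sample covariance** uses the $N-1$ divisor, consistent with the
  statistic's scaling. $\hat\Gamma$ uses the conventional biased divisor
  $N$ and is evaluated from the raw data at the sample mean, not from
  model residuals.

The eigenvalue weights are computed from the symmetric form
$\hat\Gamma^{1/2}\hat U\hat\Gamma^{1/2}$; eigenvalues below
$-10^{-10}\times$ the largest are clipped at zero with a warning. The
mixture tail probability uses characteristic-function inversion (Imhof's
method, absolute tolerance $10^{-9}$) with an exact scaled chi-square
shortcut when all weights are equal and a $10^6$-draw Monte Carlo fallback
if the quadrature fails.

## The data generator

Every indicator is a sum $X_i = L_i + E_i$: the $L_i$ are correlated
across indicators, the $E_i$ are independent of everything else. The
generator controls *where* non-normality enters while preserving
$\Sigma_0$ exactly in expectation:

* **normal** — multivariate normal via spectral factorization of
  $\Sigma_0$ (this is also the marginal condition at kurtosis 3);
* **latent** — the $L_i$ are non-normal with the correlation structure of
  the common parts (NORTA: correlated normals pushed through quantile
  functions with pairwise-calibrated intermediate correlations), the
  $E_i$ normal;
* **error** — the $L_i$ are exactly the normal common part
  $\Lambda\Phi\Lambda'$, the $E_i$ are independent non-normal variables
  scaled by the residual standard deviations;
* **marginal** — non-normality is induced directly in the indicators by
  Vale–Maurelli: Fleishman third-order polynomials in normals with
  intermediate correlations solved from the cubic moment equation.

Marginal shapes come from quantile mixtures
$F^{-1}(u) = \sum_m \beta_m F_m^{-1}(u)$ over fixed component sets per
condition: t(4.1) + uniform (latent, kurtosis 3); cubed normal + uniform +
normal (error, kurtosis 3); log-normal(0,1) + exponential(1) (kurtosis 10,
and latent at 17); standard normal + a log-normal/negative-log-normal
probability mixture (error, kurtosis 17). Weights are fitted so the
*indicator* reaches the target kurtosis: fourth cumulants add across
independent summands, so a non-normal part carrying variance share $v$
must reach component kurtosis $3 + (k-3)/v^2$. Mixture moments are
polynomial in $\beta$ with cross-moment coefficients computed by adaptive
quadrature; pure component moments use closed forms, which matters for
t(4.1) — its fourth moment (kurtosis 63) has roughly a quarter of its
mass beyond double-precision quantile range and any direct quadrature
underestimates it badly.

**Variance split.** The error condition uses the natural split:
$\mathrm{Var}(E_i)$ equals the residual variance $\theta_i$. The worst
case is then component kurtosis $3 + 14/0.36^2 = 111$, just inside the
log-normal ceiling of about 113.9 — which is why the kurtosis-17 error
condition needs the heavy sign-mixture component, whose positive-branch
probability is raised per indicator to the smallest value with 5%
headroom over its target. For the latent condition a communality-only
split is infeasible: communalities run down to 0.16, which would demand
component kurtosis near 550. The package instead assigns
$v_i = \max(c_i + 0.1,\ 0.5)$: at least half of each indicator's variance
is carried by the correlated non-normal part (worst-case component
kurtosis 59), and the margin above the communality keeps the latent
correlation block well-conditioned, so the NORTA intermediate matrix
stays (near) positive definite. The intermediate matrix is additionally
refined: after the positive-definiteness repair, implied correlations are
re-evaluated by quadrature and the pairwise targets re-adjusted until the
worst implied error is below $5\times10^{-4}$.

**Skewness.** Only kurtosis targets are part of the design; the marginal
(Vale–Maurelli) condition reuses the per-indicator skewness implied by
the latent condition's fitted mixtures at the same kurtosis, so both
share their first four marginal moments. The error condition's implied
skewness differs (its split is fixed by the model), which is unavoidable:
no single skewness value can be shared by all three sources once the
variance splits differ.

## What the generator emulates — and what it does not

At calibration scale ($N = 10^6$) the sample covariance matches
$\Sigma_0$ with no measurable systematic bias, and the analytic marginal
kurtosis equals the target exactly. Two caveats define what passing tests
show about real data. First, for heavy-tailed cells (component kurtosis
up to 111) the *sample* kurtosis at $N = 10^6$ is itself median-biased
low by order one — the light-tailed Vale–Maurelli cells land within 0.15
of the target while the log-normal-based latent cells realize mean
marginal kurtosis near 16 for a target of 17. That is estimator
behaviour, not miscalibration. Second, at kurtosis 3 the latent and error
constructions are multivariate non-normal with normal-matching marginal
skewness and kurtosis; the error construction has *identically zero*
fourth-order cumulants (independent symmetric components with kurtosis
exactly 3), so its non-normality is invisible to Mardia's kurtosis and
only appears from sixth moments on. Tests therefore check multivariate
non-normality at kurtosis 3 with the sixth-order Mahalanobis moment,
whose normal-theory value is $p(p+2)(p+4)$.

The generator reproduces the study's moment targets, not any particular
empirical data set: real indicators have skewness–kurtosis combinations,
dependence in higher moments, and floor/ceiling effects the quantile
mixtures do not emulate.

## Monte Carlo harness

`run_condition()` draws until it has `reps` valid replications: samples
whose model fit converged without a Heywood bound are kept, others are
*replaced by a fresh sample* under a new derived seed (never restarted
from new initial values), with a retry budget of ten times `reps`. Seeds
follow a counter-based schedule (master seed, condition index,
replication attempt), so any single replication is reconstructible in
isolation and aggregation is order-insensitive. Rejection uses
$p \le \alpha$ with $\alpha = .05$ by default, the Bradley band is the
closed interval $[2.5\%, 7.5\%]$, and fit-index point estimates are
medians across replications. `run_study()` crosses
3 sources $\times$ 3 kurtosis levels $\times$ 4 sample sizes $\times$ 2
specification statuses (72 cells).

Problem sizes in the shipped tests are chosen to keep a desk-scale run:
500 replications for the nominal-level baseline ($N = 1000$) and the
power spot checks ($N = 200$), 250 per cell for the eight-cell type-I
inflation scan, and $N = 10^6$ for generator calibration; each cell of
the full 1000-replication design remains reproducible through
`run_condition()` with the same seed schedule.

```{r small-run}
res <- run_condition(
  condition_spec("latent", 17, N = 200, specification = "misspecified",
                 reps = 50, seed = 7))
res$summary[, c("statistic", "rejection_rate", "median_rmsea", "median_cfi")]
```

(The pattern at full replication counts: the uncorrected and
Bartlett-corrected scaled statistics keep their power, while the
higher-moment corrections — most visibly the third-moment adjustment —
lose a large share of it under latent non-normality at kurtosis 17.)

## Known limitations

* Mean structures, multiple groups, and discrepancy functions other than
  normal-theory ML are out of scope, as are parameter standard errors,
  categorical indicators, and missing data.
* The NORTA intermediate-correlation search saturates at $\pm 0.999$;
  targets just beyond the attainable comonotone bound are clamped during
  refinement sweeps.
* The type-I inflation of the uncorrected statistic under latent
  non-normality peaks near 28–31% in this generator (eight-cell scan at
  250 replications); the magnitude of that headline number is sensitive
  to the unpublished details of the original generator's variance split
  and skewness targets, while the qualitative ordering (latent far above
  error, corrections restoring the level) is stable.
* The uncorrected CFI is deliberately not floored inside its misfit ratio
  while the corrected variants are (their printed formulas include the
  floor); `cfi_sample(..., floor_ml = TRUE)` restores symmetry if wanted.
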