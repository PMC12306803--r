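---
title: "One-step penalized functional GEE: models, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-step penalized functional GEE: models, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgee)
```

## The model

`fgee` fits marginal function-on-scalar regressions for longitudinal
functional outcomes.  Data consist of clusters $i = 1, \dots, N$ (e.g.
neurons in a recording study), longitudinal observations $j = 1, \dots, n_i$
within each cluster (e.g. trials), and a shared, evenly spaced grid of
functional-domain points $s_1 < \dots < s_L$ (e.g. within-trial time).  The
marginal mean model is

$$ g\!\left(E[Y_{i,j}(s) \mid X_{i,j}]\right)
   = \beta_0(s) + \sum_{r=1}^q X_{i,j,r}\,\beta_r(s), $$

with $g$ the identity, logit, or log link.  Each coefficient function is
expanded in $m$ B-splines, $\beta_r(s) = \sum_d \theta_{r,d} B_d(s)$, so the
whole model is parameterized by $\theta \in \mathbb{R}^p$, $p = m(q+1)$.
Estimation solves the penalized estimating equation

$$ \sum_{i=1}^N D_i^\top V_i^{-1} (Y_i - \mu_i) - \Lambda S \theta = 0, $$

where $V_i$ is a *working* covariance for the stacked cluster outcome, $S$
is a block-diagonal second-order difference penalty, and $\Lambda$ carries
one smoothing parameter per coefficient function.  No likelihood is
assumed; if the mean model is correct, the sandwich variance yields valid
inference even when $V_i$ is misspecified.

## The one-step estimator

Solving the weighted equation iteratively requires repeated inversion of
$n_i L \times n_i L$ covariances.  `fgee()` instead:

1. fits a working-independence penalized GLM (the "FoSR" initial fit
   $\hat\theta^{(0)}_{\Lambda_0}$) — cheap because no covariance is
   inverted;
2. estimates the intra-cluster correlation curve $\hat\rho(s)$ from Pearson
   residuals;
3. takes **one** Newton–Raphson step under the chosen working covariance:
   $$ \hat\theta^{(1)}_{\Lambda_1} = \hat\theta^{(0)}_{\Lambda_0} +
      \Big(\tfrac1N \sum_i W_i + \Lambda_1 S\Big)^{-1}
      \Big(\tfrac1N \sum_i b_i - \Lambda_1 S\,\hat\theta^{(0)}\Big), $$
   with per-cluster quadratic forms
   $W_i = \sum_s D_i(s)^\top \hat V_i(s)^{-1} D_i(s)$ and
   $b_i = \sum_s D_i(s)^\top \hat V_i(s)^{-1}(Y_i(s) - \hat\mu_i(s))$;
4. re-estimates $\hat\rho(s)$ at $\hat\theta^{(1)}$ and computes the
   sandwich variance, pointwise intervals, and joint bands.

For a Gaussian identity-link model at fixed $\hat\rho$ the estimating
equation is linear in $\theta$, so the single step lands exactly on the
fully-iterated solution; in general it is asymptotically as efficient as
full iteration.  The correlation curve is estimated twice on purpose: once
at $\hat\theta^{(0)}$ (plugged into the update) and once at
$\hat\theta^{(1)}$ (plugged into the variance).

## Working covariances without big matrices

$V_i$ is block-diagonal over grid points,
$V_i(s) = A_i^{1/2}(s) R_i(s) A_i^{1/2}(s)$ with $A_i(s)$ the variance
function values, and all inverse applications cost $O(n_i)$:

* **independence** — $R = I$, so $V = A$ and the estimating equation is the
  penalized GLM score;
* **exchangeable** — the Sherman–Morrison closed form of the inverse; the
  moment estimator of $\rho(s)$ averages residual cross-products over
  ordered within-cluster pairs $j \neq k$ with divisor $n_i(n_i - 1)$;
* **AR(1)** — $R_{jj'} = \rho(s)^{|j-j'|}$; the Toeplitz system is solved
  through the analytic tridiagonal form of the AR(1) correlation inverse,
  and $\rho(s)$ is the cluster-averaged lag-1 Yule–Walker ratio (equally
  spaced observations assumed).

Because the working dispersion is fixed at 1, Pearson residuals carry the
pointwise dispersion $\phi(s)$; `estimate_rho()` standardizes residuals by
$\sqrt{\widehat\phi(s)}$ before the moment estimator so the exchangeable
estimate is a correlation (the Yule–Walker ratio is scale-invariant).
Estimates are truncated to $[-1 + \epsilon, 1 - \epsilon]$ (exchangeable)
or $[0, 1 - \epsilon]$ (AR1) with $\epsilon = 10^{-3}$, and the
exchangeable curve is additionally bounded below by
$-1/(\max_i n_i - 1) + \epsilon$ so every cluster's $R_i(s)$ stays positive
definite.  An optional centered running-mean smoother (window
$\max(5, L/10)$ points, off by default) can reduce the variability of
$\hat\rho(s)$.

## Smoothing parameters

Two penalties play different roles and are chosen differently:

* $\Lambda_0$ (initial fit): selected by fast REML.  `fit_initial()`
  delegates to `mgcv::bam()` with P-spline smooths built on this package's
  exact knot vector, so the fitted curves live in the same basis; the
  coefficients are recovered by exact projection, and the REML smoothing
  parameters are mapped back to this package's penalty scale through the
  score identity $\mathbb{X}^\top(y - \hat\mu) = \Lambda_0 S \hat\theta$.
  A GCV-within-IRLS alternative (`method = "gcv"`) is provided; REML is the
  default because it is the standard for penalized regression splines and
  its behavior under intra-cluster correlation (a tendency to smooth more)
  is part of what the benchmarks are meant to exhibit.
* $\Lambda_1$ (one-step): selected by fast K-fold *cluster*
  cross-validation (`tune_lambda1()`, default $K = 10$, folds always split
  clusters, never observations).  The fold estimates reuse the full-sample
  initial fit and the full-sample Hessian factorization, so the whole
  search performs exactly one $p \times p$ factorization per candidate —
  an instrumented invariant of the implementation.  Stage 1 searches a
  shared multiplier $c \in [10^{-4}, 10^4]$ (15 log-spaced points) on the
  anchor $\Lambda_0 / N$; the division by $N$ converts the initial fit's
  summed-equation penalty to the averaged-equation scale of the update.
  Stage 2 refines each coefficient's parameter with up to two sweeps of
  local moves at the grid spacing.  Ties prefer the smoother candidate.
  The CV criterion is the held-out negative working log-likelihood.

Basis defaults follow the simulation studies: cubic B-splines on 10 equal
knot spans ($m = 13$ per coefficient), second-order difference penalty.
The spline order, knot count, and penalty order are configurable.

## Inference

* **Sandwich variance** (`sandwich_variance()`):
  $\widehat{\mathrm{Var}}(\hat\theta) = N^{-1}\hat H^{-1}\hat M\hat H^{-1}$
  with $\hat H = P_N[D^\top \hat V^{-1} D] + \Lambda S$ and
  $\hat M = P_N[U U^\top]$, $U_i = b_i - \Lambda S \hat\theta$.  Curve
  standard errors come from $B\,\hat\Sigma_r^{(\theta)}B^\top$.
* **Fast cluster bootstrap** (`fast_cluster_bootstrap()`): resamples whole
  clusters with replacement and recomputes the one-step from the cached
  $b_i$, keeping $\hat\theta^{(0)}$ and the Hessian factorization fixed, so
  each draw is one matrix–vector product.  The identity resample
  reproduces $\hat\theta^{(1)}$ exactly.
* **Pointwise CIs**: $\hat\beta_r(s) \pm z_{1-\alpha/2}\,
  \hat\sigma_r^{(\beta)}(s)$.
* **Joint bands** (`joint_ci()`): per coefficient, the band multiplier
  $\tilde q_{1-\alpha}^{(r)}$ is the empirical $(1-\alpha)$ quantile of max
  statistics over draws from the estimated sampling distribution of
  $\hat\theta_r$ (parametric normal draws by default, centered bootstrap
  draws optionally).  The default statistic is studentized on the curve
  scale, $\max_s |B\tilde\theta_r|(s)/\hat\sigma_r^{(\beta)}(s)$, with
  absolute values because the band is two-sided; a spline-coefficient-scale
  variant (`statistic = "theta"`) is provided.  The multiplier is floored
  at $z_{1-\alpha/2}$, which makes the nesting of pointwise intervals
  inside joint bands an exact finite-$T$ property rather than an asymptotic
  one.

A caveat the simulations make visible: with few clusters (tens) and
$p \approx 40$ spline coefficients, the plug-in $\widehat{\mathrm{Var}}$ is
noisy, and the max over $L = 100$ grid points is sensitive to that noise.
Pointwise coverage stays near nominal while joint bands can fall several
points short of their nominal level.  Reports of conservative joint
coverage elsewhere in this literature depend on the exact studentization
convention of the max statistic; this package deliberately uses standard
errors (not variances) as the denominator, since anything else is
unit-inconsistent with the band $\pm\,\tilde q\,\hat\sigma(s)$.

## The synthetic-data generators

`gen_sim1()` produces Gaussian outcomes with correlation in both the
longitudinal and functional directions: cluster-level and observation-level
scores on orthonormal principal components $\psi_1 \equiv 1$,
$\psi_2 = \sqrt2 \sin(2\pi s)$ (score variances 3, 2, 1.5, 1), white noise
of variance 1.5, a standard-normal cluster covariate, and an AR(1)-drifting
longitudinal covariate $X_{2,i,j} = j + e_{i,j}$ ($\alpha = 0.7$).  At a
point $s$ with $\psi_2(s) = 0$ the implied exchangeable correlation is
$3/6 = 0.5$; a pointwise working covariance is thus *misspecified* in the
functional direction by construction, which is exactly the robustness
scenario the estimator targets.

`gen_sim2()` produces binary outcomes from a marginal logit model with, at
each grid point, a latent stationary Gaussian AR(1) vector across
longitudinal observations pushed through its uniform transform.  Marginal
success probabilities are exact; the latent lag-1 correlation is exactly
$\rho$, while the induced binary-scale correlation is attenuated (as with
any threshold mechanism).  The trend covariate is centered and scaled to
unit variance per dataset before entering the linear predictor, so logits
stay in a sane range for cluster sizes up to 100; the stored covariate is
the standardized one, keeping the recorded design faithful to the
generating model.

What the generators do *not* emulate: irregular or sparse grids, missing
functional points, heteroscedastic measurement noise, within-animal
correlation between clusters, and functional (time-varying) covariates —
though the fitting code accepts concurrent functional covariates.  Passing
tests on these designs therefore says nothing about those features of real
recordings.

Generator output is bit-reproducible given a seed, and replicate $t$ of a
study uses seed $\texttt{seed} + t$, so study results are independent of
execution order.

## Numerical choices

* Binomial means are clamped to $[10^{-6}, 1 - 10^{-6}]$ before variance
  evaluation; Poisson means are floored at $10^{-10}$.
* The penalized IRLS path declares convergence at a relative
  $\theta$-change below $10^{-8}$ (at most 100 iterations) and step-halves
  if the linear predictor leaves the finite range.
* If a penalized system is singular (possible under complete separation,
  because the difference penalty leaves polynomial directions unpenalized),
  the solver retries with a ridge floor of order $10^{-9}$ times the mean
  Hessian diagonal.
* CV and GCV ties are broken toward the larger (smoother) candidate.
* The fully-iterated GLS benchmark alternates the weighted solve with
  $\hat\rho$ re-estimation (tolerance $10^{-8}$, 50 iterations), averaging
  the last two correlation estimates if the iteration oscillates.

## Problem sizes used in the shipped studies

The test suite exercises oracle equivalences on small instances (dense
$n_i L \times n_i L$ assemblies up to $24 \times 24$) and runs reduced
simulation studies: 10–30 replicates per design cell, $N \le 100$,
$n_i \le 100$, $L \le 100$.  `scripts/acceptance.R` regenerates the five
headline cells with 100 replicates each.  These sizes were chosen so a
full run completes in minutes on one core while keeping Monte-Carlo
standard errors on coverage near 0.01–0.03; the estimators themselves have
been run on $N = 100$, $n_i = 100$, $L = 100$ (a million points) in under
ten seconds for the binary model.

## Known limitations

* Regular, shared grids only; cluster sizes may vary but the grid may not.
* AR(1) correlation assumes equally spaced longitudinal observations.
* The joint bands inherit the finite-$N$ noise of the sandwich variance
  (see above); with $N \lesssim 50$ clusters they can undercover even when
  pointwise intervals are calibrated.
* GLS benchmarks are Gaussian-only by design.
* Poisson outcomes are supported by the estimator but have no
  matched generator; properties under count data are untested here.
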