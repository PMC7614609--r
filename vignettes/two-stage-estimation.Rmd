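---
title: "Point estimation after a two-stage group sequential trial"
author: "gsepoint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point estimation after a two-stage group sequential trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsepoint)
```

## The estimation problem

A two-stage group sequential trial compares a treatment against control
with one pre-planned interim analysis. If the standardized interim
statistic $Z_1$ reaches the efficacy boundary $e$, the trial stops and
rejects the null hypothesis; otherwise it continues to the final analysis.
With a one-sided O'Brien-Fleming (OBF) rule, $e_k = C(K,\alpha)\sqrt{K/k}$,
so early rejection is deliberately hard and the final test is close to
nominal.

Early stopping couples the estimate to the design. Writing $\hat\theta_1$
and $\hat\theta_{obs}$ for the interim and overall maximum likelihood
estimates (MLEs) of the treatment difference $\theta$:

* **unconditionally** (averaging over stopping stages), the end-of-trial
  MLE over-estimates $\theta$, because large interim estimates are frozen
  by early stopping while small ones get diluted by stage-2 data;
* **conditionally on continuation**, the MLE *under*-estimates $\theta$,
  because the trial only continues when $\hat\theta_1$ fell below the
  boundary.

Both statements are quantitative. With observed information $I_1 < I_2$
and $d = e - \theta\sqrt{I_1}$,

$$\mathrm{bias}_u(\theta) = \frac{I_2 - I_1}{I_2\sqrt{I_1}}\,\varphi(d),
\qquad
\mathrm{bias}_c(\theta) = -\frac{\sqrt{I_1}}{I_2}\,
\frac{\varphi(d)}{\Phi(d)},$$

and the two are tied together by the law of total expectation through the
stopping probability $p(\theta) = 1 - \Phi(d)$:

$$p(\theta)\,\mathrm{bias}_{stop}(\theta) +
  (1 - p(\theta))\,\mathrm{bias}_c(\theta) = \mathrm{bias}_u(\theta),$$

an algebraic identity the test suite asserts to $10^{-12}$ pointwise
(`bias_profile()` returns all four curves).

## The estimators

All estimators consume the same sufficient summary
(`trial_information()`): $I_1$, $I_2$, $z_1$, $z_2$, $e$. For a binary
endpoint these reduce from cumulative per-arm counts via the
pooled-variance information $I = [\bar p(1-\bar p)(1/n_C + 1/n_T)]^{-1}$
— the convention under which the standardized Wald statistic is
$\hat\theta\sqrt{I}$. Any other endpoint can be used by supplying $I_1,
I_2$ directly.

**Unconditional family.** The *UBC-MLE* solves the fixed point
$\tilde\theta = \hat\theta_{obs} - \mathrm{bias}_u(\tilde\theta)$. The
*UMVUE* Rao-Blackwellizes the (unconditionally unbiased) stage-1 MLE: given
the overall MLE and continuation, $\hat\theta_1$ is normal with mean
$\hat\theta_{obs}$ and variance $1/I_1 - 1/I_2$, truncated above at
$e/\sqrt{I_1}$; the UMVUE is that truncated mean. The *MUE* inverts the
stagewise-ordering P-value function

$$P(\theta) = \Pr_\theta(Z_1 \ge e) + \Pr_\theta(Z_1 < e,\, Z_2 \ge z_2)
           = 1 - \Phi_2\!\big(e - \theta\sqrt{I_1},\,
                              z_2 - \theta\sqrt{I_2};\, \rho\big)$$

at $1/2$, where $\rho = \sqrt{I_1/I_2}$ and $\Phi_2$ is the bivariate
normal CDF. Stagewise ordering counts stage-1 rejections as more extreme
than any stage-2 outcome; the first term is essential — without it the
function cannot reach $1/2$ near the estimate when the interim came close
to the boundary.

**Conditional family.** The *CBC-MLE* solves
$\tilde\theta_c = \hat\theta_{obs} - \mathrm{bias}_c(\tilde\theta_c)$. The
*UMVCUE* Rao-Blackwellizes the stage-2 MLE and satisfies the exact
information-weighted identity
$I_1\,\mathrm{UMVUE} + (I_2 - I_1)\,\mathrm{UMVCUE} =
I_2\,\hat\theta_{obs}$ (asserted to $10^{-12}$). The *CMUE* is the
$\theta$ whose conditional median of the overall MLE given continuation
equals the observed MLE; the conditional CDF reduces in closed form to

$$F(m \mid T = 2;\, \theta) =
  \frac{\Phi_2\big(e - \theta\sqrt{I_1},\,(m - \theta)\sqrt{I_2};\,
  \rho\big)}{\Phi(e - \theta\sqrt{I_1})},$$

which is strictly decreasing in $\theta$, so the root is unique. The
companion density `conditional_mle_density()` is checked to integrate to
one (to $10^{-6}$) and `integrate()` of it is used as an independent
quadrature route to the same CDF in the tests, alongside a Monte-Carlo
comparison against the empirical law of continuing replicates
(Kolmogorov-Smirnov distance below 0.005 at $10^6$ draws).

Two routes to the stage-2 MLE are exposed deliberately: on real binary
counts, `mle_difference(incremental_counts(...))` uses only post-interim
subjects (0.1139 in the bundled example), while `stage2_mle_weighted()`
applies $(I_2\hat\theta_{obs} - I_1\hat\theta_1)/(I_2 - I_1)$ (0.1114
there). They differ on real data because the per-stage pooled variances
differ; on the canonical simulation scale they coincide by construction,
and the simulator uses the weighted form.

## Tunable parameters

* `alpha` (one-sided overall type I error, default use cases 0.025 or
  0.05): calibrates the boundary constant $C$ by bracketed root-finding on
  $[0.5, 6]$ to $|{\rm error} - \alpha| < 10^{-8}$.
* `info_fractions` (planned, default $k/K$): used only for boundary
  calibration. Estimation uses the *observed* information ratio —
  deliberately decoupled, since real trials rarely land on the planned
  fraction (0.795 observed vs 0.5 planned in the bundled example).
* `e` may be set to `Inf`, the no-early-stopping limit in which every
  adjusted estimator collapses to the overall MLE (a tested invariant).
* Simulation: `n_reps` ($10^4$ default profile, $10^5$ for full
  reproduction runs) and an explicit integer `seed`.

## What the simulator emulates

`simulate_replicates()` draws $(Z_1, Z_2)$ from the canonical joint
distribution — the asymptotic law of the sequential Wald statistics — at
the observed information levels, then applies the efficacy rule. This is
exactly the sampling model under which the estimators are derived, so
simulation checks are internally consistent: UMVUE/UMVCUE unbiasedness,
the MUE's median property, the CMUE's conditional-median property
($\Pr(\mathrm{CMUE} < \theta \mid T = 2) = 0.5$), and agreement of
empirical stop fractions with $1 - \Phi(d)$ are all asserted within three
Monte-Carlo standard errors under fixed seeds.

What it does **not** emulate: binomial discreteness and the resulting
skewness at small samples, information drift when the pooled response rate
changes between stages, overdispersion, or dropout. Passing simulation
tests therefore demonstrate correctness of the estimators *under the
normal approximation*, not robustness of that approximation for any
particular real trial. The bootstrap (`bootstrap_se()`) is parametric on
the same canonical scale and conditions the conditional estimators'
standard errors on continuation, which is why those SEs exceed the
unconditional ones.

Replicates that stop at stage 1 report the stage-1 MLE for every
unconditional estimator: this is definitional for the MLE, MUE and UMVUE,
and is adopted as a convention for the UBC-MLE, whose correction would
otherwise require the never-observed $I_2$.

## Numerical choices

* Bivariate normal CDF: a vectorized kernel (`pbvn`) using the
  Drezner-Wesolowsky angular reduction with 32-point Gauss-Legendre
  quadrature for $|\rho| \le 0.925$, and a conditioning integral with
  quadrature panels split around the inner CDF's transition point for
  larger $|\rho|$; absolute accuracy below $10^{-9}$, cross-checked against
  a deterministic reference algorithm in the tests. Vectorization is what
  makes replicate-wise root-finding for the MUE/CMUE feasible at $10^5$
  replicates.
* Mills ratios $\varphi/\Phi$ are evaluated on the log scale
  (`pnorm(log.p = TRUE)`), which is accurate throughout the double tail;
  no asymptotic expansion is needed.
* Root-finding: element-wise bisection with brackets
  $\hat\theta_{obs} \pm 10/\sqrt{I_2}$, widened geometrically on demand;
  tolerances $10^{-10}$ on the effect scale. The bias-corrected fixed
  points are contractions (the relevant derivative is bounded below 1 by
  $(I_2-I_1)/I_2 \cdot \max_x |x\varphi(x)| < 0.25$ unconditionally, and
  by $I_1/I_2$ conditionally), so the roots are unique.
* The conditional CDF ratio switches to a probability-transformed
  quadrature when $\Phi(e - \theta\sqrt{I_1}) < 10^{-10}$, keeping the
  CMUE solver stable at extreme $\theta$.
* Degenerate inputs fail loudly: pooled proportions of 0 or 1, zero
  post-interim subjects, non-monotone cumulative counts, $I_2 \le I_1$.
* The design solver reports the exact calibrated boundary (e.g. 2.796510
  for the two-stage one-sided 0.025 design); published summaries often
  round such boundaries to 3 decimals, and at near-boundary data the
  median-type estimators are sensitive in their 4th decimal to that
  rounding, so the default pipeline uses the solver value.

## Design decisions that were genuinely open

* **Information convention.** The pooled-variance (score) information is
  the unique convention reproducing the standardized statistics printed in
  the bundled case study from its raw counts; the unpooled alternative
  does not. It is therefore fixed, not an option.
* **Boundary-calibration algorithm.** Multivariate normal rectangle
  probabilities use Miwa's deterministic algorithm (via `mvtnorm`) rather
  than quasi-Monte-Carlo, so design construction is bit-reproducible.
* **CMUE evaluation.** The conditional CDF is computed via the closed
  bivariate-normal reduction rather than direct quadrature of the density;
  the quadrature route survives as an independent cross-check in the test
  suite. The two agree to $10^{-8}$.
* **Two-stage scope.** Boundary calibration supports general $K$; the
  estimator suite is two-stage, matching the setting in which these closed
  forms exist.

## Known limitations

* Only efficacy (upper) stopping is modeled; futility boundaries change
  every formula and are out of scope.
* Estimators for $K > 2$ stages, other sample-space orderings for the MUE,
  and confidence intervals are not provided.
* The binary-endpoint reduction assumes large-sample normality; for very
  small trials the canonical approximation itself is the weak link.
* The CMUE and CBC-MLE are bias-reducing but not exactly
  (conditionally) mean-unbiased; in our simulations they retain a small
  positive conditional bias, consistent with the general trade-off that
  exact conditional unbiasedness (UMVCUE) costs variance.

## Problem sizes used in the checks

The packaged tests run the simulator at $10^4$ replicates per effect value
for distributional summaries (three effect sizes, seeded) and one
$10^5$-replicate run for bootstrap standard errors; the
Kolmogorov-Smirnov density check uses $10^6$ canonical draws. These sizes
make every Monte-Carlo band (three standard errors) narrow enough to be
informative while keeping the whole suite under a minute on a single core.
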