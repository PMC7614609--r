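# gsepoint

Unbiased and bias-adjusted point estimation for two-stage group sequential
trials with early stopping for efficacy.

## The problem

In a group sequential trial, accumulating data are compared against
pre-specified stopping boundaries at interim analyses. This is efficient and
ethical, but it breaks the usual end-of-trial estimator: because large
interim effects trigger early stopping, the maximum likelihood estimate
(MLE) of the treatment effect is selectively biased — upward on average over
all trial realizations, and *downward* in the realizations that continue to
the final analysis. Regulators ask for estimates that account for the
design; statisticians disagree on whether the unconditional or the
conditional (given the realized stopping stage) perspective is the right
one. `gsepoint` computes both families of estimators so a trial team can
report them side by side.

The package targets trial statisticians analyzing (or planning) a two-stage
design with a one-sided O'Brien-Fleming (OBF) efficacy boundary and a
binary endpoint — though any endpoint can be used by supplying the observed
information directly.

## The model

Let `theta = p_T - p_C` be the difference in success proportions, and let
`Z_1`, `Z_2` be the standardized Wald statistics at the interim and final
analysis with observed information `I_1 < I_2` (pooled-variance convention:
`I = [pbar(1-pbar)(1/n_C + 1/n_T)]^{-1}`). `(Z_1, Z_2)` follows the
canonical joint distribution: bivariate normal with means
`(theta*sqrt(I_1), theta*sqrt(I_2))`, unit variances, and correlation
`sqrt(I_1/I_2)`. The trial stops at the interim iff `Z_1 >= e`, where
`e = C(K, alpha) * sqrt(K/k)` is the OBF boundary calibrated so the overall
one-sided type I error is `alpha`.

Estimators of `theta` (with `theta_obs` the overall MLE, `theta_1` the
interim MLE):

**Unconditional perspective**

- *MLE (overall, stage 1)* — the naive estimates.
- *UBC-MLE* — solves `theta = theta_obs - b(theta)` with Emerson's
  unconditional bias `b(theta) = ((I_2-I_1)/(I_2 sqrt(I_1))) *
  phi(e - theta sqrt(I_1))`.
- *UMVUE* — Rao-Blackwellization of `theta_1`: the mean of a normal
  `(theta_obs, 1/I_1 - 1/I_2)` truncated above at `e/sqrt(I_1)`.
- *MUE* — the root of `P(theta) = 0.5` for the stagewise-ordering P-value
  `P(theta) = Pr(Z_1 >= e) + Pr(Z_1 < e, Z_2 >= z_2)`.

**Conditional perspective (given continuation, `T = 2`)**

- *MLE (stage 2)* — from the post-interim increments only.
- *CBC-MLE* — solves `theta = theta_obs - b_c(theta)` with conditional bias
  `b_c(theta) = -(sqrt(I_1)/I_2) * phi(d)/Phi(d)`, `d = e - theta sqrt(I_1)`.
- *UMVCUE* — Rao-Blackwellization of the stage-2 MLE:
  `(I_2 theta_obs - I_1 m)/(I_2 - I_1)` with `m` the UMVUE truncated mean.
- *CMUE* — the `theta` whose conditional median of the overall MLE given
  continuation equals `theta_obs`.

The package also provides analytic bias and stopping-probability profiles,
a canonical-distribution simulator, and parametric-bootstrap standard
errors.

## Worked example

A two-stage trial of a cannabis extract for muscle stiffness in multiple
sclerosis: at the interim, 12/97 control vs 27/101 treated subjects
improved; at the final analysis, 21/134 vs 42/143. The design is a
two-stage one-sided OBF rule with overall alpha 0.025.

```r
library(gsepoint)
interim <- analysis_counts(12, 97, 27, 101)
final   <- analysis_counts(21, 134, 42, 143)
design  <- obf_design(2, 0.025)     # boundaries 2.797, 1.977
estimate_report(interim, final, design = design)
```

```
two-stage group sequential estimate report (gsepoint 1.0.0)
  z1 = 2.540, z2 = 2.718; information fraction 0.795
  interim boundary 2.7965 (effect scale 0.1581)
                           label   perspective estimate rel_diff_pct
                   MLE (overall)         naive   0.1370            -
                   MLE (stage 1) unconditional   0.1436          +5%
 Median unbiased estimator (MUE) unconditional   0.1341          -2%
                           UMVUE unconditional   0.1278          -7%
    Bias-corrected MLE (UBC-MLE) unconditional   0.1328          -3%
                   MLE (stage 2)   conditional   0.1139         -17%
          Conditional MUE (CMUE)   conditional   0.1851         +35%
                          UMVCUE   conditional   0.1724         +26%
    Bias-corrected MLE (CBC-MLE)   conditional   0.1909         +39%
```

The interim statistic (2.540) came close to the boundary (2.797, or 0.1581
on the effect scale), so the two perspectives disagree noticeably: the
unconditional estimators shade the MLE of 0.1370 *down* (the design could
have stopped early on an overestimate), while the conditional estimators
shade it *up* (given that the trial continued, the interim estimate was
selected to be below the boundary). Bootstrap standard errors can be added
with `estimate_report(..., se = TRUE, seed = 1)`; analytic bias curves come
from `bias_profile()`, and sampling distributions from
`simulate_replicates()` + `evaluate_estimators()`.

A command-line front end with subcommands `estimate | design | profile |
simulate` is installed at `inst/cli/gsepoint.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/gsepoint.R", package="gsepoint"))')" \
  estimate --counts inst/extdata/musec_counts.csv \
  --design inst/extdata/musec_design.yaml
```

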