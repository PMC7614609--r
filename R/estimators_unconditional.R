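# Unconditional-perspective estimators: the analytic (Emerson) bias of the
# overall MLE, the unconditional bias-corrected MLE, the Rao-Blackwell
# UMVUE, and the median-unbiased estimator under stagewise ordering.

# ---- internal vectorized workhorses (scalar I1, I2, e) ---------------------

.emerson_bias <- function(theta, I1, I2, e) {
  ((I2 - I1) / (I2 * sqrt(I1))) * stats::dnorm(e - theta * sqrt(I1))
}

.ubc_mle_vec <- function(theta_obs, I1, I2, e) {
  if (!is.finite(e)) return(theta_obs)
  # theta + bias(theta) is strictly increasing: (I2-I1)/I2 * max|x phi(x)| < 1
  f <- function(th) th + .emerson_bias(th, I1, I2, e) - theta_obs
  .vbisect(f, theta_obs - 10 / sqrt(I2), theta_obs + 10 / sqrt(I2),
           tol = 1e-11)
}

# truncated-normal conditional mean of the stage-1 MLE given the overall MLE
# and continuation: mean theta_obs, SD sqrt(1/I1 - 1/I2), upper-truncated at
# the effect-scale boundary e/sqrt(I1)
.umvue_cont_vec <- function(theta_obs, I1, I2, e) {
  if (!is.finite(e)) return(theta_obs)
  sig <- sqrt(1 / I1 - 1 / I2)
  a <- (e / sqrt(I1) - theta_obs) / sig
  theta_obs - sig * .mills_lower(a)
}

.stagewise_pvalue_vec <- function(theta, z2, I1, I2, e) {
  # Pr(Z1 >= e) + Pr(Z1 < e, Z2 >= z2) = 1 - Phi2(e - th*sqrt(I1),
  # z2 - th*sqrt(I2); rho)
  1 - pbvn(e - theta * sqrt(I1), z2 - theta * sqrt(I2), sqrt(I1 / I2))
}

.mue_vec <- function(z2, I1, I2, e) {
  theta_obs <- z2 / sqrt(I2)
  if (!is.finite(e)) return(theta_obs)
  f <- function(th) .stagewise_pvalue_vec(th, z2, I1, I2, e) - 0.5
  .vbisect(f, theta_obs - 10 / sqrt(I2), theta_obs + 10 / sqrt(I2),
           tol = 1e-10)
}

# ---- exported interface ----------------------------------------------------

#' Unconditional (Emerson) bias of the overall MLE
#'
#' Analytic unconditional bias of the end-of-trial MLE in a two-stage design
#' with an interim efficacy boundary:
#' `bias(theta) = ((I2 - I1) / (I2 * sqrt(I1))) * phi(e - theta * sqrt(I1))`.
#' Strictly positive for finite boundaries: early stopping selects upward.
#'
#' @param theta True effect value(s); vectorized.
#' @param info A [trial_information()] object.
#' @return Bias on the effect scale.
#' @examples
#' info <- trial_information(I1 = 312.8, I2 = 393.7, e = 2.797, z2 = 2.718)
#' emerson_bias(0.1328, info)
#' @export
emerson_bias <- function(theta, info) {
  stopifnot(inherits(info, "gs_info"))
  .emerson_bias(theta, info$I1, info$I2, info$e)
}

#' Unconditional bias-corrected MLE
#'
#' Whitehead-style bias-corrected estimate: the solution of
#' `theta = theta_obs - bias(theta)` with the unconditional bias of
#' [emerson_bias()], found by bracketed bisection. Always below the overall
#' MLE for a finite boundary.
#'
#' @param info A [trial_information()] object with observed `z2`.
#' @return The bias-corrected estimate.
#' @export
ubc_mle <- function(info) {
  stopifnot(inherits(info, "gs_info"))
  .need_z2(info)
  .ubc_mle_vec(info$theta_obs, info$I1, info$I2, info$e)
}

#' Uniformly minimum variance unbiased estimator (UMVUE)
#'
#' Rao-Blackwellization of the (unconditionally unbiased) stage-1 MLE on the
#' sufficient statistic. If the trial stopped at stage 1 the UMVUE is the
#' stage-1 MLE itself. If it continued, it is the conditional expectation of
#' the stage-1 MLE given the overall MLE and continuation, which is the mean
#' of a normal distribution with mean `theta_obs` and SD
#' `sqrt(1/I1 - 1/I2)`, truncated above at the effect-scale boundary
#' `e / sqrt(I1)`.
#'
#' @param info A [trial_information()] object.
#' @param stopped_stage Stage at which the trial stopped (1 or 2).
#' @return The UMVUE of the treatment difference.
#' @export
umvue <- function(info, stopped_stage = 2L) {
  stopifnot(inherits(info, "gs_info"), stopped_stage %in% c(1L, 2L))
  if (stopped_stage == 1L) {
    if (is.na(info$theta1)) stop("stage-1 stopping requires observed z1")
    return(info$theta1)
  }
  .need_z2(info)
  .umvue_cont_vec(info$theta_obs, info$I1, info$I2, info$e)
}

#' Stagewise-ordering P-value function
#'
#' One-sided P-value function `P(theta)` for a trial that continued to the
#' final analysis, under stagewise ordering (stage-1 rejections count as
#' more extreme than any final-stage outcome):
#' `P(theta) = Pr_theta(Z1 >= e) + Pr_theta(Z1 < e, Z2 >= z2)`, with
#' `(Z1, Z2)` bivariate normal, means `(theta*sqrt(I1), theta*sqrt(I2))`,
#' unit variances and correlation `sqrt(I1/I2)`. Strictly increasing in
#' `theta`.
#'
#' @param theta True effect value(s); vectorized.
#' @param info A [trial_information()] object with observed `z2`.
#' @return P-value(s) in (0, 1).
#' @export
stagewise_pvalue <- function(theta, info) {
  stopifnot(inherits(info, "gs_info"))
  .need_z2(info)
  .stagewise_pvalue_vec(theta, info$z2, info$I1, info$I2, info$e)
}

#' Median-unbiased estimator (MUE) under stagewise ordering
#'
#' The value of `theta` at which the stagewise-ordering P-value function
#' equals one half: `P(theta_MUE) = 0.5`. Unique by strict monotonicity of
#' `P`; found by bracketed bisection to 1e-10 on the effect scale.
#'
#' @param info A [trial_information()] object with observed `z2`.
#' @return The median-unbiased estimate.
#' @export
mue <- function(info) {
  stopifnot(inherits(info, "gs_info"))
  .need_z2(info)
  .mue_vec(info$z2, info$I1, info$I2, info$e)
}
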