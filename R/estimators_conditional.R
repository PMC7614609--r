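# Conditional-perspective estimators, given continuation to the final
# analysis: conditional bias of the overall MLE, conditional bias-corrected
# MLE, the Rao-Blackwell UMVCUE, and the conditional median-unbiased
# estimator.

# ---- internal vectorized workhorses ----------------------------------------

.cond_bias_vec <- function(theta, I1, I2, e) {
  -(sqrt(I1) / I2) * .mills_lower(e - theta * sqrt(I1))
}

.cbc_mle_vec <- function(theta_obs, I1, I2, e) {
  if (!is.finite(e)) return(theta_obs)
  # theta + condbias(theta) has derivative in (1 - I1/I2, 1): increasing
  f <- function(th) th + .cond_bias_vec(th, I1, I2, e) - theta_obs
  .vbisect(f, theta_obs - 10 / sqrt(I2), theta_obs + 10 / sqrt(I2),
           tol = 1e-11)
}

.umvcue_vec <- function(theta_obs, I1, I2, e) {
  m <- .umvue_cont_vec(theta_obs, I1, I2, e)
  (I2 * theta_obs - I1 * m) / (I2 - I1)
}

# conditional CDF of the overall MLE given continuation, at effect value m:
# F(m | T = 2; theta) = Phi2(e - theta*sqrt(I1), (m - theta)*sqrt(I2); rho)
#                       / Phi(e - theta*sqrt(I1))
.cond_cdf_vec <- function(m, theta, I1, I2, e) {
  if (!is.finite(e)) return(stats::pnorm((m - theta) * sqrt(I2)))
  h <- e - theta * sqrt(I1)
  k <- (m - theta) * sqrt(I2)
  rho <- sqrt(I1 / I2)
  den <- stats::pnorm(h)
  out <- pbvn(h, k, rho) / den
  tiny <- which(den < 1e-10)
  if (length(tiny)) { # deep tail: both terms underflow, integrate stably
    hh <- rep_len(h, length(out))[tiny]
    kk <- rep_len(k, length(out))[tiny]
    out[tiny] <- vapply(seq_along(tiny), function(j) {
      # F = int_0^1 Phi((k - rho * x(u)) / s) du with x(u) = Phi^-1(u Phi(h))
      lp <- stats::pnorm(hh[j], log.p = TRUE)
      u <- (.GL96$x + 1) / 2
      x <- stats::qnorm(log(u) + lp, log.p = TRUE)
      sum(.GL96$w / 2 *
            stats::pnorm((kk[j] - rho * x) / sqrt(1 - rho^2)))
    }, numeric(1))
  }
  pmin(1, pmax(0, out))
}

.cmue_vec <- function(z2, I1, I2, e) {
  theta_obs <- z2 / sqrt(I2)
  if (!is.finite(e)) return(theta_obs)
  # the conditional CDF at fixed m is strictly decreasing in theta
  f <- function(th) 0.5 - .cond_cdf_vec(theta_obs, th, I1, I2, e)
  .vbisect(f, theta_obs - 10 / sqrt(I2), theta_obs + 10 / sqrt(I2),
           tol = 1e-10)
}

# ---- exported interface ----------------------------------------------------

#' Conditional bias of the overall MLE at the final analysis
#'
#' Analytic bias of the end-of-trial MLE conditional on the trial continuing
#' to the final analysis:
#' `-(sqrt(I1)/I2) * phi(d) / Phi(d)` with `d = e - theta * sqrt(I1)`.
#' Strictly negative for finite boundaries (continuation selects the stage-1
#' estimate downward). The Mills ratio is evaluated on the log scale so the
#' deep tail stays finite.
#'
#' @param theta True effect value(s); vectorized.
#' @param info A [trial_information()] object.
#' @return Conditional bias on the effect scale (negative).
#' @export
conditional_bias_final <- function(theta, info) {
  stopifnot(inherits(info, "gs_info"))
  .cond_bias_vec(theta, info$I1, info$I2, info$e)
}

#' Conditional bias-corrected MLE
#'
#' The solution of `theta = theta_obs - conditional_bias(theta)`, found by
#' bracketed bisection. Always above the overall MLE for a finite boundary,
#' since the conditional bias is negative.
#'
#' @param info A [trial_information()] object with observed `z2`.
#' @return The conditionally bias-corrected estimate.
#' @export
cbc_mle <- function(info) {
  stopifnot(inherits(info, "gs_info"))
  .need_z2(info)
  .cbc_mle_vec(info$theta_obs, info$I1, info$I2, info$e)
}

#' Uniformly minimum variance conditionally unbiased estimator (UMVCUE)
#'
#' Rao-Blackwellization of the (conditionally unbiased) stage-2 MLE given
#' the overall MLE and continuation:
#' `(I2 * theta_obs - I1 * m) / (I2 - I1)`, where `m` is the truncated-normal
#' conditional mean of the stage-1 MLE used by [umvue()]. Satisfies the
#' information-weighted decomposition
#' `I1 * umvue + (I2 - I1) * umvcue = I2 * theta_obs` exactly.
#'
#' @param info A [trial_information()] object with observed `z2`.
#' @return The UMVCUE of the treatment difference.
#' @export
umvcue <- function(info) {
  stopifnot(inherits(info, "gs_info"))
  .need_z2(info)
  .umvcue_vec(info$theta_obs, info$I1, info$I2, info$e)
}

#' Conditional density of the overall MLE given continuation
#'
#' Density of the end-of-trial MLE, conditional on the trial continuing to
#' the final analysis, under true effect `theta`:
#' `sqrt(I2) * phi(z2m - theta*sqrt(I2)) *
#'  Phi((e - theta*sqrt(I1) - rho*(z2m - theta*sqrt(I2))) / sqrt(1-rho^2)) /
#'  Phi(e - theta*sqrt(I1))`,
#' with `z2m = m * sqrt(I2)` and `rho = sqrt(I1/I2)`. Computed on the log
#' scale. Integrates to one over `m`; reduces to the unconditional normal
#' density when `e = Inf`.
#'
#' @param m Effect-scale evaluation point(s); vectorized.
#' @param theta True effect value.
#' @param info A [trial_information()] object.
#' @return Density value(s).
#' @export
conditional_mle_density <- function(m, theta, info) {
  stopifnot(inherits(info, "gs_info"))
  I1 <- info$I1; I2 <- info$I2; e <- info$e
  rho <- sqrt(I1 / I2)
  u <- (m - theta) * sqrt(I2)
  if (!is.finite(e)) return(sqrt(I2) * stats::dnorm(u))
  lognum <- stats::dnorm(u, log = TRUE) +
    stats::pnorm((e - theta * sqrt(I1) - rho * u) / sqrt(1 - rho^2),
                 log.p = TRUE)
  logden <- stats::pnorm(e - theta * sqrt(I1), log.p = TRUE)
  sqrt(I2) * exp(lognum - logden)
}

#' Conditional CDF of the overall MLE given continuation
#'
#' Distribution function companion to [conditional_mle_density()], computed
#' in closed form as a ratio of bivariate to univariate normal CDFs (with a
#' stable quadrature fallback deep in the tail where both underflow).
#'
#' @param m Effect-scale evaluation point(s); vectorized.
#' @param theta True effect value.
#' @param info A [trial_information()] object.
#' @return Probability value(s).
#' @export
conditional_mle_cdf <- function(m, theta, info) {
  stopifnot(inherits(info, "gs_info"))
  .cond_cdf_vec(m, theta, info$I1, info$I2, info$e)
}

#' Conditional median-unbiased estimator (CMUE)
#'
#' The value of `theta` for which the conditional median of the overall MLE
#' given continuation equals the observed overall MLE, i.e. the root of
#' `F(theta_obs | T = 2; theta) = 0.5` where `F` is
#' [conditional_mle_cdf()]. The conditional CDF is strictly decreasing in
#' `theta` (stochastic ordering), so the root is unique; it is found by
#' bracketed bisection to 1e-10 on the effect scale.
#'
#' @param info A [trial_information()] object with observed `z2`.
#' @return The conditional median-unbiased estimate.
#' @export
cmue <- function(info) {
  stopifnot(inherits(info, "gs_info"))
  .need_z2(info)
  .cmue_vec(info$z2, info$I1, info$I2, info$e)
}

#' Stage-2 MLE on the canonical (information-weighted) scale
#'
#' The estimate based only on post-interim data, recovered from the overall
#' and stage-1 estimates by the information-weighted decomposition
#' `(I2 * theta_obs - I1 * theta1) / (I2 - I1)`. On real binary-count data
#' this differs slightly from the incremental-count MLE (see
#' [incremental_counts()]) because the per-stage pooled variances differ;
#' the two coincide by construction on the canonical simulation scale. Both
#' routes are exposed.
#'
#' @param info A [trial_information()] object with observed `z1` and `z2`.
#' @return The information-weighted stage-2 estimate.
#' @export
stage2_mle_weighted <- function(info) {
  stopifnot(inherits(info, "gs_info"))
  .need_z2(info)
  if (is.na(info$theta1)) stop("requires the observed stage-1 statistic")
  (info$I2 * info$theta_obs - info$I1 * info$theta1) / (info$I2 - info$I1)
}
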