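# Analytic bias and stopping-probability curves as functions of the true
# effect, for a two-stage design with an interim efficacy boundary.

#' Probability of stopping at the interim analysis
#'
#' `Pr_theta(Z1 >= e) = 1 - Phi(e - theta * sqrt(I1))`; strictly increasing
#' in the true effect.
#'
#' @param theta True effect value(s); vectorized.
#' @param info A [trial_information()] object.
#' @return Stopping probability.
#' @export
stopping_probability <- function(theta, info) {
  stopifnot(inherits(info, "gs_info"))
  stats::pnorm(info$e - theta * sqrt(info$I1), lower.tail = FALSE)
}

#' Conditional bias of the stage-1 MLE given early stopping
#'
#' Expected over-estimation in trial realizations that stop early for
#' efficacy: `E[theta1_hat | Z1 >= e] - theta = phi(d) / ((1 - Phi(d)) *
#' sqrt(I1))` with `d = e - theta * sqrt(I1)`. Strictly positive; the upper
#' Mills ratio is evaluated on the log scale for tail stability.
#'
#' @param theta True effect value(s); vectorized.
#' @param info A [trial_information()] object.
#' @return Conditional bias given stopping (positive).
#' @export
bias_given_stop <- function(theta, info) {
  stopifnot(inherits(info, "gs_info"))
  .mills_upper(info$e - theta * sqrt(info$I1)) / sqrt(info$I1)
}

#' Bias and stopping-probability profile over a grid of true effects
#'
#' Evaluates, on a grid of true effect values, the four analytic curves that
#' characterize selection bias in a two-stage efficacy design: conditional
#' bias given early stopping ([bias_given_stop()]), conditional bias given
#' continuation ([conditional_bias_final()]), unconditional bias
#' ([emerson_bias()]), and the stopping probability
#' ([stopping_probability()]). The curves satisfy the law of total
#' expectation exactly:
#' `p_stop * bias_stop + (1 - p_stop) * bias_continue = bias_unconditional`.
#'
#' @param info A [trial_information()] object (observed statistics are not
#'   needed, only `I1`, `I2`, `e`).
#' @param theta_grid Numeric vector of true effect values.
#' @return A data frame of class `gs_bias_profile` with columns `theta`,
#'   `bias_given_stop`, `bias_given_continue`, `unconditional_bias`,
#'   `stop_probability`.
#' @examples
#' sc <- obf_normal_scenario(100)
#' head(bias_profile(sc, seq(-0.5, 1, by = 0.25)))
#' @export
bias_profile <- function(info, theta_grid) {
  stopifnot(inherits(info, "gs_info"), all(is.finite(theta_grid)))
  out <- data.frame(
    theta = theta_grid,
    bias_given_stop = bias_given_stop(theta_grid, info),
    bias_given_continue = conditional_bias_final(theta_grid, info),
    unconditional_bias = emerson_bias(theta_grid, info),
    stop_probability = stopping_probability(theta_grid, info)
  )
  class(out) <- c("gs_bias_profile", "data.frame")
  out
}

#' Two-stage normal-outcome design scenario
#'
#' Convenience constructor for a two-arm trial with a normally distributed
#' outcome of known standard deviation, equal allocation, and an interim
#' analysis at a given information fraction with a one-sided
#' O'Brien-Fleming efficacy boundary. The information at analysis `k` is
#' `n_k / (2 * sd^2)` with `n_k` the cumulative per-arm sample size, so the
#' final information is `n_total / (4 * sd^2)`. With `alpha = 0.05` this
#' reproduces the standard 80%-power pairings (N = 620, 100, 40 for effects
#' 0.2, 0.5, 0.8).
#'
#' @param n_total Total (two-arm) sample size at the final analysis.
#' @param sd Known outcome standard deviation.
#' @param alpha Overall one-sided type I error of the design.
#' @param info_fraction Interim information fraction.
#' @return A [trial_information()] object with design quantities only.
#' @export
obf_normal_scenario <- function(n_total, sd = 1, alpha = 0.05,
                                info_fraction = 0.5) {
  stopifnot(n_total > 0, sd > 0)
  I2 <- (n_total / 2) / (2 * sd^2)
  design <- obf_design(2L, alpha, c(info_fraction, 1))
  trial_information(I1 = info_fraction * I2, I2 = I2,
                    e = design$z_boundaries[1])
}
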