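# Canonical-joint-distribution trial simulator, estimator sampling
# distributions, and parametric-bootstrap standard errors.

.UNCOND <- c("mle_overall", "mle_stage1", "mue", "umvue", "ubc_mle")
.COND <- c("mle_stage2", "cmue", "umvcue", "cbc_mle")

#' Simulate two-stage trial replicates from the canonical joint distribution
#'
#' Draws `(Z1, Z2)` from the bivariate normal canonical joint distribution
#' with means `(theta*sqrt(I1), theta*sqrt(I2))`, unit variances and
#' correlation `sqrt(I1/I2)`, and applies the interim efficacy rule
#' `Z1 >= e`. Both statistics are returned for every replicate (the latent
#' `z2` of a stopped trial is never used by the estimators but is retained
#' for diagnostics such as the pre-truncation correlation).
#'
#' @param theta True effect on the difference-in-proportions scale.
#' @param info A [trial_information()] object.
#' @param n_reps Number of trial replicates.
#' @param seed Optional integer seed for reproducibility.
#' @return A data frame of class `gs_replicates` with columns
#'   `stopped_stage`, `z1`, `z2`, and attributes `theta` and `info`.
#' @examples
#' info <- trial_information(I1 = 312.8, I2 = 393.7, e = 2.797, z2 = 2.718)
#' reps <- simulate_replicates(0.14, info, 1000, seed = 1)
#' mean(reps$stopped_stage == 1) # about 0.37
#' @export
simulate_replicates <- function(theta, info, n_reps, seed = NULL) {
  stopifnot(inherits(info, "gs_info"), n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  rho <- sqrt(info$I1 / info$I2)
  mu1 <- theta * sqrt(info$I1)
  mu2 <- theta * sqrt(info$I2)
  z1 <- stats::rnorm(n_reps, mu1)
  z2 <- mu2 + rho * (z1 - mu1) + sqrt(1 - rho^2) * stats::rnorm(n_reps)
  out <- data.frame(stopped_stage = ifelse(z1 >= info$e, 1L, 2L),
                    z1 = z1, z2 = z2)
  attr(out, "theta") <- theta
  attr(out, "info") <- info
  class(out) <- c("gs_replicates", "data.frame")
  out
}

# all estimators for a set of replicates; returns a list of named vectors
.compute_estimates <- function(replicates, info) {
  I1 <- info$I1; I2 <- info$I2; e <- info$e
  s1 <- replicates$stopped_stage == 1L
  th1 <- replicates$z1 / sqrt(I1)
  z2c <- replicates$z2[!s1]
  tho <- z2c / sqrt(I2)

  fill <- function(cont_values) {
    # replicates stopping at stage 1 report the stage-1 MLE (the overall
    # MLE by definition; MUE and UMVUE reduce to it; the bias-corrected
    # MLE is set to it since I2 is never observed)
    v <- th1
    v[!s1] <- cont_values
    v
  }
  uncond <- list(
    mle_overall = fill(tho),
    mle_stage1 = th1,
    mue = fill(.mue_vec(z2c, I1, I2, e)),
    umvue = fill(.umvue_cont_vec(tho, I1, I2, e)),
    ubc_mle = fill(.ubc_mle_vec(tho, I1, I2, e))
  )
  cond <- list(
    mle_stage2 = (sqrt(I2) * z2c - sqrt(I1) * replicates$z1[!s1]) /
      (I2 - I1),
    cmue = .cmue_vec(z2c, I1, I2, e),
    umvcue = .umvcue_vec(tho, I1, I2, e),
    cbc_mle = .cbc_mle_vec(tho, I1, I2, e)
  )
  list(unconditional = uncond, conditional = cond, stopped = s1)
}

#' Summarize estimator sampling distributions over simulated replicates
#'
#' Computes every estimator for every replicate and summarizes means and
#' standard deviations: unconditional estimators over all replicates (with
#' replicates that stop at the interim reporting the stage-1 MLE), and
#' conditional estimators over the continuing replicates only. Also reports
#' the by-stage split of the unconditional estimators.
#'
#' @param replicates A [simulate_replicates()] result.
#' @param info A [trial_information()] object (the same design the
#'   replicates were drawn under).
#' @return An object of class `gs_sim_result`: list with elements `overall`
#'   (data frame: estimator, perspective, mean, sd, n), `by_stage` (the
#'   unconditional estimators split by stopping stage), `stop_fraction`,
#'   `n_reps`, `theta`.
#' @export
evaluate_estimators <- function(replicates, info) {
  stopifnot(inherits(replicates, "gs_replicates"), inherits(info, "gs_info"))
  est <- .compute_estimates(replicates, info)
  s1 <- est$stopped
  if (all(s1)) {
    warning("no replicates continued to stage 2; conditional block is empty")
  }
  summ <- function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v))
  overall <- rbind(
    do.call(rbind, lapply(est$unconditional, summ)),
    do.call(rbind, lapply(est$conditional, summ))
  )
  overall <- data.frame(
    estimator = c(.UNCOND, .COND),
    perspective = rep(c("unconditional", "conditional"),
                      c(length(.UNCOND), length(.COND))),
    overall, row.names = NULL
  )
  by_stage <- do.call(rbind, lapply(.UNCOND, function(nm) {
    v <- est$unconditional[[nm]]
    rbind(
      data.frame(estimator = nm, stage = 1L, t(summ(v[s1]))),
      data.frame(estimator = nm, stage = 2L, t(summ(v[!s1])))
    )
  }))
  structure(
    list(overall = overall, by_stage = by_stage,
         stop_fraction = mean(s1), n_reps = nrow(replicates),
         theta = attr(replicates, "theta")),
    class = "gs_sim_result"
  )
}

#' @export
print.gs_sim_result <- function(x, ...) {
  cat(sprintf(
    "simulation summary: %d replicates, theta = %s, stop fraction %.3f\n",
    x$n_reps, format(x$theta), x$stop_fraction))
  df <- x$overall
  df$mean <- round(df$mean, 4)
  df$sd <- round(df$sd, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Parametric bootstrap standard errors for all estimators
#'
#' Simulates trial replicates from the canonical joint distribution at an
#' assumed true effect and reports the standard deviation of each estimator
#' across replicates: unconditional estimators over all replicates,
#' conditional estimators over the continuing replicates (conditioning on
#' continuation, consistent with conditional SEs exceeding unconditional
#' ones).
#'
#' @param theta_assumed Assumed true difference in proportions.
#' @param info A [trial_information()] object.
#' @param n_reps Number of bootstrap replicates (>= 1000).
#' @param seed Optional integer seed.
#' @return A data frame with columns `estimator`, `perspective`, `se`.
#' @export
bootstrap_se <- function(theta_assumed, info, n_reps = 1e5, seed = NULL) {
  stopifnot(n_reps >= 1e3)
  reps <- simulate_replicates(theta_assumed, info, n_reps, seed = seed)
  res <- evaluate_estimators(reps, info)
  data.frame(estimator = res$overall$estimator,
             perspective = res$overall$perspective,
             se = res$overall$sd)
}

#' Raw per-replicate estimator values
#'
#' Returns the per-replicate estimates underlying [evaluate_estimators()],
#' for histogram or density export: unconditional estimator vectors of
#' length `n_reps` (a mixture of the stage-1 stoppers' point mass and the
#' continuing replicates), conditional estimator vectors over the
#' continuing replicates only.
#'
#' @param replicates A [simulate_replicates()] result.
#' @param info A [trial_information()] object.
#' @return A list with elements `unconditional`, `conditional` (named lists
#'   of numeric vectors) and `stopped` (logical vector).
#' @export
sampling_distribution <- function(replicates, info) {
  stopifnot(inherits(replicates, "gs_replicates"), inherits(info, "gs_info"))
  est <- .compute_estimates(replicates, info)
  list(unconditional = est$unconditional,
       conditional = est$conditional,
       stopped = est$stopped)
}
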