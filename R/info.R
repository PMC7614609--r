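# The sufficient quantities every estimator consumes: observed information
# at each stage, standardized statistics, effect-scale MLEs, and the z-scale
# interim efficacy boundary.

#' Trial information summary for a two-stage group sequential trial
#'
#' Bundles the quantities all estimators operate on: observed information
#' `I1 < I2` at the interim and final analysis, the z-scale interim efficacy
#' boundary `e`, and (when observed data are available) the standardized
#' statistics `z1`, `z2` with their effect-scale counterparts
#' `theta1 = z1/sqrt(I1)` and `theta_obs = z2/sqrt(I2)`. The endpoint only
#' enters through these quantities, so a trial with any outcome type can be
#' analyzed by supplying its information directly.
#'
#' Either the z-scale or the effect-scale value may be supplied for each
#' stage; the other is derived. `e = Inf` is allowed and represents a design
#' in which early stopping is impossible (all adjusted estimators then
#' collapse to the overall MLE).
#'
#' @param I1,I2 Observed information at the interim and final analysis;
#'   `0 < I1 < I2`.
#' @param e Z-scale interim efficacy boundary (may be `Inf`).
#' @param z1,z2 Standardized Wald statistics (optional).
#' @param theta1,theta_obs Effect-scale MLEs (optional alternatives to
#'   `z1`, `z2`).
#' @return An object of class `gs_info`.
#' @examples
#' trial_information(I1 = 312.8, I2 = 393.7, e = 2.797, z1 = 2.540, z2 = 2.718)
#' @export
trial_information <- function(I1, I2, e, z1 = NULL, z2 = NULL,
                              theta1 = NULL, theta_obs = NULL) {
  stopifnot(is.finite(I1), is.finite(I2), I1 > 0, I2 > I1,
            length(e) == 1L, !is.na(e))
  resolve <- function(z, theta, I, what) {
    if (!is.null(z) && !is.null(theta) &&
        abs(z - theta * sqrt(I)) > 1e-6) {
      stop("inconsistent z and effect-scale values for ", what)
    }
    if (is.null(z) && !is.null(theta)) z <- theta * sqrt(I)
    if (is.null(z)) z <- NA_real_
    z
  }
  z1 <- resolve(z1, theta1, I1, "stage 1")
  z2 <- resolve(z2, theta_obs, I2, "stage 2")
  structure(
    list(I1 = I1, I2 = I2, e = as.numeric(e),
         z1 = z1, z2 = z2,
         theta1 = z1 / sqrt(I1), theta_obs = z2 / sqrt(I2),
         info_fraction = I1 / I2),
    class = "gs_info"
  )
}

#' Build the trial information summary from cumulative counts
#'
#' Reduces cumulative two-arm binary counts at the interim and final
#' analysis to the [trial_information()] summary, using the pooled-variance
#' information convention (see [pooled_information()]).
#'
#' @param interim,final Cumulative [analysis_counts()] at the two analyses.
#' @param e Z-scale interim efficacy boundary.
#' @return An object of class `gs_info`.
#' @examples
#' interim <- analysis_counts(12, 97, 27, 101)
#' final <- analysis_counts(21, 134, 42, 143)
#' gs_info_from_counts(interim, final, e = 2.797)
#' @export
gs_info_from_counts <- function(interim, final, e) {
  I1 <- pooled_information(interim)
  I2 <- pooled_information(final)
  if (I2 <= I1) {
    stop("final-analysis information must exceed interim information")
  }
  trial_information(I1 = I1, I2 = I2, e = e,
                    theta1 = mle_difference(interim),
                    theta_obs = mle_difference(final))
}

#' @export
print.gs_info <- function(x, ...) {
  cat(sprintf("trial information: I1 = %.2f, I2 = %.2f (fraction %.3f)\n",
              x$I1, x$I2, x$info_fraction))
  cat(sprintf("interim boundary: e = %.4f (effect scale %.4f)\n",
              x$e, x$e / sqrt(x$I1)))
  if (!is.na(x$z1)) {
    cat(sprintf("stage 1: z1 = %.4f, theta1 = %.4f\n", x$z1, x$theta1))
  }
  if (!is.na(x$z2)) {
    cat(sprintf("overall: z2 = %.4f, theta_obs = %.4f\n", x$z2, x$theta_obs))
  }
  invisible(x)
}

# internal: require observed final-stage data
.need_z2 <- function(info) {
  if (is.na(info$z2)) {
    stop("this estimator needs the observed final-stage statistic (z2)")
  }
  invisible(info)
}
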