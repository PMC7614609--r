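# Cumulative two-arm binary counts and their reduction to effect estimates,
# observed information and standardized Wald statistics.

#' Cumulative two-arm binary counts at one analysis
#'
#' Container for the raw data of a two-arm trial with a binary endpoint at a
#' single (interim or final) analysis: cumulative successes and totals per
#' arm.
#'
#' @param successes_control,total_control Successes and total subjects on the
#'   control arm.
#' @param successes_treatment,total_treatment Successes and total subjects on
#'   the treatment arm.
#' @return An object of class `gs_counts`.
#' @examples
#' analysis_counts(12, 97, 27, 101)
#' @export
analysis_counts <- function(successes_control, total_control,
                            successes_treatment, total_treatment) {
  x <- c(successes_control, total_control, successes_treatment,
         total_treatment)
  if (length(x) != 4L || any(!is.finite(x)) || any(x != round(x))) {
    stop("counts must be four finite integers")
  }
  if (total_control <= 0 || total_treatment <= 0) {
    stop("totals must be positive")
  }
  if (successes_control < 0 || successes_control > total_control ||
      successes_treatment < 0 || successes_treatment > total_treatment) {
    stop("successes must lie in [0, total] for each arm")
  }
  structure(
    list(successes_control = as.integer(successes_control),
         total_control = as.integer(total_control),
         successes_treatment = as.integer(successes_treatment),
         total_treatment = as.integer(total_treatment)),
    class = "gs_counts"
  )
}

#' @export
print.gs_counts <- function(x, ...) {
  cat(sprintf("two-arm binary counts: control %d/%d, treatment %d/%d\n",
              x$successes_control, x$total_control,
              x$successes_treatment, x$total_treatment))
  invisible(x)
}

#' Observed information at one analysis (pooled-variance convention)
#'
#' Statistical information for the difference in proportions at a single
#' analysis, using the pooled success proportion:
#' `I = 1 / (pbar * (1 - pbar) * (1/n0 + 1/n1))`. This is the score-test
#' (null-variance) convention, under which the standardized Wald statistic is
#' `theta_hat * sqrt(I)`.
#'
#' @param counts A [analysis_counts()] object.
#' @return Observed information (inverse-variance units).
#' @examples
#' pooled_information(analysis_counts(12, 97, 27, 101))
#' @export
pooled_information <- function(counts) {
  stopifnot(inherits(counts, "gs_counts"))
  pbar <- (counts$successes_control + counts$successes_treatment) /
    (counts$total_control + counts$total_treatment)
  if (pbar <= 0 || pbar >= 1) {
    stop("degenerate pooled proportion (0 or 1): information is undefined")
  }
  1 / (pbar * (1 - pbar) *
         (1 / counts$total_control + 1 / counts$total_treatment))
}

#' Maximum likelihood estimate of the difference in proportions
#'
#' Difference in observed success proportions, treatment minus control.
#'
#' @param counts A [analysis_counts()] object.
#' @return The MLE of the treatment difference.
#' @examples
#' mle_difference(analysis_counts(21, 134, 42, 143)) # 0.1370
#' @export
mle_difference <- function(counts) {
  stopifnot(inherits(counts, "gs_counts"))
  counts$successes_treatment / counts$total_treatment -
    counts$successes_control / counts$total_control
}

#' Incremental (stage-specific) counts between two analyses
#'
#' Component-wise difference of cumulative counts; applying
#' [mle_difference()] to the result gives the stage-2 MLE, i.e. the estimate
#' based only on the data accrued after the interim analysis.
#'
#' @param interim,final Cumulative [analysis_counts()] at the interim and
#'   final analysis.
#' @return An [analysis_counts()] object holding the stage-2 increments.
#' @examples
#' incremental_counts(analysis_counts(12, 97, 27, 101),
#'                    analysis_counts(21, 134, 42, 143))
#' @export
incremental_counts <- function(interim, final) {
  stopifnot(inherits(interim, "gs_counts"), inherits(final, "gs_counts"))
  d <- mapply(function(a, b) b - a, unclass(interim), unclass(final))
  if (any(d < 0)) {
    stop("final cumulative counts must be >= interim counts component-wise")
  }
  if (d[["total_control"]] == 0 || d[["total_treatment"]] == 0) {
    stop("no additional subjects after the interim: stage-2 MLE is undefined")
  }
  analysis_counts(d[["successes_control"]], d[["total_control"]],
                  d[["successes_treatment"]], d[["total_treatment"]])
}

#' Standardized Wald statistic
#'
#' @param theta_hat Effect estimate.
#' @param information Observed information `I` at the same analysis.
#' @return `theta_hat * sqrt(I)`.
#' @examples
#' wald_z(0.1436, 312.8)
#' @export
wald_z <- function(theta_hat, information) {
  stopifnot(information > 0)
  theta_hat * sqrt(information)
}

#' Read cumulative counts from a delimited text file
#'
#' The file must be a CSV with columns `analysis_index`,
#' `successes_control`, `total_control`, `successes_treatment`,
#' `total_treatment`, one row per analysis (cumulative counts).
#'
#' @param path Path to the CSV file.
#' @return A list of [analysis_counts()] objects ordered by
#'   `analysis_index`.
#' @examples
#' path <- system.file("extdata", "musec_counts.csv", package = "gsepoint")
#' read_counts(path)
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path)
  need <- c("analysis_index", "successes_control", "total_control",
            "successes_treatment", "total_treatment")
  if (!all(need %in% names(df))) {
    stop("counts file must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[order(df$analysis_index), , drop = FALSE]
  out <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch(
      analysis_counts(df$successes_control[i], df$total_control[i],
                      df$successes_treatment[i], df$total_treatment[i]),
      error = function(e) {
        stop(sprintf("counts file row %d (analysis %s): %s", i,
                     df$analysis_index[i], conditionMessage(e)))
      }
    )
  })
  names(out) <- as.character(df$analysis_index)
  out
}
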