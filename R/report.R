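# Estimate reporting and file-based entry points: count-file parsing,
# design configuration, the full estimator suite as a single table, and
# CSV/JSON serialization.

.LABELS <- c(mle_overall = "MLE (overall)",
             mle_stage1 = "MLE (stage 1)",
             mue = "Median unbiased estimator (MUE)",
             umvue = "UMVUE",
             ubc_mle = "Bias-corrected MLE (UBC-MLE)",
             mle_stage2 = "MLE (stage 2)",
             cmue = "Conditional MUE (CMUE)",
             umvcue = "UMVCUE",
             cbc_mle = "Bias-corrected MLE (CBC-MLE)")

#' Full point-estimate report for a two-stage trial
#'
#' Reduces cumulative counts at the interim and final analysis to the
#' sufficient statistics and computes the complete estimator suite: the
#' overall, stage-1 and stage-2 MLEs, and the unconditional (MUE, UMVUE,
#' UBC-MLE) and conditional (CMUE, UMVCUE, CBC-MLE) adjusted estimators.
#' The stage-2 MLE is computed from the incremental counts (the
#' information-weighted alternative is available via
#' [stage2_mle_weighted()]). Relative differences are with respect to the
#' overall MLE. Optionally attaches parametric-bootstrap standard errors.
#'
#' If the interim statistic crosses the boundary the trial would have
#' stopped at stage 1; the conditional estimators are then omitted with a
#' message and the unconditional ones reduce to the stage-1 MLE.
#'
#' @param interim,final Cumulative [analysis_counts()] at the two analyses.
#' @param design A [obf_design()] object supplying the interim boundary, or
#'   `NULL` if `boundary` is given directly.
#' @param boundary Z-scale interim efficacy boundary (alternative to
#'   `design`).
#' @param se If `TRUE`, add parametric-bootstrap standard errors.
#' @param theta_se Assumed true effect for the bootstrap.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Optional integer seed for the bootstrap.
#' @return A data frame of class `gs_estimate_report` with columns
#'   `estimator`, `label`, `perspective`, `estimate`, `se` (optional),
#'   `rel_diff_pct`; design quantities are carried in attributes.
#' @examples
#' interim <- analysis_counts(12, 97, 27, 101)
#' final <- analysis_counts(21, 134, 42, 143)
#' estimate_report(interim, final, design = obf_design(2, 0.025))
#' @export
estimate_report <- function(interim, final, design = NULL, boundary = NULL,
                            se = FALSE, theta_se = 0.14, n_boot = 1e5,
                            seed = NULL) {
  if (is.null(boundary)) {
    if (is.null(design)) stop("supply either a design or a boundary")
    stopifnot(inherits(design, "gs_design"))
    if (design$n_stages != 2L) stop("the estimator suite is two-stage")
    boundary <- design$z_boundaries[1]
  }
  info <- gs_info_from_counts(interim, final, e = boundary)
  stopped <- info$z1 >= info$e
  if (stopped) {
    message("interim statistic crossed the boundary: the trial stops at ",
            "stage 1; conditional estimators are omitted")
    est <- c(mle_overall = info$theta1, mle_stage1 = info$theta1,
             mue = info$theta1, umvue = info$theta1, ubc_mle = info$theta1)
  } else {
    est <- c(
      mle_overall = info$theta_obs,
      mle_stage1 = info$theta1,
      mue = mue(info),
      umvue = umvue(info, stopped_stage = 2L),
      ubc_mle = ubc_mle(info),
      mle_stage2 = mle_difference(incremental_counts(interim, final)),
      cmue = cmue(info),
      umvcue = umvcue(info),
      cbc_mle = cbc_mle(info)
    )
  }
  nm <- names(est)
  out <- data.frame(
    estimator = nm,
    label = unname(.LABELS[nm]),
    perspective = ifelse(nm %in% .COND, "conditional",
                         ifelse(nm == "mle_overall", "naive",
                                "unconditional")),
    estimate = unname(est),
    rel_diff_pct = 100 * (unname(est) - est[["mle_overall"]]) /
      est[["mle_overall"]]
  )
  if (se) {
    bs <- bootstrap_se(theta_se, info, n_reps = n_boot, seed = seed)
    out$se <- bs$se[match(out$estimator, bs$estimator)]
    out <- out[, c("estimator", "label", "perspective", "estimate", "se",
                   "rel_diff_pct")]
  }
  structure(out,
            class = c("gs_estimate_report", "data.frame"),
            info = info,
            boundary = boundary,
            boundary_effect_scale = boundary / sqrt(info$I1),
            info_fraction = info$info_fraction,
            seed = seed,
            package_version = as.character(utils::packageVersion("gsepoint")))
}

#' @export
print.gs_estimate_report <- function(x, ...) {
  info <- attr(x, "info")
  cat(sprintf("two-stage group sequential estimate report (gsepoint %s)\n",
              attr(x, "package_version")))
  cat(sprintf("  z1 = %.3f, z2 = %.3f; information fraction %.3f\n",
              info$z1, info$z2, attr(x, "info_fraction")))
  cat(sprintf("  interim boundary %.4f (effect scale %.4f)\n",
              attr(x, "boundary"), attr(x, "boundary_effect_scale")))
  df <- as.data.frame(x)
  df$estimate <- sprintf("%.4f", df$estimate)
  if ("se" %in% names(df)) df$se <- sprintf("%.3f", df$se)
  df$rel_diff_pct <- sprintf("%+d%%", round(df$rel_diff_pct))
  df$rel_diff_pct[df$estimator == "mle_overall"] <- "-"
  df$estimator <- NULL
  print(df, row.names = FALSE)
  invisible(x)
}

#' Read a design configuration file
#'
#' Reads a YAML or JSON design configuration with keys `stages`, `alpha`
#' and (optionally) `info_fractions`, and constructs the corresponding
#' [obf_design()]. Validation is strict: unknown keys are rejected so that
#' a misspelled key cannot silently change the boundaries.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [obf_design()] object.
#' @export
read_design_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    stop("design config must be a .yaml/.yml or .json file")
  }
  allowed <- c("stages", "alpha", "info_fractions")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown design config keys: ", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$stages) || is.null(cfg$alpha)) {
    stop("design config needs keys 'stages' and 'alpha'")
  }
  if (is.null(cfg$info_fractions)) {
    obf_design(cfg$stages, cfg$alpha)
  } else {
    obf_design(cfg$stages, cfg$alpha, as.numeric(cfg$info_fractions))
  }
}

#' Write an estimate report to CSV or JSON
#'
#' CSV output follows the reporting convention of rounding estimates to 4
#' decimal places, standard errors to 3, and relative differences to whole
#' percents; JSON output carries full-precision values plus the design
#' metadata (boundary on both scales, information fraction, package
#' version, seed).
#'
#' @param report A [estimate_report()] result.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path,
                         format = c("auto", "csv", "json")) {
  stopifnot(inherits(report, "gs_estimate_report"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  }
  if (format == "csv") {
    df <- as.data.frame(report)
    df$estimate <- round(df$estimate, 4)
    if ("se" %in% names(df)) df$se <- round(df$se, 3)
    df$rel_diff_pct <- round(df$rel_diff_pct)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    info <- attr(report, "info")
    payload <- list(
      package_version = attr(report, "package_version"),
      seed = attr(report, "seed"),
      design = list(
        boundary_z = attr(report, "boundary"),
        boundary_effect_scale = attr(report, "boundary_effect_scale"),
        I1 = info$I1, I2 = info$I2,
        info_fraction = attr(report, "info_fraction"),
        z1 = info$z1, z2 = info$z2
      ),
      estimates = as.data.frame(report)
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Run the full estimation pipeline from files
#'
#' Reads a counts file ([read_counts()]) and a design configuration
#' ([read_design_config()]) or explicit boundary, computes the full
#' estimate report, and optionally writes it out.
#'
#' @param counts_file CSV of cumulative counts, one row per analysis; the
#'   first and last analyses are used.
#' @param design_config Optional path to a YAML/JSON design configuration.
#' @param boundary Optional explicit z-scale interim boundary.
#' @param output Optional output path (CSV or JSON by extension).
#' @param ... Passed on to [estimate_report()] (e.g. `se`, `seed`).
#' @return The [estimate_report()], invisibly if written to a file.
#' @export
run_estimate <- function(counts_file, design_config = NULL, boundary = NULL,
                         output = NULL, ...) {
  counts <- read_counts(counts_file)
  if (length(counts) < 2L) stop("counts file must contain two analyses")
  design <- if (!is.null(design_config)) read_design_config(design_config)
  report <- estimate_report(counts[[1L]], counts[[length(counts)]],
                            design = design, boundary = boundary, ...)
  if (!is.null(output)) {
    write_report(report, output)
    return(invisible(report))
  }
  report
}

#' Run the design, profile and simulate pipelines
#'
#' Thin file-oriented wrappers over [obf_design()], [bias_profile()] and
#' [simulate_replicates()]/[evaluate_estimators()], emitting CSV tables.
#'
#' @param design_config Path to a YAML/JSON design configuration.
#' @param output Optional CSV output path.
#' @return `run_design`: the boundary table as a data frame.
#' @export
run_design <- function(design_config, output = NULL) {
  design <- read_design_config(design_config)
  df <- data.frame(stage = seq_len(design$n_stages),
                   info_fraction = design$info_fractions,
                   z_boundary = design$z_boundaries,
                   nominal_p = design$nominal_pvalues)
  if (!is.null(output)) {
    utils::write.csv(df, output, row.names = FALSE, quote = FALSE)
  }
  df
}

#' @param info A [trial_information()] object.
#' @param theta_grid Grid of true effect values.
#' @return `run_profile`: the [bias_profile()] data frame.
#' @rdname run_design
#' @export
run_profile <- function(info, theta_grid, output = NULL) {
  prof <- bias_profile(info, theta_grid)
  if (!is.null(output)) {
    utils::write.csv(as.data.frame(prof), output, row.names = FALSE,
                     quote = FALSE)
  }
  prof
}

#' @param theta Vector of true effects to simulate under.
#' @param n_reps Replicates per effect value.
#' @param seed Integer seed; per-theta streams are derived by offset.
#' @return `run_simulate`: a data frame stacking the per-theta summaries.
#' @rdname run_design
#' @export
run_simulate <- function(theta, info, n_reps = 1e4, seed = 1,
                         output = NULL) {
  rows <- lapply(seq_along(theta), function(i) {
    reps <- simulate_replicates(theta[i], info, n_reps, seed = seed + i - 1)
    res <- evaluate_estimators(reps, info)
    cbind(theta = theta[i], res$overall,
          stop_fraction = res$stop_fraction)
  })
  df <- do.call(rbind, rows)
  if (!is.null(output)) {
    utils::write.csv(df, output, row.names = FALSE, quote = FALSE)
  }
  df
}
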