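# O'Brien-Fleming group sequential design construction: boundary constant,
# z-scale boundaries, and the overall type I error under the canonical joint
# distribution of the sequential test statistics.

# correlation matrix of (Z_1, ..., Z_K): Corr(Z_j, Z_k) = sqrt(t_j / t_k)
.canonical_corr <- function(info_fractions) {
  S <- outer(info_fractions, info_fractions,
             function(a, b) sqrt(pmin(a, b) / pmax(a, b)))
  diag(S) <- 1
  S
}

.check_fractions <- function(info_fractions) {
  if (any(!is.finite(info_fractions)) || any(info_fractions <= 0) ||
      any(info_fractions > 1) || any(diff(info_fractions) <= 0) ||
      info_fractions[length(info_fractions)] != 1) {
    stop("info_fractions must be strictly increasing, in (0, 1], last = 1")
  }
  invisible(info_fractions)
}

#' Overall type I error of a one-sided group sequential efficacy rule
#'
#' Probability, under the null effect, that the trial rejects at some
#' analysis: `Pr(exists k: Z_k >= e_k)` where `(Z_1, ..., Z_K)` follows the
#' canonical joint distribution (multivariate normal, unit variances,
#' `Corr(Z_j, Z_k) = sqrt(t_j / t_k)`). Computed as one minus the
#' multivariate normal rectangle probability via Miwa's deterministic
#' algorithm (absolute accuracy well below 1e-8 for the K used here).
#'
#' @param z_boundaries Vector of z-scale efficacy boundaries, one per
#'   analysis.
#' @param info_fractions Planned information fractions, strictly increasing,
#'   last equal to 1.
#' @return One-sided rejection probability under the null.
#' @examples
#' type_one_error(c(2.797, 1.977), c(0.5, 1)) # about 0.025
#' @export
type_one_error <- function(z_boundaries, info_fractions) {
  .check_fractions(info_fractions)
  stopifnot(length(z_boundaries) == length(info_fractions),
            all(is.finite(z_boundaries)))
  K <- length(z_boundaries)
  if (K == 1L) {
    return(stats::pnorm(z_boundaries, lower.tail = FALSE))
  }
  p <- mvtnorm::pmvnorm(upper = z_boundaries,
                        corr = .canonical_corr(info_fractions),
                        algorithm = mvtnorm::Miwa(steps = 4097))
  1 - as.numeric(p)
}

#' O'Brien-Fleming group sequential design
#'
#' Constructs the one-sided O'Brien-Fleming efficacy boundaries
#' `e_k = C(K, alpha) / sqrt(t_k)` (equal to `C * sqrt(K/k)` for equally
#' spaced looks), with the constant `C` calibrated by bracketed root-finding
#' so that the overall type I error under the canonical joint distribution
#' equals `alpha`.
#'
#' @param n_stages Number of analyses `K` (>= 1).
#' @param alpha Overall one-sided type I error, in (0, 0.5).
#' @param info_fractions Planned information fractions; defaults to equally
#'   spaced looks `k/K`.
#' @return An object of class `gs_design`: a list with `n_stages`, `alpha`,
#'   `info_fractions`, `boundary_constant`, `z_boundaries` and
#'   `nominal_pvalues` (the one-sided normal tail at each boundary).
#' @examples
#' obf_design(2, 0.025) # interim boundary about 2.797, final 1.977
#' @export
obf_design <- function(n_stages, alpha,
                       info_fractions = seq_len(n_stages) / n_stages) {
  stopifnot(n_stages >= 1, n_stages == round(n_stages),
            alpha > 0, alpha < 0.5,
            length(info_fractions) == n_stages)
  .check_fractions(info_fractions)
  if (n_stages == 1L) {
    C <- stats::qnorm(alpha, lower.tail = FALSE)
  } else {
    f <- function(C) {
      type_one_error(C / sqrt(info_fractions), info_fractions) - alpha
    }
    C <- stats::uniroot(f, c(0.5, 6), tol = 1e-12)$root
    achieved <- type_one_error(C / sqrt(info_fractions), info_fractions)
    if (abs(achieved - alpha) > 1e-8) {
      stop("boundary calibration did not converge to the requested alpha")
    }
  }
  z_boundaries <- C / sqrt(info_fractions)
  structure(
    list(n_stages = as.integer(n_stages),
         alpha = alpha,
         info_fractions = info_fractions,
         boundary_constant = C,
         z_boundaries = z_boundaries,
         nominal_pvalues = stats::pnorm(z_boundaries, lower.tail = FALSE)),
    class = "gs_design"
  )
}

#' @export
print.gs_design <- function(x, ...) {
  cat(sprintf(
    "O'Brien-Fleming design: K = %d, one-sided alpha = %g, C = %.6f\n",
    x$n_stages, x$alpha, x$boundary_constant))
  print(data.frame(stage = seq_len(x$n_stages),
                   info_fraction = x$info_fractions,
                   z_boundary = round(x$z_boundaries, 4),
                   nominal_p = round(x$nominal_pvalues, 4)),
        row.names = FALSE)
  invisible(x)
}
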