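# Shared fixtures: the MUSEC trial counts (cumulative, interim and final)
# and the derived trial information under the pooled-variance convention.

musec_interim <- analysis_counts(12, 97, 27, 101)
musec_final <- analysis_counts(21, 134, 42, 143)

# exact solver boundary for the two-stage one-sided 0.025 OBF design
musec_design <- obf_design(2, 0.025, c(0.5, 1))
musec_e <- musec_design$z_boundaries[1]

musec_info <- gs_info_from_counts(musec_interim, musec_final, e = musec_e)

# same information with the boundary as printed in the trial report
musec_info_printed <- gs_info_from_counts(musec_interim, musec_final,
                                          e = 2.797)

# scalar reference for the bivariate normal CDF, via the independent
# deterministic algorithm in mvtnorm
pbvn_ref <- function(h, k, rho) {
  as.numeric(mvtnorm::pmvnorm(upper = c(h, k),
                              corr = matrix(c(1, rho, rho, 1), 2),
                              algorithm = mvtnorm::Miwa(steps = 4097)))
}

# absolute-difference expectation (testthat tolerances are relative)
expect_close <- function(x, y, tol) {
  expect_lt(max(abs(x - y)), tol)
}
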