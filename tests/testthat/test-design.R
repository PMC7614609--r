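# Design construction, information calculus and count reduction.

test_that("pooled information reproduces the printed trial statistics", {
  I1 <- pooled_information(musec_interim)
  I2 <- pooled_information(musec_final)
  expect_close(wald_z(mle_difference(musec_interim), I1), 2.540, 5e-4)
  expect_close(wald_z(mle_difference(musec_final), I2), 2.718, 5e-4)
  expect_close(I1 / I2, 0.795, 5e-4)
  expect_close(1 - I1 / I2, 0.205, 5e-4)
  # back-solved from the printed z and effect: I = (z / theta)^2
  expect_close(I1, (2.540 / 0.1436)^2, 0.5)
})

test_that("pooled information is monotone in sample size and errs when degenerate", {
  base <- pooled_information(analysis_counts(20, 100, 30, 100))
  bigger <- pooled_information(analysis_counts(40, 200, 60, 200))
  expect_gt(bigger, base)
  # closed form: equal arms n = 100, pooled p = 0.5 ->
  # I = 1 / (0.25 * (2/100)) = 200
  expect_equal(pooled_information(analysis_counts(50, 100, 50, 100)), 200)
  expect_error(pooled_information(analysis_counts(0, 10, 0, 10)),
               "degenerate")
  expect_error(pooled_information(analysis_counts(10, 10, 10, 10)),
               "degenerate")
})

test_that("MLE differences match the printed stage estimates", {
  expect_close(mle_difference(musec_final), 0.1370, 5e-5)
  expect_close(mle_difference(musec_interim), 0.1436, 5e-5)
  expect_equal(mle_difference(analysis_counts(5, 50, 5, 50)), 0)
})

test_that("incremental counts give the stage-2 MLE and enforce monotonicity", {
  inc <- incremental_counts(musec_interim, musec_final)
  expect_equal(unclass(inc)[c(1, 2, 3, 4)],
               list(successes_control = 9L, total_control = 37L,
                    successes_treatment = 15L, total_treatment = 42L))
  expect_close(mle_difference(inc), 0.1139, 5e-5)
  expect_error(incremental_counts(musec_final, musec_interim), ">=")
  expect_error(incremental_counts(musec_interim, musec_interim),
               "undefined")
  inc2 <- incremental_counts(analysis_counts(0, 10, 0, 10),
                             analysis_counts(1, 20, 3, 20))
  expect_equal(mle_difference(inc2), 0.2)
})

test_that("OBF boundaries reproduce the trial design and the figure threshold", {
  d <- obf_design(2, 0.025, c(0.5, 1))
  expect_close(d$z_boundaries, c(2.797, 1.977), 2e-3)
  expect_equal(d$z_boundaries[1], d$boundary_constant * sqrt(2))
  d5 <- obf_design(2, 0.05, c(0.5, 1))
  expect_close(d5$nominal_pvalues[1], 0.0088, 5e-5)
  # one-stage design degenerates to the normal quantile
  d1 <- obf_design(1, 0.05)
  expect_close(d1$z_boundaries, qnorm(0.95), 1e-10)
  expect_error(obf_design(2, 0.025, c(1, 0.5)))
  expect_error(obf_design(2, 0.025, c(0.5, 0.9)))
})

test_that("type I error round-trips the design alpha across K and alpha", {
  for (K in 1:3) {
    for (alpha in c(0.01, 0.025, 0.05)) {
      d <- obf_design(K, alpha)
      expect_close(type_one_error(d$z_boundaries, d$info_fractions), alpha,
                   1e-7)
    }
  }
  expect_close(type_one_error(1.6449, 1), 0.05, 1e-4)
  # OBF boundaries are non-increasing across stages
  expect_true(all(diff(obf_design(3, 0.025)$z_boundaries) < 0))
})

test_that("two-stage type I error matches an independent bivariate computation", {
  # P(reject) = P(Z1 >= e1) + P(Z1 < e1, Z2 >= e2), via the package's own
  # bivariate kernel rather than the mvtnorm call inside type_one_error
  e <- c(2.797, 1.977)
  rho <- sqrt(0.5)
  direct <- pnorm(e[1], lower.tail = FALSE) +
    (pnorm(e[1]) - pbvn(e[1], e[2], rho))
  expect_close(type_one_error(e, c(0.5, 1)), direct, 1e-8)
  expect_close(direct, 0.025, 5e-4)
})

test_that("wald_z is the effect scaled by root information", {
  expect_equal(wald_z(0.1436, 312.8), 0.1436 * sqrt(312.8))
  expect_equal(wald_z(0, 500), 0)
})

test_that("trial information validates and derives both scales", {
  info <- trial_information(I1 = 100, I2 = 200, e = 2.5, z1 = 1, z2 = 2)
  expect_equal(info$theta1, 0.1)
  expect_equal(info$theta_obs, 2 / sqrt(200))
  expect_equal(info$info_fraction, 0.5)
  expect_error(trial_information(I1 = 200, I2 = 100, e = 2))
  expect_error(trial_information(I1 = 100, I2 = 200, e = 2, z1 = 1,
                                 theta1 = 0.5), "inconsistent")
})
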