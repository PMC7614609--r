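# Conditional estimators given continuation: conditional bias, CBC-MLE,
# UMVCUE, the conditional MLE density/CDF and the conditional MUE.

test_that("estimates reproduce the published case-study values", {
  expect_close(cbc_mle(musec_info), 0.1909, 5e-5)
  expect_close(umvcue(musec_info), 0.1724, 5e-5)
  expect_close(cmue(musec_info), 0.1851, 5e-5)
  expect_close(stage2_mle_weighted(musec_info), 0.1114, 5e-5)
})

test_that("conditional bias is negative, vanishes without a boundary, and solves the fixed point", {
  info <- musec_info_printed
  grid <- seq(-0.5, 1, by = 0.1)
  expect_true(all(conditional_bias_final(grid, info) < 0))
  direct <- -(sqrt(info$I1) / info$I2) *
    dnorm(info$e - 0.1909 * sqrt(info$I1)) /
    pnorm(info$e - 0.1909 * sqrt(info$I1))
  expect_equal(conditional_bias_final(0.1909, info), direct)
  expect_close(direct, -0.0539, 1e-4)
  cbc <- cbc_mle(info)
  expect_close(info$theta_obs - conditional_bias_final(cbc, info), cbc,
               1e-10)
  expect_gt(cbc, info$theta_obs)
  no_stop <- trial_information(I1 = info$I1, I2 = info$I2, e = Inf,
                               z2 = info$z2)
  expect_equal(conditional_bias_final(0.14, no_stop), 0)
  expect_equal(cbc_mle(no_stop), no_stop$theta_obs)
  expect_equal(umvcue(no_stop), no_stop$theta_obs)
  expect_close(cmue(no_stop), no_stop$theta_obs, 1e-9)
})

test_that("information-weighted decomposition ties UMVUE and UMVCUE exactly", {
  info <- musec_info
  lhs <- info$I1 * umvue(info, 2) + (info$I2 - info$I1) * umvcue(info)
  expect_close(lhs / (info$I2 * info$theta_obs), 1, 1e-12)
})

test_that("the conditional MLE density normalizes and matches the CDF", {
  for (theta in c(0, 0.14, 0.3)) {
    total <- integrate(conditional_mle_density, -Inf, Inf, theta = theta,
                       info = musec_info, rel.tol = 1e-9)$value
    expect_close(total, 1, 1e-6)
    # quadrature of the density is an independent route to the CDF used by
    # the CMUE root-finder
    at <- musec_info$theta_obs
    quad <- integrate(conditional_mle_density, -Inf, at, theta = theta,
                      info = musec_info, rel.tol = 1e-10)$value
    expect_close(conditional_mle_cdf(at, theta, musec_info), quad, 1e-8)
  }
})

test_that("without a boundary the conditional density is the unconditional normal", {
  no_stop <- trial_information(I1 = musec_info$I1, I2 = musec_info$I2,
                               e = Inf, z2 = musec_info$z2)
  m <- seq(-0.1, 0.4, by = 0.05)
  expect_close(conditional_mle_density(m, 0.14, no_stop),
               sqrt(no_stop$I2) * dnorm((m - 0.14) * sqrt(no_stop$I2)),
               1e-12)
})

test_that("the conditional density matches the empirical law of continuing replicates", {
  set.seed(7)
  n <- 1e6
  theta <- 0.14
  info <- musec_info
  rho <- sqrt(info$I1 / info$I2)
  z1 <- rnorm(n, theta * sqrt(info$I1))
  z2 <- theta * sqrt(info$I2) + rho * (z1 - theta * sqrt(info$I1)) +
    sqrt(1 - rho^2) * rnorm(n)
  keep <- z1 < info$e
  m <- sort(z2[keep] / sqrt(info$I2))
  Fhat <- seq_along(m) / length(m)
  Fan <- conditional_mle_cdf(m, theta, info)
  expect_lt(max(abs(Fhat - Fan)), 0.005)
})

test_that("the conditional CDF is strictly decreasing in theta (root uniqueness)", {
  grid <- seq(-0.2, 0.6, by = 0.05)
  Fs <- vapply(grid, function(th) {
    conditional_mle_cdf(musec_info$theta_obs, th, musec_info)
  }, numeric(1))
  expect_true(all(diff(Fs) < 0))
  # deep-tail fallback branch stays a proper probability
  far <- conditional_mle_cdf(musec_info$theta_obs, 0.8, musec_info)
  expect_true(far >= 0 && far <= 1)
})

test_that("case-study ordering of estimators holds as a regression fixture", {
  info <- musec_info
  mle <- info$theta_obs
  lower <- c(mue(info), ubc_mle(info), umvue(info, 2))
  upper <- c(cmue(info), umvcue(info), cbc_mle(info))
  expect_true(all(lower < mle))
  expect_true(all(upper > mle))
})
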