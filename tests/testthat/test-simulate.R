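# Canonical-distribution simulator, estimator sampling distributions and
# bootstrap standard errors.

test_that("replicates follow the canonical joint distribution", {
  reps <- simulate_replicates(0.14, musec_info, 1e5, seed = 3)
  expect_equal(nrow(reps), 1e5)
  # stopping rule bookkeeping
  expect_true(all((reps$z1 >= musec_info$e) == (reps$stopped_stage == 1L)))
  # empirical stop fraction vs the analytic stopping probability
  p <- stopping_probability(0.14, musec_info)
  expect_close(mean(reps$stopped_stage == 1L), p,
               3 * sqrt(p * (1 - p) / 1e5))
  # pre-truncation correlation equals the canonical parameter
  expect_close(cor(reps$z1, reps$z2), sqrt(musec_info$info_fraction),
               0.005)
  # marginal means on both stages
  expect_close(mean(reps$z1), 0.14 * sqrt(musec_info$I1), 3 / sqrt(1e5) * 1.1)
  expect_close(mean(reps$z2), 0.14 * sqrt(musec_info$I2), 3 / sqrt(1e5) * 1.1)
})

test_that("identical seeds give identical results", {
  a <- simulate_replicates(0.14, musec_info, 2000, seed = 9)
  b <- simulate_replicates(0.14, musec_info, 2000, seed = 9)
  expect_identical(a, b)
  ra <- evaluate_estimators(a, musec_info)
  rb <- evaluate_estimators(b, musec_info)
  expect_identical(ra$overall, rb$overall)
})

test_that("unbiased estimators recover theta and the MLE is biased upward", {
  for (theta in c(0.10, 0.14, 0.18)) {
    reps <- simulate_replicates(theta, musec_info, 1e4,
                                seed = 100 + round(1000 * theta))
    res <- evaluate_estimators(reps, musec_info)
    ov <- res$overall
    get <- function(nm, col) ov[ov$estimator == nm, col]
    mc <- function(nm) 3 * get(nm, "sd") / sqrt(get(nm, "n"))
    # UMVUE unbiased over all replicates; UMVCUE conditionally unbiased
    expect_close(get("umvue", "mean"), theta, mc("umvue"))
    expect_close(get("umvcue", "mean"), theta, mc("umvcue"))
    expect_close(get("mle_stage1", "mean"), theta, mc("mle_stage1"))
    expect_close(get("mle_stage2", "mean"), theta, mc("mle_stage2"))
    # unconditional selection bias of the overall MLE is positive
    expect_gt(get("mle_overall", "mean"), theta)
    # median property of the MUE (stage-1 stoppers report the stage-1 MLE)
    muev <- sampling_distribution(reps, musec_info)$unconditional$mue
    expect_close(mean(muev < theta), 0.5, 3 * 0.5 / sqrt(1e4))
  }
})

test_that("conditional median property of the CMUE holds under simulation", {
  theta <- 0.14
  reps <- simulate_replicates(theta, musec_info, 1e4, seed = 21)
  sd_ <- sampling_distribution(reps, musec_info)
  cmues <- sd_$conditional$cmue
  n <- length(cmues)
  expect_close(mean(cmues < theta), 0.5, 3 * 0.5 / sqrt(n))
})

test_that("evaluate_estimators mirrors the published simulation layout", {
  reps <- simulate_replicates(0.14, musec_info, 1e4, seed = 240)
  res <- evaluate_estimators(reps, musec_info)
  expect_s3_class(res, "gs_sim_result")
  expect_setequal(res$overall$estimator,
                  c("mle_overall", "mle_stage1", "mue", "umvue", "ubc_mle",
                    "mle_stage2", "cmue", "umvcue", "cbc_mle"))
  # group sizes add up
  bs <- res$by_stage
  expect_true(all(tapply(bs$n, bs$estimator, sum) == 1e4))
  # conditional estimators are evaluated over continuing replicates only
  n_cont <- sum(reps$stopped_stage == 2L)
  expect_true(all(res$overall$n[res$overall$perspective == "conditional"]
                  == n_cont))
  # stage-1 stoppers report the stage-1 MLE for every unconditional
  # estimator, so the stage-1 rows coincide
  s1rows <- bs[bs$stage == 1L, ]
  expect_equal(diff(range(s1rows$mean)), 0)
})

test_that("without a boundary all estimators coincide with the overall MLE", {
  no_stop <- trial_information(I1 = musec_info$I1, I2 = musec_info$I2,
                               e = Inf)
  reps <- simulate_replicates(0.14, no_stop, 2000, seed = 5)
  expect_true(all(reps$stopped_stage == 2L))
  sd_ <- sampling_distribution(reps, no_stop)
  mle <- sd_$unconditional$mle_overall
  for (nm in c("mue", "umvue", "ubc_mle")) {
    expect_close(sd_$unconditional[[nm]], mle, 1e-7)
  }
  for (nm in c("cmue", "umvcue", "cbc_mle")) {
    expect_close(sd_$conditional[[nm]], mle, 1e-7)
  }
  # and the bootstrap SE of the MLE approaches the closed form 1/sqrt(I2)
  bs <- bootstrap_se(0.14, no_stop, n_reps = 5e3, seed = 6)
  expect_close(bs$se[bs$estimator == "mle_overall"], 1 / sqrt(no_stop$I2),
               3 * (1 / sqrt(no_stop$I2)) / sqrt(2 * 5e3))
})

test_that("the sampling distributions show the published mixture structure", {
  reps <- simulate_replicates(0.14, musec_info, 1e4, seed = 77)
  sd_ <- sampling_distribution(reps, musec_info)
  n_cont <- sum(!sd_$stopped)
  expect_true(all(lengths(sd_$unconditional) == 1e4))
  expect_true(all(lengths(sd_$conditional) == n_cont))
  # stage-2 MLE has by far the widest conditional sampling distribution
  sds <- vapply(sd_$conditional, sd, numeric(1))
  expect_gt(sds[["mle_stage2"]], 1.3 * max(sds[c("cmue", "umvcue",
                                                 "cbc_mle")]))
  # unconditional estimators are a mixture: stoppers carry the stage-1 MLE
  expect_identical(sd_$unconditional$mue[sd_$stopped],
                   sd_$unconditional$mle_stage1[sd_$stopped])
})
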