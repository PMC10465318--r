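test_that("ratio_estimate substitutes the Taylor formulas directly", {
  est <- ratio_estimate(0.1, 0.05, 0.2)
  expect_equal(est$beta_iv, 0.5)
  expect_equal(est$se_iv, 0.25)
  expect_equal(est$or_iv, exp(0.5))

  null <- ratio_estimate(0, 0.05, 0.2)
  expect_equal(null$or_iv, 1)
  expect_equal(null$p, 1)

  second <- ratio_estimate(0.1, 0.05, 0.2, se_gx = 0.04, second_order = TRUE)
  expect_equal(second$se_iv,
               sqrt(0.05^2 / 0.2^2 + 0.1^2 * 0.04^2 / 0.2^4))
  expect_gt(second$se_iv, est$se_iv)

  expect_error(ratio_estimate(0.1, 0.05, 0), "degenerate")
})

test_that("the weak-instrument guard refuses F < 10 unless forced", {
  co <- small_cohort(n = 150, seed = 23, pgs_beta = -0.05)
  expect_error(ratio_mr(co, "si", "baseline"), "strength threshold")
  forced <- ratio_mr(co, "si", "baseline", force = TRUE)
  expect_s3_class(forced, "ratio_mr")
})

test_that("ratio MR is scale-equivariant in the exposure with an invariant
           Wald z", {
  co <- small_cohort(n = 3000, seed = 29)
  a <- ratio_mr(co, "si", "baseline")
  co2 <- co
  co2$vitd <- co2$vitd * 2
  b <- ratio_mr(co2, "si", "baseline")
  expect_equal(b$beta_iv, a$beta_iv / 2, tolerance = 1e-10)
  expect_equal(b$beta_iv / b$se_iv, a$beta_iv / a$se_iv, tolerance = 1e-10)
  expect_equal(b$p_linear, a$p_linear, tolerance = 1e-10)
})

test_that("the ratio estimator recovers a linear causal slope", {
  # 40 replicates at n = 4000 with slope 0.05 log-odds per ng/mL; the
  # deeper 200-replicate recovery run lives in the acceptance suite
  R <- 40; s <- 0.05
  est <- vapply(seq_len(R), function(r) {
    co <- generate_cohort(small_config(n = 4000, seed = 40000 + r,
                                       causal_model = "linear",
                                       causal_slope = s))
    ratio_mr(co, "si", "baseline")$beta_iv
  }, numeric(1))
  mc_se <- sd(est) / sqrt(R)
  expect_lt(abs(mean(est) - s), 3 * mc_se)
})

test_that("under the causal null the MR p-value is uniform", {
  R <- 150
  ps <- vapply(seq_len(R), function(r) {
    co <- generate_cohort(small_config(n = 1200, seed = 50000 + r))
    ratio_mr(co, "si", "baseline", force = TRUE)$p_linear
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  rate <- mean(ps < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / R))
})

test_that("power is alpha at the null OR, increases with n and approaches
           1", {
  expect_equal(mr_power_binary(1000, 0.04, 0.24, true_or = 1)$power, 0.05)
  p1 <- mr_power_binary(500, 0.04, 0.24, 1.5)$power
  p2 <- mr_power_binary(5000, 0.04, 0.24, 1.5)$power
  p3 <- mr_power_binary(5e6, 0.04, 0.24, 1.5)$power
  expect_true(p1 < p2 && p2 < p3)
  expect_gt(p3, 0.9999)
  # monotone in |log OR|
  expect_gt(mr_power_binary(1000, 0.04, 0.24, 2)$power,
            mr_power_binary(1000, 0.04, 0.24, 1.5)$power)
  expect_equal(mr_power_binary(1000, 0.04, 0.24, 0.5)$power,
               mr_power_binary(1000, 0.04, 0.24, 2)$power)
})

test_that("sex stratification partitions the sample and drops sex from the
           covariates", {
  co <- small_cohort(n = 2500, seed = 35)
  res <- sex_stratified(co, ratio_mr, trait = "si", horizon = "baseline",
                        force = TRUE, covariates = c("age", "sex"))
  expect_false(is_unavailable(res$male))
  expect_false(is_unavailable(res$female))
  expect_equal(res$male$n + res$female$n, nrow(co))

  males <- co[co$sex == "male", ]
  solo <- sex_stratified(males, ratio_mr, trait = "si",
                         horizon = "baseline", force = TRUE,
                         covariates = c("age", "sex"))
  expect_true(is_unavailable(solo$female))
  expect_false(is_unavailable(solo$male))
})
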