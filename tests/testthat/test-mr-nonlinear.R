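test_that("instrument-free exposure is orthogonal to the score and reduces
           the variance", {
  co <- small_cohort(n = 3000, seed = 51)
  res <- instrument_free_exposure(co, covariates = character())
  pgs <- compute_pgs(co)$score
  expect_lt(abs(cor(res, pgs)), 1e-10)
  expect_lt(abs(mean(res)), 1e-10)
  expect_lt(sd(res), sd(co$vitd))

  # constant score: residuals reduce to the centred exposure
  co$g_rs10741657 <- 1L; co$g_rs4588 <- 1L; co$g_rs7041 <- 1L
  co$pgs <- NULL
  res0 <- instrument_free_exposure(co, covariates = character())
  expect_equal(res0, co$vitd - mean(co$vitd), tolerance = 1e-10)
})

test_that("decile assignment gives near-equal deterministic strata", {
  expect_equal(tabulate(stratify_deciles(rnorm(100))), rep(10L, 10))
  set.seed(1)
  v <- rnorm(1411)
  a <- stratify_deciles(v)
  expect_equal(sort(unique(tabulate(a))), c(141L, 142L))
  expect_equal(sum(tabulate(a)), 1411L)
  expect_identical(a, stratify_deciles(v))
  # stratum means of the stratified values increase with the index
  expect_true(all(diff(tapply(v, a, mean)) > 0))

  expect_error(stratify_deciles(rnorm(50)), "at least")
  expect_error(stratify_deciles(rep(1, 200)), "degenerate")
})

test_that("K = 1 collapses the LACE to the full-sample linear MR estimate", {
  co <- small_cohort(n = 2000, seed = 57)
  aset <- build_outcomes(ensure_pgs_test(co), "si", "baseline")
  strata <- compute_laces(aset, rep(1L, nrow(aset)))
  lin <- ratio_mr(co, "si", "baseline", force = TRUE)
  expect_equal(strata$lace[1], lin$beta_iv, tolerance = 1e-10)
  expect_equal(strata$se_lace[1], lin$se_iv, tolerance = 1e-10)
})

test_that("per-stratum LACEs recover a linear causal slope when pooled", {
  R <- 30; s <- 0.05
  pooled <- vapply(seq_len(R), function(r) {
    co <- generate_cohort(small_config(n = 4000, seed = 60000 + r,
                                       causal_model = "linear",
                                       causal_slope = s))
    nonlinear_mr(co, "si", "baseline")$pooled_lace
  }, numeric(1))
  expect_lt(abs(mean(pooled) - s), 3 * sd(pooled) / sqrt(R))
})

test_that("the pooled LACE agrees with the linear MR estimate under a
           linear effect", {
  co <- generate_cohort(small_config(n = 8000, seed = 61,
                                     causal_model = "linear",
                                     causal_slope = 0.05))
  nl <- nonlinear_mr(co, "si", "baseline")
  lin <- ratio_mr(co, "si", "baseline")
  expect_lt(abs(nl$pooled_lace - lin$beta_iv),
            3 * sqrt(nl$pooled_se^2 + lin$se_iv^2))
})

test_that("identical stratum estimates give Q = 0, p = 1 and a linear best
           FP", {
  strata <- data.frame(stratum = 1:10, n = 100, n_cases = 20,
                       x_mean = seq(14, 32, 2),
                       beta_x = 1, se_x = 0.1,
                       beta_y = 0.05, se_y = 0.02,
                       lace = 0.05, se_lace = 0.02,
                       usable = TRUE, flag = "")
  class(strata) <- c("lace_set", "data.frame")
  res <- fp_meta_regression(strata)
  expect_equal(res$cochran_Q, 0, tolerance = 1e-20)
  expect_equal(res$p_cochranQ, 1)
  expect_equal(res$p_fp, 1)          # best degree-1 FP reduces to linear
  expect_equal(res$pooled_lace, 0.05)

  const <- instrument_constancy(strata)
  expect_equal(const$Q, 0, tolerance = 1e-20)
  expect_equal(const$p_Q_instrument, 1)
})

test_that("a forced trend in the instrument association is detected", {
  strata <- data.frame(stratum = 1:10, n = 100, n_cases = 20,
                       x_mean = seq(14, 32, 2),
                       beta_x = seq(0.5, 1.4, 0.1), se_x = 0.001,
                       beta_y = 0.05, se_y = 0.02,
                       lace = 0.05, se_lace = 0.02,
                       usable = TRUE, flag = "")
  class(strata) <- c("lace_set", "data.frame")
  const <- instrument_constancy(strata)
  expect_lt(const$p_trend_instrument, 1e-10)
  expect_lt(const$p_Q_instrument, 1e-10)
  expect_error(instrument_constancy(strata[1:2, ]), "at least 3")
})

test_that("the three non-linearity p-values are invariant to an affine
           shift of the score", {
  co <- small_cohort(n = 2500, seed = 63)
  co <- ensure_pgs_test(co)
  a <- nonlinear_mr(co, "si", "baseline")
  co2 <- co
  co2$pgs <- co2$pgs + 3L
  b <- nonlinear_mr(co2, "si", "baseline")
  expect_equal(b$p_fp, a$p_fp, tolerance = 1e-8)
  expect_equal(b$p_quadratic, a$p_quadratic, tolerance = 1e-8)
  expect_equal(b$p_cochranQ, a$p_cochranQ, tolerance = 1e-8)
})

test_that("sparse strata are flagged and excluded rather than crashing", {
  co <- small_cohort(n = 1500, seed = 65)
  aset <- build_outcomes(ensure_pgs_test(co), "sa", "baseline")  # ~1.5% cases
  res <- instrument_free_exposure(aset)
  assignment <- stratify_deciles(res)
  strata <- compute_laces(aset, assignment)
  expect_true(any(!strata$usable))
  expect_true(all(strata$flag[!strata$usable] != ""))
})
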