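test_that("generation is deterministic and respects the configured size", {
  cfg <- small_config(n = 300, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  attr(a, "generator_config") <- NULL
  attr(b, "generator_config") <- NULL
  expect_identical(a, b)
  expect_equal(nrow(a), 300)
  expect_true(all(a$vitd > 0))
  expect_true(all(unlist(a[c("g_rs10741657", "g_rs4588", "g_rs7041")]) %in%
                    0:2))
  expect_true(all(unlist(a[paste0(rep(c("si", "sp", "sa"), each = 3),
                                  "_w", 1:3)]) %in% c("yes", "no")))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(n_participants = 10), "n_participants")
  expect_error(generator_config(male_fraction = 1.2), "proportions")
  expect_error(generator_config(baseline_prevalences = c(si = -0.1, sp = 0.1,
                                                         sa = 0.01)),
               "proportions")
  expect_error(generator_config(allele_freqs = c(a = 0, b = 0.5, c = 0.5)),
               "allele_freqs")
  # pgs + confounder variance exceeding the marginal exposure variance
  expect_error(generator_config(pgs_beta = -6, confounder_effect_exposure = 0),
               "variance")
  # 2-year incident rate below the 1-year rate is incoherent
  expect_error(generator_config(incident_rates_2y = c(si = 0.1, sp = 0.05,
                                                      sa = 0.01)),
               "2-year")
})

test_that("degenerate prevalence of zero yields all-negative wave 1", {
  co <- small_cohort(n = 200, seed = 5,
                     baseline_prevalences = c(si = 0, sp = 0.1, sa = 0.01))
  expect_true(all(co$si_w1 == "no"))
})

test_that("baseline prevalence matches the binomial sampling oracle", {
  # oracle: per-replicate prevalence is Binomial(n, 0.241)/n, so the mean
  # over R replicates has SE sqrt(0.241 * 0.759 / (n * R))
  n <- 1426; R <- 200
  prev <- vapply(seq_len(R), function(r) {
    mean(generate_cohort(small_config(n = n, seed = 1000 + r))$si_w1 == "yes")
  }, numeric(1))
  mc_se <- sqrt(0.241 * (1 - 0.241) / (n * R))
  expect_lt(abs(mean(prev) - 0.241), 3 * mc_se)
})

test_that("incident-rate conditioning holds among baseline negatives", {
  co <- generate_cohort(small_config(n = 20000, seed = 77))
  for (tr in c("si", "sp")) {
    neg <- co[[paste0(tr, "_w1")]] == "no"
    r1 <- mean(co[[paste0(tr, "_w2")]][neg] == "yes")
    r2 <- mean((co[[paste0(tr, "_w2")]][neg] == "yes") |
                 (co[[paste0(tr, "_w3")]][neg] == "yes"))
    cfg <- attr(co, "generator_config")
    tol1 <- 3 * sqrt(cfg$incident_rates_1y[[tr]] *
                       (1 - cfg$incident_rates_1y[[tr]]) / sum(neg))
    tol2 <- 3 * sqrt(cfg$incident_rates_2y[[tr]] *
                       (1 - cfg$incident_rates_2y[[tr]]) / sum(neg))
    expect_lt(abs(r1 - cfg$incident_rates_1y[[tr]]), tol1)
    expect_lt(abs(r2 - cfg$incident_rates_2y[[tr]]), tol2)
  }
})

test_that("genotypes follow Hardy-Weinberg proportions at the configured
           frequencies", {
  co <- generate_cohort(small_config(n = 20000, seed = 31))
  cfg <- attr(co, "generator_config")
  for (s in names(cfg$allele_freqs)) {
    p <- cfg$allele_freqs[[s]]
    g <- co[[paste0("g_", s)]]
    obs <- tabulate(g + 1L, 3L)
    expected <- nrow(co) * c((1 - p)^2, 2 * p * (1 - p), p^2)
    chi2 <- sum((obs - expected)^2 / expected)
    expect_gt(pchisq(chi2, df = 2, lower.tail = FALSE), 0.001)
    expect_lt(abs(mean(g) / 2 - p), 3 * sqrt(p * (1 - p) / (2 * nrow(co))))
  }
})

test_that("exposure marginals and the calibrated instrument R^2 are
           realized", {
  co <- generate_cohort(small_config(n = 50000, seed = 13))
  cfg <- attr(co, "generator_config")
  expect_lt(abs(mean(co$vitd) - 23.12), 0.15)
  expect_lt(abs(sd(co$vitd) - 5.76), 0.15)
  inst <- fit_instrument(co)
  expect_lt(abs(inst$r_squared - cfg$target_r2), 0.005)
  expect_lt(inst$beta_gx, 0)   # lowering-allele convention
})

test_that("calibrate_pgs_beta is analytic and scale-equivariant", {
  cfg <- small_config()
  expect_equal(calibrate_pgs_beta(0, cfg), 0)
  b1 <- calibrate_pgs_beta(0.0397, cfg)
  cfg2 <- cfg
  cfg2$exposure_mean_sd <- c(23.12, 2 * 5.76)
  expect_equal(calibrate_pgs_beta(0.0397, cfg2), 2 * b1)
  # closed form: beta^2 * Var(PGS) / sd^2 = r2
  vpgs <- sum(2 * cfg$allele_freqs * (1 - cfg$allele_freqs))
  expect_equal(b1^2 * vpgs / 5.76^2, 0.0397, tolerance = 1e-12)
  expect_error(calibrate_pgs_beta(0.999, cfg), "unattainable")
})

test_that("missingness is applied at the configured rate", {
  co <- small_cohort(n = 5000, seed = 21, missing_rate = 0.1)
  miss <- mean(is.na(co$vitd))
  expect_lt(abs(miss - 0.1), 3 * sqrt(0.1 * 0.9 / 5000))
  expect_true(anyNA(co$g_rs4588))
})

test_that("cohort CSV round-trips with empty-field missing values", {
  co <- small_cohort(n = 60, seed = 8, missing_rate = 0.05)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(names(back), names(co))
  expect_equal(back$vitd, co$vitd)
  expect_identical(is.na(back$si_w2), is.na(co$si_w2))
})
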