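test_that("outcome construction matches hand enumeration on the toy table", {
  toy <- toy_wave_table()
  base <- build_outcomes(toy, "si", "baseline")
  expect_equal(nrow(base), 11)
  expect_equal(sum(base$outcome), 2)

  inc1 <- build_outcomes(toy, "si", "incident_1y")
  expect_equal(nrow(inc1), 8)               # 9 baseline-negative, 1 missing w2
  expect_equal(sum(inc1$outcome), 3)
  expect_equal(attr(inc1, "n_dropped_missing"), 1)
  expect_false(any(inc1$participant_id %in% c("T05", "T06")))

  inc2 <- build_outcomes(toy, "si", "incident_2y")
  expect_equal(nrow(inc2), 7)
  expect_equal(sum(inc2$outcome), 5)
  # wave-2 "yes" with wave-3 missing still counts as a case ("and/or")
  expect_true("T07" %in% inc2$participant_id)
  expect_equal(attr(inc2, "n_dropped_missing"), 2)
})

test_that("incident analysis sets are nested in the baseline negatives", {
  co <- small_cohort(n = 2000, seed = 3)
  neg <- co$participant_id[co$si_w1 == "no"]
  for (hz in c("incident_1y", "incident_2y")) {
    aset <- build_outcomes(co, "si", hz)
    expect_true(all(aset$participant_id %in% neg))
  }
})

test_that("25(OH)D categories respect the 20 and 30 ng/mL boundaries and
           partition the sample", {
  x <- c(19.99, 20, 29.99, 30, 23.12, 5, 60)
  expect_equal(as.character(categorize_vitd(x)),
               c("deficiency", "insufficiency", "insufficiency",
                 "sufficiency", "insufficiency", "deficiency",
                 "sufficiency"))
  co <- small_cohort(n = 1000, seed = 4)
  expect_equal(sum(table(categorize_vitd(co$vitd))), 1000)
  expect_error(categorize_vitd(c(10, -1)), "positive")
})

test_that("fit_continuous on a single binary predictor equals the 2x2
           cross-product odds ratio", {
  d <- data.frame(outcome = rep(c(1, 0, 1, 0), c(10, 90, 20, 80)),
                  vitd = rep(c(1, 1, 0, 0), c(10, 90, 20, 80)))
  fit <- fit_continuous(d)
  logor <- fit$table$estimate[fit$table$term == "vitd"]
  expect_equal(logor, log((10 * 80) / (90 * 20)), tolerance = 1e-6)
  expect_equal(exp(logor), 0.4444444, tolerance = 1e-6)
})

test_that("fit_continuous errors on a one-class outcome and flags
           separation", {
  d <- data.frame(outcome = rep(1, 50), vitd = rnorm(50, 23, 5))
  expect_error(fit_continuous(d), "one class")
  sep <- data.frame(outcome = rep(c(0, 1), each = 50),
                    vitd = c(rnorm(50, 10, 1), rnorm(50, 40, 1)))
  expect_error(fit_continuous(sep), "separation")
})

test_that("a null exposure has OR near 1 and the CI brackets the point
           estimate", {
  co <- small_cohort(n = 8000, seed = 6)
  aset <- build_outcomes(co, "si", "baseline")
  fit <- fit_continuous(aset, covariates = c("age", "sex"))
  row <- fit$table[fit$table$term == "vitd", ]
  expect_lt(abs(log(row$or)), 3 * row$se)
  expect_true(row$ci_lower < row$or && row$or < row$ci_upper)
})

test_that("categorical fit recovers a constructed insufficiency odds ratio", {
  # deficiency: odds 0.25; insufficiency: odds 0.125 (OR 0.5);
  # sufficiency: odds 0.25 (OR 1)
  d <- data.frame(
    vitd = rep(c(15, 25, 35), times = c(500, 900, 500)),
    outcome = c(rep(c(1, 0), c(100, 400)), rep(c(1, 0), c(100, 800)),
                rep(c(1, 0), c(100, 400))))
  fit <- fit_categorical(d)
  tab <- fit$table
  or_ins <- tab$or[tab$term == "vitd_catinsufficiency"]
  or_suf <- tab$or[tab$term == "vitd_catsufficiency"]
  expect_equal(or_ins, 0.5, tolerance = 1e-6)
  expect_equal(or_suf, 1, tolerance = 1e-6)
  expect_equal(fit$reference, "deficiency")
})

test_that("an empty category leaves the other contrast estimable", {
  d <- data.frame(vitd = rep(c(15, 25), times = c(300, 300)),
                  outcome = rep(c(1, 0, 1, 0), c(60, 240, 30, 270)))
  fit <- fit_categorical(d)
  expect_equal(fit$undefined, "sufficiency")
  expect_false("vitd_catsufficiency" %in% fit$table$term)
  expect_true("vitd_catinsufficiency" %in% fit$table$term)
})
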