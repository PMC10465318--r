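#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set for [generate_cohort()].  The
#' defaults reproduce the marginal structure of a three-wave early-adolescent
#' cohort: serum 25(OH)D approximately normal with mean 23.12 and SD 5.76
#' ng/mL, baseline suicidal ideation/plans/attempts (SI/SP/SA) prevalences
#' 24.1%/10.1%/1.5%, 1-year incident rates 12.8%/7.8%/2.8% and 2-year
#' incident rates 25.6%/13.4%/4.1% among baseline-negatives, 60.8% male,
#' age 12.48 (SD 0.48) years, and a three-SNP unweighted polygenic score
#' whose per-allele effect is calibrated so the score explains 3.97% of the
#' 25(OH)D variance.
#'
#' The polygenic score counts 25(OH)D-lowering alleles, so `pgs_beta` is
#' negative by convention: each additional low-vitamin-D allele lowers the
#' expected serum concentration.  The default allele frequencies are
#' placeholders plausible for an East-Asian population; they are
#' configuration parameters, not estimates.
#'
#' A single standard-normal latent confounder shifts both the exposure
#' (`confounder_effect_exposure`, ng/mL per confounder SD) and each outcome's
#' log-odds (`confounder_effect_outcome`).  The Gaussian exposure noise is
#' scaled so the marginal SD equals `exposure_mean_sd[2]` exactly, which
#' requires `pgs_beta^2 * Var(PGS) + confounder_effect_exposure^2 <
#' exposure_mean_sd[2]^2`.
#'
#' @param n_participants number of rows to generate (at least 20).
#' @param male_fraction proportion of males.
#' @param age_mean_sd length-2 numeric, mean and SD of age in years.
#' @param allele_freqs named length-3 vector of frequencies (in (0,1)) of the
#'   25(OH)D-lowering allele at rs10741657, rs4588 and rs7041.
#' @param pgs_beta change in 25(OH)D (ng/mL) per low-vitamin-D allele;
#'   negative by convention.  `NULL` (default) calibrates its magnitude with
#'   [calibrate_pgs_beta()] so the score explains `target_r2` of the
#'   exposure variance.
#' @param target_r2 variance fraction used when `pgs_beta` is `NULL`.
#' @param exposure_mean_sd length-2 numeric, marginal mean and SD of serum
#'   25(OH)D in ng/mL.
#' @param confounder_effect_exposure ng/mL shift per confounder SD.
#' @param confounder_effect_outcome log-odds shift per confounder SD.
#' @param causal_model `"null"`, `"linear"` or `"threshold"` effect of
#'   25(OH)D on each outcome's log-odds.
#' @param causal_slope log-odds per ng/mL (linear model), or the slope below
#'   the threshold (threshold model).
#' @param causal_threshold ng/mL; above it the threshold model is flat.
#' @param baseline_prevalences,incident_rates_1y,incident_rates_2y named
#'   length-3 vectors (si, sp, sa) of proportions.  Incident rates apply to
#'   participants negative for that trait at wave 1.
#' @param persistence probability a wave-positive participant is positive
#'   again at the next wave (only affects baseline-positive trajectories,
#'   which no incident analysis uses).
#' @param missing_rate completely-at-random missingness applied per cell to
#'   genotypes, exposure and outcomes.
#' @param seed integer seed; the generator is fully deterministic given the
#'   config.
#' @return a validated list of class `"generator_config"`.
#' @seealso [generate_cohort()], [calibrate_pgs_beta()]
#' @export
generator_config <- function(n_participants = 1426L,
                             male_fraction = 0.608,
                             age_mean_sd = c(12.48, 0.48),
                             allele_freqs = c(rs10741657 = 0.60,
                                              rs4588 = 0.30,
                                              rs7041 = 0.25),
                             pgs_beta = NULL,
                             target_r2 = 0.0397,
                             exposure_mean_sd = c(23.12, 5.76),
                             confounder_effect_exposure = -1.0,
                             confounder_effect_outcome = 0.3,
                             causal_model = c("null", "linear", "threshold"),
                             causal_slope = 0,
                             causal_threshold = 20,
                             baseline_prevalences = c(si = 0.241, sp = 0.101,
                                                      sa = 0.015),
                             incident_rates_1y = c(si = 0.128, sp = 0.078,
                                                   sa = 0.028),
                             incident_rates_2y = c(si = 0.256, sp = 0.134,
                                                   sa = 0.041),
                             persistence = 0.6,
                             missing_rate = 0,
                             seed = 1L) {
  causal_model <- match.arg(causal_model)
  cfg <- list(n_participants = as.integer(n_participants),
              male_fraction = male_fraction,
              age_mean_sd = age_mean_sd,
              allele_freqs = allele_freqs,
              pgs_beta = pgs_beta,
              target_r2 = target_r2,
              exposure_mean_sd = exposure_mean_sd,
              confounder_effect_exposure = confounder_effect_exposure,
              confounder_effect_outcome = confounder_effect_outcome,
              causal_model = causal_model,
              causal_slope = causal_slope,
              causal_threshold = causal_threshold,
              baseline_prevalences = baseline_prevalences,
              incident_rates_1y = incident_rates_1y,
              incident_rates_2y = incident_rates_2y,
              persistence = persistence,
              missing_rate = missing_rate,
              seed = as.integer(seed))
  if (is.null(cfg$pgs_beta)) {
    cfg$pgs_beta <- -calibrate_pgs_beta(cfg$target_r2, cfg)
  }
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  stop_cfg <- function(...) stop("invalid generator config: ", ...,
                                 call. = FALSE)
  if (!is.finite(cfg$n_participants) || cfg$n_participants < 20L) {
    stop_cfg("n_participants must be >= 20")
  }
  props <- c(male_fraction = cfg$male_fraction,
             missing_rate = cfg$missing_rate,
             persistence = cfg$persistence,
             cfg$baseline_prevalences, cfg$incident_rates_1y,
             cfg$incident_rates_2y)
  if (any(!is.finite(props)) || any(props < 0) || any(props > 1)) {
    stop_cfg("all proportions must lie in [0, 1]")
  }
  if (length(cfg$allele_freqs) != 3L || any(cfg$allele_freqs <= 0) ||
      any(cfg$allele_freqs >= 1)) {
    stop_cfg("allele_freqs must be three proportions in (0, 1)")
  }
  if (length(cfg$exposure_mean_sd) != 2L || cfg$exposure_mean_sd[2] <= 0) {
    stop_cfg("exposure_mean_sd must be (mean, sd) with sd > 0")
  }
  if (length(cfg$age_mean_sd) != 2L || cfg$age_mean_sd[2] < 0) {
    stop_cfg("age_mean_sd must be (mean, sd) with sd >= 0")
  }
  bad_inc <- cfg$incident_rates_2y < cfg$incident_rates_1y
  if (any(bad_inc)) {
    stop_cfg("2-year incident rates must be >= 1-year rates (",
             paste(names(cfg$incident_rates_1y)[bad_inc], collapse = ", "),
             ")")
  }
  v_pgs <- pgs_variance(cfg$allele_freqs)
  resid_var <- cfg$exposure_mean_sd[2]^2 - cfg$pgs_beta^2 * v_pgs -
    cfg$confounder_effect_exposure^2
  if (resid_var <= 0) {
    stop_cfg("pgs and confounder effects exceed the target exposure ",
             "variance; reduce |pgs_beta| or |confounder_effect_exposure|")
  }
  invisible(cfg)
}

# Variance of an allele-count score under Hardy-Weinberg: sum of 2 p (1 - p).
pgs_variance <- function(allele_freqs) {
  sum(2 * allele_freqs * (1 - allele_freqs))
}

#' Per-allele effect giving a target instrument R-squared
#'
#' Analytic calibration of the polygenic-score effect on the exposure: with
#' score variance \eqn{V_G = \sum_k 2 p_k (1 - p_k)} under Hardy-Weinberg and
#' total exposure variance \eqn{\sigma_X^2}, the variance fraction explained
#' by the score is \eqn{\beta^2 V_G / \sigma_X^2}, so
#' \eqn{|\beta| = \sigma_X \sqrt{R^2 / V_G}}.
#'
#' @param target_r2 desired variance fraction, in `[0, 1)`.
#' @param config a [generator_config()] (only `allele_freqs` and
#'   `exposure_mean_sd` are used; may be a plain list with those fields).
#' @return the magnitude of the per-allele effect in ng/mL (apply a negative
#'   sign for a score that counts 25(OH)D-lowering alleles).
#' @export
calibrate_pgs_beta <- function(target_r2, config) {
  if (!is.numeric(target_r2) || length(target_r2) != 1L ||
      !is.finite(target_r2) || target_r2 < 0 || target_r2 >= 1) {
    stop("target_r2 must be a single value in [0, 1)")
  }
  v_pgs <- pgs_variance(config$allele_freqs)
  if (v_pgs <= 0) stop("degenerate allele frequencies: score has no variance")
  sd_x <- config$exposure_mean_sd[2]
  # feasibility: the genetic component cannot exceed the total variance net
  # of the confounder contribution when the config carries one
  c_x <- config$confounder_effect_exposure
  if (!is.null(c_x) && target_r2 >= 1 - c_x^2 / sd_x^2) {
    stop("target_r2 unattainable: genetic plus confounder variance would ",
         "exceed the configured exposure variance")
  }
  sd_x * sqrt(target_r2 / v_pgs)
}

# Solve the intercept a such that mean(plogis(a + eta)) == target.
calibrate_intercept <- function(eta, target) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  uniroot(function(a) mean(plogis(a + eta)) - target,
          interval = c(-40, 40), tol = 1e-10)$root
}

draw_binary <- function(eta, alpha) {
  if (!is.finite(alpha)) {
    return(rep(if (alpha > 0) 1L else 0L, length(eta)))
  }
  rbinom(length(eta), 1L, plogis(alpha + eta))
}

# Causal contribution of the exposure to the outcome log-odds, centred at
# the configured exposure mean so intercept calibration is stable.
causal_logodds <- function(vitd, cfg) {
  switch(cfg$causal_model,
         null = rep(0, length(vitd)),
         linear = cfg$causal_slope * (vitd - cfg$exposure_mean_sd[1]),
         threshold = cfg$causal_slope *
           pmin(vitd - cfg$causal_threshold, 0))
}

#' Generate a synthetic three-wave cohort
#'
#' Draws a cohort table with the structure the downstream analyses assume:
#' genotypes at Hardy-Weinberg proportions, serum 25(OH)D built from the
#' polygenic score, a latent shared confounder and Gaussian noise scaled so
#' the marginal SD matches the configuration, and three annual waves of
#' dichotomous SI/SP/SA outcomes drawn from logistic models embedding the
#' configured causal effect.  Wave-2 and wave-3 intercepts are calibrated so
#' the configured 1- and 2-year incident rates hold, in expectation, among
#' participants negative for the trait at wave 1.
#'
#' The generator is deterministic given the config (including its seed), and
#' each column family draws from its own RNG substream, so adding a column
#' to the generator does not perturb previously generated ones.
#'
#' @param config a [generator_config()].
#' @return a `data.frame` with one row per participant: `participant_id`,
#'   `sex`, `age`, six socio-demographic/behavioural covariates, three
#'   psychiatric scores, genotypes `g_rs10741657`, `g_rs4588`, `g_rs7041`
#'   (counts of the 25(OH)D-lowering allele, 0/1/2), `vitd` (ng/mL) and
#'   wave-by-trait outcomes `si_w1` ... `sa_w3` coded `"yes"`/`"no"` with
#'   `NA` for missing.
#' @examples
#' cohort <- generate_cohort(generator_config(n_participants = 200, seed = 7))
#' mean(cohort$si_w1 == "yes")
#' @export
generate_cohort <- function(config) {
  cfg <- if (inherits(config, "generator_config")) config else {
    do.call(generator_config, config)
  }
  validate_generator_config(cfg)
  n <- cfg$n_participants
  seed <- cfg$seed

  sex <- with_substream(seed, 1L, {
    ifelse(rbinom(n, 1L, cfg$male_fraction) == 1L, "male", "female")
  })
  age <- with_substream(seed, 2L, {
    round(rnorm(n, cfg$age_mean_sd[1], cfg$age_mean_sd[2]), 2)
  })

  covars <- with_substream(seed, 3L, {
    data.frame(
      household_registration = sample(c("urban", "rural"), n, TRUE,
                                      prob = c(0.55, 0.45)),
      family_economy = sample(c("low", "middle", "high"), n, TRUE,
                              prob = c(0.25, 0.60, 0.15)),
      paternal_education = sample(c("primary", "secondary", "tertiary"), n,
                                  TRUE, prob = c(0.30, 0.50, 0.20)),
      maternal_education = sample(c("primary", "secondary", "tertiary"), n,
                                  TRUE, prob = c(0.35, 0.45, 0.20)),
      moderate_pa = sample(c("none", "1-3_days", ">=4_days"), n, TRUE,
                           prob = c(0.30, 0.45, 0.25)),
      vigorous_pa = sample(c("none", "1-3_days", ">=4_days"), n, TRUE,
                           prob = c(0.40, 0.40, 0.20)),
      impulsivity = round(rnorm(n, 50, 10), 1),
      depression = round(rnorm(n, 50, 10), 1),
      anxiety = round(rnorm(n, 50, 10), 1),
      stringsAsFactors = FALSE)
  })

  confounder <- with_substream(seed, 4L, rnorm(n))

  geno <- with_substream(seed, 5L, {
    vapply(cfg$allele_freqs, function(p) rbinom(n, 2L, p), integer(n))
  })
  colnames(geno) <- paste0("g_", names(cfg$allele_freqs))
  pgs <- rowSums(geno)

  v_pgs <- pgs_variance(cfg$allele_freqs)
  sd_noise <- sqrt(cfg$exposure_mean_sd[2]^2 - cfg$pgs_beta^2 * v_pgs -
                     cfg$confounder_effect_exposure^2)
  vitd <- with_substream(seed, 6L, {
    mu <- cfg$exposure_mean_sd[1] +
      cfg$pgs_beta * (pgs - 2 * sum(cfg$allele_freqs)) +
      cfg$confounder_effect_exposure * confounder
    pmax(round(mu + rnorm(n, 0, sd_noise), 2), 0.5)
  })

  h <- causal_logodds(vitd, cfg)
  eta <- h + cfg$confounder_effect_outcome * confounder

  traits <- c("si", "sp", "sa")
  waves <- matrix(NA_integer_, n, 9L,
                  dimnames = list(NULL, paste0(rep(traits, each = 3L), "_w",
                                               rep(1:3, 3L))))
  for (i in seq_along(traits)) {
    tr <- traits[i]
    w1 <- with_substream(seed, 10L + i, {
      draw_binary(eta, calibrate_intercept(eta, cfg$baseline_prevalences[[tr]]))
    })
    w2 <- with_substream(seed, 20L + i, {
      out <- integer(n)
      neg <- w1 == 0L
      if (any(neg)) {
        a2 <- calibrate_intercept(eta[neg], cfg$incident_rates_1y[[tr]])
        out[neg] <- draw_binary(eta[neg], a2)
      }
      if (any(!neg)) out[!neg] <- rbinom(sum(!neg), 1L, cfg$persistence)
      out
    })
    w3 <- with_substream(seed, 30L + i, {
      out <- integer(n)
      r1 <- cfg$incident_rates_1y[[tr]]
      r2 <- cfg$incident_rates_2y[[tr]]
      new3 <- if (r1 < 1) (r2 - r1) / (1 - r1) else 0
      nn <- w1 == 0L & w2 == 0L          # still at risk of a first onset
      if (any(nn)) {
        a3 <- calibrate_intercept(eta[nn], new3)
        out[nn] <- draw_binary(eta[nn], a3)
      }
      prev_pos <- w2 == 1L
      if (any(prev_pos)) out[prev_pos] <- rbinom(sum(prev_pos), 1L,
                                                 cfg$persistence)
      relapse <- w1 == 1L & w2 == 0L
      if (any(relapse)) out[relapse] <- rbinom(sum(relapse), 1L, 0.2)
      out
    })
    waves[, paste0(tr, "_w", 1:3)] <- cbind(w1, w2, w3)
  }
  wave_df <- as.data.frame(lapply(as.data.frame(waves),
                                  function(x) c("no", "yes")[x + 1L]),
                           stringsAsFactors = FALSE)

  cohort <- data.frame(participant_id = sprintf("P%05d", seq_len(n)),
                       sex = sex, age = age, covars,
                       as.data.frame(geno), vitd = vitd, wave_df,
                       stringsAsFactors = FALSE)

  if (cfg$missing_rate > 0) {
    maskable <- c(colnames(geno), "vitd", colnames(waves))
    cohort[maskable] <- with_substream(seed, 60L, {
      lapply(cohort[maskable], function(col) {
        col[rbinom(n, 1L, cfg$missing_rate) == 1L] <- NA
        col
      })
    })
  }
  attr(cohort, "generator_config") <- cfg
  cohort
}

#' Write / read a cohort table as CSV
#'
#' The on-disk format is RFC-4180 CSV with a fixed column order (the order
#' produced by [generate_cohort()]) and missing values as empty fields.
#'
#' @param cohort a cohort `data.frame`.
#' @param path file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the cohort `data.frame`.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"))
  df
}
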