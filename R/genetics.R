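#' Unweighted vitamin D polygenic score
#'
#' Sums the counts of the 25(OH)D-lowering allele over the included SNPs.
#' The score is unweighted: each allele contributes 1 regardless of its
#' estimated effect size.  A participant's score is missing whenever any
#' included genotype is missing (complete-case propagation).
#'
#' @param cohort a cohort `data.frame` (or any data.frame holding the
#'   genotype columns).
#' @param snps character vector of genotype column names; defaults to the
#'   three instrument SNPs.
#' @return an object of class `"pgs_result"`: a list with `score` (integer
#'   vector, one per row, in `[0, 2 * length(snps)]`), `included_snps` and
#'   `excluded_snps` (data.frame of snp/reason, empty here; populated when
#'   the result comes from [screen_snps()] driven scoring).
#' @examples
#' d <- data.frame(g_rs10741657 = c(0, 2, 1), g_rs4588 = c(0, 2, 0),
#'                 g_rs7041 = c(0, 2, 2))
#' compute_pgs(d)$score
#' @export
compute_pgs <- function(cohort,
                        snps = c("g_rs10741657", "g_rs4588", "g_rs7041")) {
  missing_cols <- setdiff(snps, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("genotype columns not found: ", paste(missing_cols, collapse = ", "))
  }
  g <- as.matrix(cohort[snps])
  storage.mode(g) <- "double"
  bad <- which(!is.na(g) & !(g %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("genotypes must be allele counts in {0, 1, 2}; offending row(s): ",
         paste(unique(utils::head(bad[, "row"], 5L)), collapse = ", "),
         " in column(s) ",
         paste(unique(snps[utils::head(bad[, "col"], 5L)]), collapse = ", "))
  }
  score <- as.integer(rowSums(g))   # NA if any component missing
  structure(list(score = score, included_snps = snps,
                 excluded_snps = data.frame(snp = character(),
                                            reason = character(),
                                            stringsAsFactors = FALSE)),
            class = "pgs_result")
}

#' @export
print.pgs_result <- function(x, ...) {
  cat("Unweighted polygenic score over", length(x$included_snps), "SNPs:",
      paste(x$included_snps, collapse = ", "), "\n")
  cat("  non-missing scores:", sum(!is.na(x$score)), "of", length(x$score),
      "; range", paste(range(x$score, na.rm = TRUE), collapse = "-"), "\n")
  invisible(x)
}

# Cohort with a `pgs` column attached (computed if absent).
ensure_pgs <- function(cohort, snps = c("g_rs10741657", "g_rs4588",
                                        "g_rs7041")) {
  if (!("pgs" %in% names(cohort))) {
    cohort$pgs <- compute_pgs(cohort, snps)$score
  }
  cohort
}

#' Screen candidate SNPs for association with the exposure
#'
#' Fits, per SNP, a linear model of serum 25(OH)D on the allele count
#' adjusted for age and sex, and excludes SNPs whose association p-value is
#' at or above `alpha`.  SNPs with no genotypic variation are excluded with
#' reason `"no variation"` rather than causing an error.
#'
#' @param cohort cohort `data.frame` with `vitd`, `age`, `sex` and the
#'   genotype columns.
#' @param snps genotype column names to screen.
#' @param alpha significance level for retention (default 0.05).
#' @param adjust covariate names for the per-SNP model.
#' @return a `data.frame` with one row per SNP: `snp`, `beta`, `se`, `p`,
#'   `kept` (logical) and `reason` for exclusions.
#' @export
screen_snps <- function(cohort, snps = c("g_rs10741657", "g_rs4588",
                                         "g_rs7041"),
                        alpha = 0.05, adjust = c("age", "sex")) {
  if (length(snps) < 1L) stop("at least one candidate SNP is required")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  rows <- lapply(snps, function(s) {
    d <- cohort[c("vitd", s, adjust)]
    d <- d[complete.cases(d), , drop = FALSE]
    g <- d[[s]]
    if (length(unique(g)) < 2L) {
      return(data.frame(snp = s, beta = NA_real_, se = NA_real_,
                        p = NA_real_, kept = FALSE, reason = "no variation",
                        stringsAsFactors = FALSE))
    }
    f <- as.formula(paste("vitd ~", s,
                          if (length(adjust)) paste("+", paste(adjust,
                                                               collapse = " + "))
                          else ""))
    fit <- lm(f, data = d)
    sm <- summary(fit)$coefficients
    b <- sm[s, "Estimate"]
    se <- sm[s, "Std. Error"]
    p <- sm[s, "Pr(>|t|)"]
    keep <- p < alpha
    data.frame(snp = s, beta = b, se = se, p = p, kept = keep,
               reason = if (keep) "" else "p >= alpha",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Instrument F-statistic from R-squared and sample size
#'
#' The strength of the genetic instrument given the variance fraction it
#' explains: `F = (n - 2) * r2 / (1 - r2)`.  Values above 10 conventionally
#' indicate an instrument strong enough for ratio estimation.
#'
#' @param r_squared variance fraction explained by the instrument, in
#'   `[0, 1)`.
#' @param n sample size.
#' @return the F-statistic.
#' @examples
#' instrument_f(0.0397, 1411)  # 58.25
#' @export
instrument_f <- function(r_squared, n) {
  if (any(r_squared < 0 | r_squared >= 1)) {
    stop("r_squared must lie in [0, 1)")
  }
  (n - 2) * r_squared / (1 - r_squared)
}

#' Fit the instrument-exposure association
#'
#' Regresses serum 25(OH)D on the polygenic score with adjustment for age
#' and sex.  The reported `r_squared` is the incremental (partial) variance
#' fraction attributable to the score after the adjustment covariates, and
#' the F-statistic follows [instrument_f()].
#'
#' @param cohort cohort `data.frame`; a `pgs` column is computed from the
#'   genotype columns if absent.
#' @param covariates adjustment covariates (default age and sex).
#' @return an object of class `"instrument_fit"`: list with `beta_gx`,
#'   `se_gx`, `p_gx`, `r_squared`, `f_statistic`, `n`.
#' @export
fit_instrument <- function(cohort, covariates = c("age", "sex")) {
  cohort <- ensure_pgs(cohort)
  d <- cohort[c("vitd", "pgs", covariates)]
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n < 10L) stop("too few complete rows to fit the instrument (", n, ")")
  rhs_red <- if (length(covariates)) paste(covariates, collapse = " + ")
             else "1"
  fit_full <- lm(as.formula(paste("vitd ~ pgs +", rhs_red)), data = d)
  fit_red <- lm(as.formula(paste("vitd ~", rhs_red)), data = d)
  sm <- summary(fit_full)$coefficients
  rss_full <- sum(residuals(fit_full)^2)
  rss_red <- sum(residuals(fit_red)^2)
  r2 <- max(0, (rss_red - rss_full) / rss_red)
  structure(list(beta_gx = sm["pgs", "Estimate"],
                 se_gx = sm["pgs", "Std. Error"],
                 p_gx = sm["pgs", "Pr(>|t|)"],
                 r_squared = r2,
                 f_statistic = instrument_f(r2, n),
                 n = n),
            class = "instrument_fit")
}

#' @export
print.instrument_fit <- function(x, ...) {
  cat("Instrument-exposure association (25(OH)D ~ PGS, adjusted):\n")
  cat(sprintf("  beta = %.3f (SE %.3f), p = %.3g\n", x$beta_gx, x$se_gx,
              x$p_gx))
  cat(sprintf("  R^2 = %.4f, F = %.2f, n = %d\n", x$r_squared,
              x$f_statistic, x$n))
  invisible(x)
}

#' Pleiotropy check: polygenic score against candidate risk factors
#'
#' A valid instrument should be unrelated to confounders of the
#' exposure-outcome relation.  For each supplied covariate this tests the
#' association with the polygenic score: continuous covariates by the slope
#' in a linear model on the score, categorical covariates by a likelihood
#' ratio test of a (multinomial) logistic model on the score.
#'
#' @param cohort cohort `data.frame` (a `pgs` column is computed if absent).
#' @param covariates character vector of covariate names; may be empty.
#' @return a `data.frame` with `covariate`, `type` and `p`; the attribute
#'   `"p_range"` holds the min-max of the p-values (NULL when empty).
#' @export
check_pleiotropy <- function(cohort, covariates) {
  cohort <- ensure_pgs(cohort)
  if (length(covariates) == 0L) {
    out <- data.frame(covariate = character(), type = character(),
                      p = numeric(), stringsAsFactors = FALSE)
    attr(out, "p_range") <- NULL
    return(out)
  }
  missing_cols <- setdiff(covariates, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("covariates not found: ", paste(missing_cols, collapse = ", "))
  }
  rows <- lapply(covariates, function(v) {
    d <- cohort[c(v, "pgs")]
    d <- d[complete.cases(d), , drop = FALSE]
    x <- d[[v]]
    if (is.numeric(x)) {
      fit <- lm(x ~ pgs, data = d)
      p <- summary(fit)$coefficients["pgs", "Pr(>|t|)"]
      type <- "continuous"
    } else {
      y <- factor(x)
      if (nlevels(y) < 2L) {
        return(data.frame(covariate = v, type = "constant", p = NA_real_,
                          stringsAsFactors = FALSE))
      }
      if (nlevels(y) == 2L) {
        full <- glm(y ~ pgs, data = d, family = binomial())
        null <- glm(y ~ 1, data = d, family = binomial())
        p <- pchisq(null$deviance - full$deviance, df = 1, lower.tail = FALSE)
        type <- "binary"
      } else {
        full <- nnet::multinom(y ~ pgs, data = d, trace = FALSE)
        null <- nnet::multinom(y ~ 1, data = d, trace = FALSE)
        stat <- 2 * (logLik(full) - logLik(null))
        p <- pchisq(as.numeric(stat), df = nlevels(y) - 1L,
                    lower.tail = FALSE)
        type <- "categorical"
      }
    }
    data.frame(covariate = v, type = type, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "p_range") <- range(out$p, na.rm = TRUE)
  out
}
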