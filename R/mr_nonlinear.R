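# Non-linear Mendelian randomization by decile-stratified localized average
# causal effects (LACE) with fractional-polynomial meta-regression.

#' Instrument-free exposure
#'
#' Residuals of serum 25(OH)D after regressing on the polygenic score,
#' optionally (and by default) also on age and sex to match the MR
#' adjustment set.  Stratifying on these residuals rather than on the raw
#' exposure avoids inducing collider bias, because the residuals are
#' orthogonal to the instrument.
#'
#' @param cohort cohort `data.frame` (a `pgs` column is computed if absent).
#' @param covariates extra covariates in the residualizing regression;
#'   `character()` residualizes on the score alone.
#' @return numeric vector aligned with `cohort` rows (`NA` where inputs are
#'   missing); mean zero by construction.
#' @export
instrument_free_exposure <- function(cohort, covariates = c("age", "sex")) {
  cohort <- ensure_pgs(cohort)
  d <- cohort[c("vitd", "pgs", covariates)]
  cc <- complete.cases(d)
  rhs <- paste(c("pgs", covariates), collapse = " + ")
  fit <- lm(as.formula(paste("vitd ~", rhs)), data = d[cc, , drop = FALSE])
  out <- rep(NA_real_, nrow(cohort))
  out[cc] <- residuals(fit)
  out
}

#' Rank-based assignment into K near-equal strata
#'
#' Splits the sample into `K` quantile groups of the supplied values
#' (typically the instrument-free exposure).  Group sizes differ by at most
#' one; ties are broken by the stable original row order, so the assignment
#' is deterministic given the table.
#'
#' @param values numeric vector; `NA`s receive `NA` assignments.
#' @param K number of strata (default 10).
#' @return integer vector of stratum indices 1..K aligned with `values`.
#' @export
stratify_deciles <- function(values, K = 10L) {
  K <- as.integer(K)
  if (K < 2L) stop("K must be at least 2")
  idx <- which(!is.na(values))
  n <- length(idx)
  if (n < 10L * K) {
    stop("too few observations to form ", K, " strata: need at least ",
         10L * K, ", have ", n)
  }
  if (length(unique(values[idx])) == 1L) {
    stop("degenerate input: all values identical, quantiles undefined")
  }
  sizes <- rep(n %/% K, K) + c(rep(1L, n %% K), rep(0L, K - n %% K))
  ord <- idx[order(values[idx])]        # order() is stable: ties keep row order
  out <- rep(NA_integer_, length(values))
  out[ord] <- rep(seq_len(K), times = sizes)
  out
}

#' Localized average causal effects per stratum
#'
#' Within each stratum of the instrument-free exposure, fits the linear
#' instrument-exposure regression and the logistic instrument-outcome
#' regression (both adjusted for age and sex by default) and forms the
#' ratio estimate \eqn{LACE_j = \beta_{Y,j} / \beta_{X,j}} with the
#' first-order Taylor SE.  A stratum with a single outcome class, a
#' degenerate within-stratum instrument, or perfect separation is flagged
#' and excluded from downstream meta-regression.
#'
#' @param data an analysis set (from [build_outcomes()]) with `outcome`,
#'   `vitd` and `pgs` columns.
#' @param assignment integer stratum indices aligned with `data` rows (see
#'   [stratify_deciles()]).
#' @param covariates within-stratum adjustment covariates.
#' @param stratum_beta_x use the stratum-specific instrument-exposure
#'   coefficient in each ratio (default); `FALSE` uses the full-sample
#'   coefficient in every stratum.
#' @return a `data.frame` of class `"lace_set"`, one row per stratum:
#'   `stratum`, `n`, `n_cases`, `x_mean`, `beta_x`, `se_x`, `beta_y`,
#'   `se_y`, `lace`, `se_lace`, `usable`, `flag`.
#' @export
compute_laces <- function(data, assignment, covariates = c("age", "sex"),
                          stratum_beta_x = TRUE) {
  if (nrow(data) != length(assignment)) {
    stop("assignment length must match the analysis set")
  }
  K <- max(assignment, na.rm = TRUE)
  full_bx <- if (!stratum_beta_x) {
    inst <- fit_instrument(data, covariates = covariates)
    c(inst$beta_gx, inst$se_gx)
  } else NULL
  rhs <- paste(c("pgs", covariates), collapse = " + ")
  rows <- lapply(seq_len(K), function(j) {
    d <- data[!is.na(assignment) & assignment == j, , drop = FALSE]
    d <- d[complete.cases(d[c("outcome", "vitd", "pgs", covariates)]), ,
           drop = FALSE]
    base <- data.frame(stratum = j, n = nrow(d), n_cases = sum(d$outcome),
                       x_mean = mean(d$vitd), beta_x = NA_real_,
                       se_x = NA_real_, beta_y = NA_real_, se_y = NA_real_,
                       lace = NA_real_, se_lace = NA_real_, usable = FALSE,
                       flag = "", stringsAsFactors = FALSE)
    if (nrow(d) < length(covariates) + 3L) {
      base$flag <- "too few rows"
      return(base)
    }
    if (length(unique(d$outcome)) < 2L) {
      base$flag <- "single outcome class"
      return(base)
    }
    if (stratum_beta_x) {
      fs <- lm(as.formula(paste("vitd ~", rhs)), data = d)
      smx <- summary(fs)$coefficients
      if (!("pgs" %in% rownames(smx))) {
        base$flag <- "degenerate instrument"
        return(base)
      }
      bx <- smx["pgs", "Estimate"]; sx <- smx["pgs", "Std. Error"]
    } else {
      bx <- full_bx[1]; sx <- full_bx[2]
    }
    red <- tryCatch(suppressWarnings(
      glm(as.formula(paste("outcome ~", rhs)), data = d,
          family = binomial())), error = function(e) NULL)
    if (is.null(red) || !red$converged || !("pgs" %in% rownames(
      summary(red)$coefficients))) {
      base$flag <- "outcome model failed"
      return(base)
    }
    smy <- summary(red)$coefficients
    by <- smy["pgs", "Estimate"]; sy <- smy["pgs", "Std. Error"]
    if (abs(by) > 15 && any(red$fitted.values < 1e-10 |
                            red$fitted.values > 1 - 1e-10)) {
      base$flag <- "separation"
      return(base)
    }
    base$beta_x <- bx; base$se_x <- sx
    base$beta_y <- by; base$se_y <- sy
    if (!is.finite(bx) || abs(bx) < 1e-8) {
      base$flag <- "weak within-stratum instrument"
      return(base)
    }
    base$lace <- by / bx
    base$se_lace <- sy / abs(bx)
    base$usable <- TRUE
    base
  })
  out <- do.call(rbind, rows)
  class(out) <- c("lace_set", "data.frame")
  out
}

#' @export
print.lace_set <- function(x, ...) {
  cat("Localized average causal effects over", nrow(x), "strata (",
      sum(x$usable), "usable )\n")
  print.data.frame(format(as.data.frame(x), digits = 3), row.names = FALSE)
  invisible(x)
}

# Inverse-variance weighted least squares on a design without error in x;
# fixed-effect convention: coefficient covariance is (X'WX)^{-1}, not
# rescaled by the residual mean square.
wls_fit <- function(X, y, w) {
  XtW <- t(X * w)
  V <- solve(XtW %*% X)
  beta <- drop(V %*% (XtW %*% y))
  fitted <- drop(X %*% beta)
  rss <- sum(w * (y - fitted)^2)
  list(beta = beta, vcov = V, rss = rss, fitted = fitted)
}

#' Instrument-constancy diagnostics across strata
#'
#' Tests whether the instrument-exposure association is constant across the
#' strata of instrument-free exposure: Cochran's Q over the per-stratum
#' coefficients with inverse-variance weights (chi-square, K-1 df) and a
#' trend test from the inverse-variance weighted regression of the
#' per-stratum coefficient on the stratum mean exposure (Wald p on the
#' slope).
#'
#' @param strata a `"lace_set"` from [compute_laces()].
#' @return list with `Q`, `df`, `p_Q_instrument`, `trend_slope`,
#'   `trend_se`, `p_trend_instrument`, `k_used`.
#' @export
instrument_constancy <- function(strata) {
  s <- strata[strata$usable & is.finite(strata$beta_x) &
                strata$se_x > 0, , drop = FALSE]
  k <- nrow(s)
  if (k < 3L) stop("need at least 3 usable strata, have ", k)
  w <- 1 / s$se_x^2
  pooled <- sum(w * s$beta_x) / sum(w)
  Q <- sum(w * (s$beta_x - pooled)^2)
  tr <- wls_fit(cbind(1, s$x_mean), s$beta_x, w)
  slope <- tr$beta[2]
  se_slope <- sqrt(tr$vcov[2, 2])
  list(Q = Q, df = k - 1L,
       p_Q_instrument = pchisq(Q, k - 1L, lower.tail = FALSE),
       trend_slope = slope, trend_se = se_slope,
       p_trend_instrument = wald_p(slope, se_slope),
       k_used = k)
}

# Derivative of the FP effect function h(x) = sum_k beta_k x^{p_k} with
# respect to x, per basis column; p = 0 (log) differentiates to 1/x, a
# repeated power p contributes p x^{p-1} and x^{p-1} (p log x + 1).
fp_deriv_basis <- function(x, powers) {
  d1 <- function(p) if (p == 0) 1 / x else p * x^(p - 1)
  if (length(powers) == 1L) {
    m <- cbind(d1(powers))
  } else if (powers[1] == powers[2]) {
    p <- powers[1]
    m <- cbind(d1(p), x^(p - 1) * (p * log(x) + 1))
  } else {
    m <- cbind(d1(powers[1]), d1(powers[2]))
  }
  colnames(m) <- paste0("d", seq_len(ncol(m)))
  m
}

#' Fractional-polynomial meta-regression of LACEs
#'
#' Models the per-stratum localized average causal effects as the derivative
#' of a fractional-polynomial effect function \eqn{h(x)} evaluated at the
#' stratum mean exposure, fitted by inverse-variance weighted least squares
#' over the FP power grid (degrees 1 and 2).  A linear causal effect has a
#' constant derivative, so the linear reference model is the weighted mean
#' of the LACEs (the degree-1 candidate with power 1).
#'
#' Reports the three non-linearity tests:
#' \describe{
#'   \item{p_fp}{fractional polynomial test — chi-square difference between
#'     the weighted RSS of the best degree-1 FP and of the linear model,
#'     1 df (the searched power counts as the extra parameter).}
#'   \item{p_quadratic}{Wald p on the slope of the inverse-variance weighted
#'     regression of LACE on the stratum mean exposure (linear trend among
#'     LACEs).}
#'   \item{p_cochranQ}{Cochran's Q of the LACEs about their pooled
#'     (inverse-variance weighted) mean, chi-square with K-1 df.}
#' }
#' plus the instrument-constancy diagnostics of [instrument_constancy()].
#'
#' @param strata a `"lace_set"` from [compute_laces()].
#' @param powers FP power grid.
#' @param scale divisor applied to the stratum mean exposure before the
#'   power transforms (absorbed by the coefficients).
#' @return an object of class `"nlmr_result"`: the usable strata, pooled
#'   LACE and its SE, best degree-1 and degree-2 powers, the three test
#'   p-values, instrument-constancy p-values and the count of excluded
#'   strata.
#' @export
fp_meta_regression <- function(strata, powers = fp_powers_default,
                               scale = 10) {
  s <- strata[strata$usable & is.finite(strata$lace) &
                strata$se_lace > 0, , drop = FALSE]
  k <- nrow(s)
  if (k < 4L) stop("need at least 4 usable strata, have ", k)
  y <- s$lace
  w <- 1 / s$se_lace^2
  x <- s$x_mean / scale
  if (any(x <= 0)) stop("stratum mean exposures must be positive")

  # linear (constant-derivative) reference: weighted mean of the LACEs
  lin <- wls_fit(matrix(1, k, 1), y, w)
  pooled <- lin$beta[1]
  pooled_se <- sqrt(lin$vcov[1, 1])
  rss_lin <- lin$rss

  fit_power <- function(pw) {
    X <- fp_deriv_basis(x, pw)
    tryCatch(wls_fit(X, y, w)$rss, error = function(e) NA_real_)
  }
  rss_d1 <- vapply(powers, fit_power, numeric(1))
  pairs <- fp_pairs(powers)
  rss_d2 <- vapply(seq_len(nrow(pairs)),
                   function(i) fit_power(pairs[i, ]), numeric(1))
  best1 <- which.min(rss_d1)
  best2 <- which.min(rss_d2)

  p_fp <- pchisq(rss_lin - rss_d1[best1], df = 1, lower.tail = FALSE)
  quad <- wls_fit(cbind(1, s$x_mean), y, w)
  p_quadratic <- wald_p(quad$beta[2], sqrt(quad$vcov[2, 2]))
  p_cochranQ <- pchisq(rss_lin, df = k - 1L, lower.tail = FALSE)
  constancy <- instrument_constancy(strata)

  structure(list(strata = strata,
                 k_total = nrow(strata), k_used = k,
                 k_excluded = nrow(strata) - k,
                 pooled_lace = pooled, pooled_se = pooled_se,
                 best_fp1_power = powers[best1],
                 best_fp2_powers = pairs[best2, ],
                 p_fp = p_fp, p_quadratic = p_quadratic,
                 p_cochranQ = p_cochranQ,
                 cochran_Q = rss_lin,
                 p_Q_instrument = constancy$p_Q_instrument,
                 p_trend_instrument = constancy$p_trend_instrument),
            class = "nlmr_result")
}

#' @export
print.nlmr_result <- function(x, ...) {
  cat("Non-linear MR over", x$k_used, "of", x$k_total, "strata\n")
  cat(sprintf("  pooled LACE = %.4f (SE %.4f) log-odds per ng/mL\n",
              x$pooled_lace, x$pooled_se))
  cat(sprintf("  P_fp = %.3f, P_quadratic = %.3f, P_CochranQ = %.3f\n",
              x$p_fp, x$p_quadratic, x$p_cochranQ))
  cat(sprintf("  instrument constancy: P_Q = %.3f, P_trend = %.3f\n",
              x$p_Q_instrument, x$p_trend_instrument))
  invisible(x)
}

#' End-to-end non-linear MR for one outcome
#'
#' Convenience wrapper: builds the analysis set, residualizes the exposure,
#' stratifies into `K` quantile groups and runs [compute_laces()] plus
#' [fp_meta_regression()].
#'
#' @inheritParams ratio_mr
#' @param K number of strata of instrument-free exposure.
#' @param residual_covariates covariates in the residualizing regression.
#' @return an `"nlmr_result"`; `NULL` components on failure propagate as
#'   errors.
#' @export
nonlinear_mr <- function(cohort, trait = c("si", "sp", "sa"),
                         horizon = c("baseline", "incident_1y",
                                     "incident_2y"),
                         K = 10L, covariates = c("age", "sex"),
                         residual_covariates = covariates) {
  cohort <- ensure_pgs(cohort)
  aset <- build_outcomes(cohort, trait, horizon)
  cc <- complete.cases(aset[c("outcome", "vitd", "pgs", covariates)])
  aset <- aset[cc, , drop = FALSE]
  res <- instrument_free_exposure(aset, covariates = residual_covariates)
  assignment <- stratify_deciles(res, K = K)
  strata <- compute_laces(aset, assignment, covariates = covariates)
  out <- fp_meta_regression(strata)
  out$trait <- match.arg(trait)
  out$horizon <- match.arg(horizon)
  out
}
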