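# Linear Mendelian randomization by the ratio-of-coefficients method.

#' Ratio (Wald) estimate from first-stage and reduced-form coefficients
#'
#' The instrumental-variable estimate is the ratio of the instrument-outcome
#' coefficient to the instrument-exposure coefficient,
#' \eqn{\hat\beta_{IV} = \hat\beta_{GY} / \hat\beta_{GX}}.  Its standard
#' error uses the first-order Taylor approximation
#' \eqn{SE(\hat\beta_{GY}) / |\hat\beta_{GX}|}; the optional second-order
#' term adds the uncertainty of the denominator,
#' \eqn{\sqrt{SE_{GY}^2/\beta_{GX}^2 +
#' \beta_{GY}^2 SE_{GX}^2/\beta_{GX}^4}}.
#'
#' @param beta_gy,se_gy instrument-outcome (reduced-form) log-odds
#'   coefficient and SE.
#' @param beta_gx,se_gx instrument-exposure coefficient and SE.
#' @param second_order include the denominator variance term (default
#'   FALSE).
#' @param tol smallest admissible `|beta_gx|`.
#' @return list with `beta_iv`, `se_iv`, `or_iv`, `ci95`, `p`.
#' @examples
#' ratio_estimate(0.1, 0.05, 0.2, 0.02)  # beta_iv 0.5, se_iv 0.25
#' @export
ratio_estimate <- function(beta_gy, se_gy, beta_gx, se_gx = NA_real_,
                           second_order = FALSE, tol = 1e-10) {
  if (!is.finite(beta_gx) || abs(beta_gx) < tol) {
    stop("weak/degenerate instrument: |beta_gx| below tolerance, ",
         "refusing the ratio")
  }
  beta_iv <- beta_gy / beta_gx
  se_iv <- if (second_order) {
    sqrt(se_gy^2 / beta_gx^2 + beta_gy^2 * se_gx^2 / beta_gx^4)
  } else {
    se_gy / abs(beta_gx)
  }
  list(beta_iv = beta_iv, se_iv = se_iv, or_iv = exp(beta_iv),
       ci95 = or_ci(beta_iv, se_iv), p = wald_p(beta_iv, se_iv))
}

#' Linear MR of 25(OH)D on a suicidality outcome
#'
#' Individual-level ratio-of-coefficients Mendelian randomization: a linear
#' first-stage regression of serum 25(OH)D on the polygenic score and a
#' logistic reduced-form regression of the outcome on the score, both
#' adjusted for age and sex (the MR adjustment set), combined as
#' [ratio_estimate()].  The causal odds ratio is per 1 ng/mL of genetically
#' determined 25(OH)D.
#'
#' By default the fit refuses to divide when the instrument F-statistic is
#' below `f_threshold` (10, the conventional adequacy bound); set
#' `force = TRUE` to override.
#'
#' @param cohort cohort `data.frame` (a `pgs` column is computed if absent).
#' @param trait,horizon outcome specification passed to [build_outcomes()].
#' @param covariates MR adjustment covariates (default age and sex).
#' @param f_threshold minimum instrument F-statistic.
#' @param force fit even with a weak instrument.
#' @param second_order use the second-order Taylor SE.
#' @return an object of class `"ratio_mr"`: `beta_gx`, `se_gx`, `beta_gy`,
#'   `se_gy`, `beta_iv`, `se_iv`, `or_iv`, `ci95`, `p_linear`,
#'   `f_statistic`, `n`, `n_cases`, `trait`, `horizon`.
#' @export
ratio_mr <- function(cohort, trait = c("si", "sp", "sa"),
                     horizon = c("baseline", "incident_1y", "incident_2y"),
                     covariates = c("age", "sex"), f_threshold = 10,
                     force = FALSE, second_order = FALSE) {
  cohort <- ensure_pgs(cohort)
  aset <- build_outcomes(cohort, trait, horizon)
  d <- aset[c("outcome", "vitd", "pgs", covariates)]
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < 10L) stop("too few complete rows for MR (", nrow(d), ")")
  if (length(unique(d$outcome)) < 2L) {
    stop("outcome has one class; MR odds ratio undefined")
  }
  inst <- fit_instrument(d, covariates = covariates)
  if (!force && inst$f_statistic < f_threshold) {
    stop(sprintf(paste0("instrument F = %.2f below the strength threshold ",
                        "%.1f; use force = TRUE to override"),
                 inst$f_statistic, f_threshold))
  }
  rhs <- paste(c("pgs", covariates), collapse = " + ")
  red <- suppressWarnings(glm(as.formula(paste("outcome ~", rhs)),
                              data = d, family = binomial()))
  sm <- summary(red)$coefficients
  beta_gy <- sm["pgs", "Estimate"]
  se_gy <- sm["pgs", "Std. Error"]
  est <- ratio_estimate(beta_gy, se_gy, inst$beta_gx, inst$se_gx,
                        second_order = second_order)
  structure(c(list(beta_gx = inst$beta_gx, se_gx = inst$se_gx,
                   beta_gy = beta_gy, se_gy = se_gy),
              setNames(est[c("beta_iv", "se_iv", "or_iv", "ci95", "p")],
                       c("beta_iv", "se_iv", "or_iv", "ci95", "p_linear")),
              list(f_statistic = inst$f_statistic,
                   r_squared = inst$r_squared,
                   n = nrow(d), n_cases = sum(d$outcome),
                   trait = match.arg(trait), horizon = match.arg(horizon))),
            class = "ratio_mr")
}

#' @export
print.ratio_mr <- function(x, ...) {
  cat(sprintf("Linear MR (ratio of coefficients): %s, %s\n", toupper(x$trait),
              x$horizon))
  cat(sprintf("  n = %d (%d cases); instrument F = %.2f\n", x$n, x$n_cases,
              x$f_statistic))
  cat(sprintf("  OR per ng/mL = %.3f (95%% CI %.3f-%.3f), P_linear = %.3f\n",
              x$or_iv, x$ci95[1], x$ci95[2], x$p_linear))
  invisible(x)
}

#' Power of a binary-outcome Mendelian randomization study
#'
#' Closed-form normal-approximation power for the instrumental-variable test
#' of a binary outcome.  The reduced-form Wald statistic for a causal odds
#' ratio `true_or` per SD of the exposure is approximately
#' \eqn{z = |\log OR| \sqrt{n R^2_{GX} K (1 - K)}}, with `K` the case
#' fraction and \eqn{R^2_{GX}} the exposure variance explained by the
#' instrument, giving
#' \eqn{power = \Phi(z - z_{1-\alpha/2}) + \Phi(-z - z_{1-\alpha/2})}.
#'
#' @param n sample size.
#' @param r_squared_gx instrument-exposure variance fraction, in (0, 1).
#' @param case_fraction outcome prevalence in the sample, in (0, 1).
#' @param true_or causal odds ratio per 1 SD of the exposure.
#' @param alpha two-sided significance level.
#' @return an object of class `"mr_power"`: the inputs plus `power`.
#' @examples
#' mr_power_binary(1411, 0.0397, 0.241, true_or = 1.5)
#' @export
mr_power_binary <- function(n, r_squared_gx, case_fraction, true_or,
                            alpha = 0.05) {
  if (r_squared_gx <= 0 || r_squared_gx >= 1) {
    stop("r_squared_gx must lie in (0, 1)")
  }
  if (case_fraction <= 0 || case_fraction >= 1) {
    stop("case_fraction must lie in (0, 1)")
  }
  if (true_or <= 0) stop("true_or must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  z <- abs(log(true_or)) *
    sqrt(n * r_squared_gx * case_fraction * (1 - case_fraction))
  q <- qnorm(1 - alpha / 2)
  structure(list(n = n, r_squared_gx = r_squared_gx,
                 case_fraction = case_fraction, true_or = true_or,
                 alpha = alpha,
                 power = pnorm(z - q) + pnorm(-z - q)),
            class = "mr_power")
}

#' @export
print.mr_power <- function(x, ...) {
  cat(sprintf(paste0("MR power (binary outcome): n = %d, R^2 = %.3f, ",
                     "K = %.3f, OR = %.2f/SD -> power = %.3f at alpha = %.2f\n"),
              x$n, x$r_squared_gx, x$case_fraction, x$true_or, x$power,
              x$alpha))
  invisible(x)
}

#' Run any pipeline stage separately by sex
#'
#' Applies `fun` to the male-only and female-only subsets of the cohort.
#' When a `covariates` argument is supplied it is forwarded with `"sex"`
#' removed, since sex is constant within a stratum.  A stratum that is empty
#' or in which `fun` fails yields the condition object rather than aborting
#' the other stratum.
#'
#' @param cohort cohort `data.frame` with a `sex` column.
#' @param fun a function whose first argument accepts a cohort subset.
#' @param ... further arguments to `fun`.
#' @param covariates optional covariate names; `"sex"` is stripped before
#'   forwarding.
#' @return an object of class `"sex_stratified"`: list with elements `male`
#'   and `female`, each either the stage result or a condition/`NULL`
#'   marking the stratum unavailable.
#' @export
sex_stratified <- function(cohort, fun, ..., covariates = NULL) {
  if (!("sex" %in% names(cohort))) stop("cohort has no sex column")
  run_stratum <- function(level) {
    sub <- cohort[!is.na(cohort$sex) & cohort$sex == level, , drop = FALSE]
    if (nrow(sub) == 0L) {
      return(structure(list(message = "empty stratum"),
                       class = c("stratum_unavailable", "condition")))
    }
    args <- list(sub, ...)
    if (!is.null(covariates)) args$covariates <- setdiff(covariates, "sex")
    tryCatch(do.call(fun, args),
             error = function(e) structure(
               list(message = conditionMessage(e)),
               class = c("stratum_unavailable", "condition")))
  }
  structure(list(male = run_stratum("male"), female = run_stratum("female")),
            class = "sex_stratified")
}

#' Test whether a stratum result is unavailable
#' @param x an element of a [sex_stratified()] result.
#' @return logical.
#' @export
is_unavailable <- function(x) inherits(x, "stratum_unavailable")

#' @export
print.sex_stratified <- function(x, ...) {
  for (s in c("male", "female")) {
    cat("==", s, "==\n")
    if (is_unavailable(x[[s]])) {
      cat("  unavailable:", x[[s]]$message, "\n")
    } else {
      print(x[[s]])
    }
  }
  invisible(x)
}
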