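#' Build an analysis set for one outcome specification
#'
#' Constructs the binary outcome for one trait (SI, SP or SA) at one horizon:
#' \describe{
#'   \item{baseline}{outcome is the wave-1 report; all rows with a
#'     non-missing wave-1 value are eligible.}
#'   \item{incident_1y}{restricted to participants negative for that trait
#'     at wave 1; outcome is the wave-2 report.}
#'   \item{incident_2y}{restricted to participants negative at wave 1;
#'     outcome is positive if the trait is reported at wave 2 and/or wave 3,
#'     negative only when both waves are negative.}
#' }
#' The restriction is per-trait: a participant positive for SP at baseline
#' still enters the incident-SI set if SI-negative at wave 1.  Rows whose
#' required waves are missing (for incident_2y: neither wave positive and at
#' least one missing) are dropped and counted.
#'
#' @param cohort cohort `data.frame`.
#' @param trait one of `"si"`, `"sp"`, `"sa"`.
#' @param horizon one of `"baseline"`, `"incident_1y"`, `"incident_2y"`.
#' @return the eligible subset of `cohort` with an added integer column
#'   `outcome` (1 = case); attributes `"n_dropped_missing"`,
#'   `"trait"`, `"horizon"`.
#' @examples
#' d <- data.frame(si_w1 = c("no", "no", "yes"), si_w2 = c("yes", "no", "no"),
#'                 si_w3 = c("no", "yes", "no"))
#' build_outcomes(d, "si", "incident_2y")$outcome  # 1, 1
#' @export
build_outcomes <- function(cohort, trait = c("si", "sp", "sa"),
                           horizon = c("baseline", "incident_1y",
                                       "incident_2y")) {
  trait <- match.arg(trait)
  horizon <- match.arg(horizon)
  w1 <- yesno_to_binary(cohort[[paste0(trait, "_w1")]])
  if (horizon == "baseline") {
    keep <- !is.na(w1)
    out <- w1[keep]
  } else {
    w2 <- yesno_to_binary(cohort[[paste0(trait, "_w2")]])
    eligible <- !is.na(w1) & w1 == 0L
    if (horizon == "incident_1y") {
      keep <- eligible & !is.na(w2)
      out <- w2[keep]
    } else {
      w3 <- yesno_to_binary(cohort[[paste0(trait, "_w3")]])
      any_yes <- (!is.na(w2) & w2 == 1L) | (!is.na(w3) & w3 == 1L)
      both_no <- !is.na(w2) & w2 == 0L & !is.na(w3) & w3 == 0L
      keep <- eligible & (any_yes | both_no)
      out <- as.integer(any_yes[keep])
    }
  }
  n_eligible <- if (horizon == "baseline") sum(!is.na(w1)) else {
    sum(!is.na(w1) & w1 == 0L)
  }
  res <- cohort[keep, , drop = FALSE]
  res$outcome <- out
  attr(res, "n_dropped_missing") <- n_eligible - nrow(res)
  attr(res, "trait") <- trait
  attr(res, "horizon") <- horizon
  res
}

#' Categorize serum 25(OH)D
#'
#' Clinical categories: deficiency below 20 ng/mL, insufficiency from 20 up
#' to (not including) 30 ng/mL, sufficiency at or above 30 ng/mL.  The
#' boundaries 20 and 30 belong to the higher category.
#'
#' @param vitd numeric vector of serum 25(OH)D in ng/mL (positive; `NA`
#'   passes through).
#' @return a factor with ordered levels `deficiency`, `insufficiency`,
#'   `sufficiency`.
#' @examples
#' categorize_vitd(c(19.99, 20, 29.99, 30))
#' @export
categorize_vitd <- function(vitd) {
  if (any(!is.na(vitd) & vitd <= 0)) {
    stop("vitd must be positive (ng/mL)")
  }
  cut(vitd, breaks = c(0, 20, 30, Inf), right = FALSE,
      labels = c("deficiency", "insufficiency", "sufficiency"))
}

# Shared logistic fit + OR table; errors on one-class outcomes and flags
# perfect separation instead of silently diverging.
fit_logistic_or <- function(data, rhs_terms, covariates, exposure_terms) {
  vars <- unique(c("outcome", all.vars(as.formula(
    paste("~", paste(c(rhs_terms, covariates), collapse = " + "))))))
  d <- data[intersect(vars, names(data))]
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) == 0L) stop("no complete rows for this model")
  if (length(unique(d$outcome)) < 2L) {
    stop("outcome has one class; odds ratios are undefined")
  }
  f <- as.formula(paste("outcome ~",
                        paste(c(rhs_terms, covariates), collapse = " + ")))
  fit <- suppressWarnings(glm(f, data = d, family = binomial()))
  mu <- fit$fitted.values
  if (!fit$converged ||
      (any(mu < 1e-10 | mu > 1 - 1e-10) &&
       any(abs(coef(fit)[exposure_terms]) > 15, na.rm = TRUE))) {
    stop("perfect separation detected; odds ratios are not estimable")
  }
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)
  tab <- data.frame(term = terms,
                    estimate = sm[, "Estimate"],
                    se = sm[, "Std. Error"],
                    or = exp(sm[, "Estimate"]),
                    ci_lower = exp(sm[, "Estimate"] - 1.96 * sm[, "Std. Error"]),
                    ci_upper = exp(sm[, "Estimate"] + 1.96 * sm[, "Std. Error"]),
                    p = sm[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, loglik = as.numeric(logLik(fit)),
                 n = nrow(d), n_cases = sum(d$outcome), glm = fit),
            class = "or_fit")
}

#' @export
print.or_fit <- function(x, ...) {
  cat("Logistic model:", x$n, "rows,", x$n_cases, "cases\n")
  tab <- x$table
  tab$or <- sprintf("%.3f", tab$or)
  tab$ci <- sprintf("(%.3f, %.3f)", tab$ci_lower, tab$ci_upper)
  print(tab[c("term", "or", "ci", "p")], row.names = FALSE)
  invisible(x)
}

#' Adjusted logistic model with continuous 25(OH)D
#'
#' Maximum-likelihood logistic regression of the binary outcome on the
#' continuous serum 25(OH)D concentration plus covariates; the exposure
#' coefficient is reported as an odds ratio per 1 ng/mL with a 95% CI and a
#' two-sided Wald p-value.
#'
#' @param data an analysis set from [build_outcomes()] (needs `outcome` and
#'   the exposure column).
#' @param covariates adjustment covariate names.
#' @param exposure exposure column name (default `"vitd"`).
#' @return an object of class `"or_fit"`; the exposure row of `$table`
#'   carries the headline OR.
#' @export
fit_continuous <- function(data, covariates = character(),
                           exposure = "vitd") {
  fit_logistic_or(data, exposure, covariates, exposure)
}

#' Adjusted logistic model with categorical 25(OH)D
#'
#' Dummy-coded logistic regression over the clinical 25(OH)D categories with
#' the deficiency group as reference.  An empty category yields an undefined
#' (NA) contrast while the remaining contrasts are still fitted.
#'
#' @inheritParams fit_continuous
#' @return an object of class `"or_fit"` whose `$table` contains one row per
#'   non-reference category (plus covariates); `$categories` records the
#'   per-category counts, with `NA` odds ratios for empty categories.
#' @export
fit_categorical <- function(data, covariates = character(),
                            exposure = "vitd") {
  data$vitd_cat <- categorize_vitd(data[[exposure]])
  counts <- table(data$vitd_cat)
  present <- names(counts)[counts > 0]
  if (length(present) < 2L) stop("need at least two 25(OH)D categories")
  data$vitd_cat <- droplevels(data$vitd_cat)
  res <- fit_logistic_or(data, "vitd_cat", covariates,
                         paste0("vitd_cat", levels(data$vitd_cat)[-1]))
  res$categories <- as.data.frame(counts, stringsAsFactors = FALSE)
  names(res$categories) <- c("category", "n")
  res$reference <- levels(data$vitd_cat)[1]
  res$undefined <- setdiff(c("deficiency", "insufficiency", "sufficiency"),
                           present)
  res
}
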