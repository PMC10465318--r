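#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm glm glm.fit binomial coef vcov residuals qnorm pnorm
#'   pchisq qchisq plogis qlogis rbinom rnorm uniroot complete.cases
#'   logLik anova as.formula model.matrix sd var setNames binom.test
#' @importFrom utils read.csv write.csv write.table
NULL

# Evaluate `expr` with the RNG seeded at `seed + offset`, restoring the
# caller's RNG state afterwards.  Each generated column draws from its own
# substream so adding a column never perturbs the ones before it.
with_substream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) %% 1000003L) * 1000L + as.integer(offset))
  expr
}

# Two-sided normal-reference p-value for an estimate and its SE.
wald_p <- function(est, se) {
  ifelse(se > 0, 2 * pnorm(-abs(est / se)), NA_real_)
}

# exp-scale 95% CI with the conventional 1.96 multiplier.
or_ci <- function(beta, se, z = 1.96) {
  c(lower = exp(beta - z * se), upper = exp(beta + z * se))
}

# Recode "yes"/"no" (character or factor) to 1/0, keeping NA.
yesno_to_binary <- function(x) {
  x <- as.character(x)
  out <- rep(NA_integer_, length(x))
  out[x == "yes"] <- 1L
  out[x == "no"] <- 0L
  bad <- !is.na(x) & !(x %in% c("yes", "no"))
  if (any(bad)) {
    stop("outcome values must be 'yes', 'no' or missing; offending rows: ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  out
}

# Build a numeric model matrix (without intercept column) for a covariate
# list, expanding factors to dummies; returns NULL for an empty list.
covariate_matrix <- function(data, covariates) {
  if (length(covariates) == 0L) return(NULL)
  missing_cols <- setdiff(covariates, names(data))
  if (length(missing_cols) > 0L) {
    stop("covariates not found in data: ", paste(missing_cols, collapse = ", "))
  }
  f <- as.formula(paste("~", paste(covariates, collapse = " + ")))
  mm <- model.matrix(f, data = data)
  mm[, -1, drop = FALSE]
}

# Logistic fit via glm.fit on a pre-built design; returns deviance and
# convergence flag.  Used by the fractional-polynomial scans where many
# candidate designs share the same response.
logistic_deviance <- function(X, y) {
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  list(deviance = fit$deviance,
       converged = fit$converged,
       coef = fit$coefficients,
       rank = fit$rank)
}

fmt_or <- function(or, ci) {
  sprintf("%.2f (%.2f-%.2f)", or, ci[1], ci[2])
}
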