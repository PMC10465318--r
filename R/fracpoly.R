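# Fractional-polynomial machinery shared by the observational dose-response
# test and the LACE meta-regression.

#' @export
fp_powers_default <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

# One FP transform column: x^p, with p = 0 meaning log(x).
fp_term <- function(x, p) {
  if (p == 0) log(x) else x^p
}

# Basis for a degree-1 or degree-2 FP.  A repeated power p contributes
# x^p and x^p * log(x) (the Royston-Altman convention).
fp_basis <- function(x, powers) {
  if (length(powers) == 1L) {
    m <- cbind(fp_term(x, powers))
  } else if (powers[1] == powers[2]) {
    m <- cbind(fp_term(x, powers[1]), fp_term(x, powers[1]) * log(x))
  } else {
    m <- cbind(fp_term(x, powers[1]), fp_term(x, powers[2]))
  }
  colnames(m) <- paste0("fp", seq_len(ncol(m)))
  m
}

# All degree-2 power pairs (p1 <= p2) over the grid, repeats included.
fp_pairs <- function(powers = fp_powers_default) {
  idx <- which(upper.tri(matrix(0, length(powers), length(powers)),
                         diag = TRUE), arr.ind = TRUE)
  cbind(powers[idx[, "row"]], powers[idx[, "col"]])
}

#' Fractional-polynomial non-linearity test for a binary outcome
#'
#' Searches the Royston-Altman fractional-polynomial family of degrees 1 and
#' 2 over the power grid \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\} (0 denoting log,
#' a repeated power p contributing \eqn{x^p} and \eqn{x^p \log x}) for the
#' best-fitting logistic dose-response in the exposure, then reports two
#' likelihood-ratio tests:
#' \describe{
#'   \item{p_overall}{best degree-2 model against the covariates-only null
#'     (4 df): is there any exposure effect?}
#'   \item{p_nonlinear}{best degree-2 model against the linear-exposure
#'     model (3 df): is the effect non-linear?}
#' }
#' The exposure is divided by `scale` (default 10) before the power
#' transforms to keep the cubic terms numerically tame; this rescaling is
#' absorbed by the coefficients and changes no p-value.  Exposures must be
#' strictly positive; otherwise a shift to positivity is applied and
#' recorded.
#'
#' @param data analysis set with an `outcome` column (see
#'   [build_outcomes()]).
#' @param covariates adjustment covariate names.
#' @param exposure exposure column name.
#' @param powers the FP power grid.
#' @param scale divisor applied to the exposure before transforming.
#' @return an object of class `"fp_test"`: best powers for degrees 1 and 2,
#'   the log-likelihoods of the null, linear and best models, `p_overall`,
#'   `p_nonlinear`, the number of skipped (non-converged) candidates and
#'   `n`.
#' @export
fp_nonlinearity_test <- function(data, covariates = character(),
                                 exposure = "vitd",
                                 powers = fp_powers_default,
                                 scale = 10) {
  keep_cols <- unique(c("outcome", exposure, covariates))
  d <- data[intersect(keep_cols, names(data))]
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) == 0L) stop("no complete rows")
  y <- d$outcome
  if (length(unique(y)) < 2L) stop("outcome has one class")
  x <- d[[exposure]] / scale
  shift <- 0
  if (any(x <= 0)) {
    shift <- -min(x) + min(x[x > 0], 1)  # shift to strict positivity
    x <- x + shift
  }
  Z <- covariate_matrix(d, covariates)
  ones <- rep(1, length(y))
  base_design <- if (is.null(Z)) cbind(`(Intercept)` = ones) else {
    cbind(`(Intercept)` = ones, Z)
  }

  skipped <- 0L
  dev_of <- function(B) {
    fit <- tryCatch(logistic_deviance(cbind(base_design, B), y),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      skipped <<- skipped + 1L
      return(NA_real_)
    }
    fit$deviance
  }

  dev_null <- logistic_deviance(base_design, y)$deviance
  dev_d1 <- vapply(powers, function(p) dev_of(fp_basis(x, p)), numeric(1))
  pairs <- fp_pairs(powers)
  dev_d2 <- vapply(seq_len(nrow(pairs)),
                   function(i) dev_of(fp_basis(x, pairs[i, ])), numeric(1))

  dev_linear <- dev_d1[powers == 1]
  best1 <- which.min(dev_d1)
  best2 <- which.min(dev_d2)
  dev_best1 <- dev_d1[best1]
  dev_best2 <- dev_d2[best2]

  structure(list(best_powers_d1 = powers[best1],
                 best_powers_d2 = pairs[best2, ],
                 loglik_null = -dev_null / 2,
                 loglik_linear = -dev_linear / 2,
                 loglik_best_d1 = -dev_best1 / 2,
                 loglik_best_d2 = -dev_best2 / 2,
                 p_overall = pchisq(dev_null - dev_best2, df = 4,
                                    lower.tail = FALSE),
                 p_nonlinear = pchisq(dev_linear - dev_best2, df = 3,
                                      lower.tail = FALSE),
                 skipped = skipped, shift = shift, scale = scale,
                 n = length(y)),
            class = "fp_test")
}

#' @export
print.fp_test <- function(x, ...) {
  cat("Fractional-polynomial dose-response test (n =", x$n, ")\n")
  cat("  best degree-1 power:", x$best_powers_d1,
      "; best degree-2 powers:", paste(x$best_powers_d2, collapse = ", "),
      "\n")
  cat(sprintf("  P_overall = %.4g (4 df), P_non-linear = %.4g (3 df)\n",
              x$p_overall, x$p_nonlinear))
  if (x$skipped > 0) cat("  candidates skipped (non-convergence):",
                         x$skipped, "\n")
  invisible(x)
}
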