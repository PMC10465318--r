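# Config-driven orchestration of the full analysis: genetics ->
# observational -> linear MR -> non-linear MR, per outcome and optionally
# per sex, with TSV reports and a JSON run manifest.

OBS_COVARIATES <- c("sex", "age", "household_registration", "family_economy",
                    "paternal_education", "maternal_education",
                    "moderate_pa", "vigorous_pa", "impulsivity",
                    "depression", "anxiety")
MR_COVARIATES <- c("age", "sex")
SNP_COLUMNS <- c("g_rs10741657", "g_rs4588", "g_rs7041")
OUTCOME_COLUMNS <- paste0(rep(c("si", "sp", "sa"), each = 3), "_w", 1:3)

#' Analysis configuration
#'
#' Collects the knobs of [run_all()]: which outcomes to analyse, the
#' observational and MR covariate sets, the number of strata for non-linear
#' MR, the significance level, and flags for the sex-stratified and power
#' sub-analyses.
#'
#' @param traits,horizons the outcome grid (crossed).
#' @param obs_covariates covariates for the observational logistic and FP
#'   models.
#' @param mr_covariates covariates for all MR stages.
#' @param K strata for non-linear MR.
#' @param alpha two-sided significance level.
#' @param stratify_sex also run every stage on male-only and female-only
#'   subsets.
#' @param power run the MR power calculation.
#' @param power_or assumed causal odds ratio per exposure SD for the power
#'   calculation.
#' @param seed integer recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return a list of class `"analysis_config"`.
#' @export
analysis_config <- function(traits = c("si", "sp", "sa"),
                            horizons = c("baseline", "incident_1y",
                                         "incident_2y"),
                            obs_covariates = OBS_COVARIATES,
                            mr_covariates = MR_COVARIATES,
                            K = 10L, alpha = 0.05,
                            stratify_sex = FALSE, power = TRUE,
                            power_or = 1.5, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(traits = traits, horizons = horizons,
                 obs_covariates = obs_covariates,
                 mr_covariates = mr_covariates, K = as.integer(K),
                 alpha = alpha, stratify_sex = isTRUE(stratify_sex),
                 power = isTRUE(power), power_or = power_or,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take the [analysis_config()]
#' defaults.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return an `"analysis_config"`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(analysis_config, raw)
}

#' Validate a cohort table against the expected schema
#'
#' Checks column presence, genotype domain (allele counts 0/1/2), outcome
#' coding (`yes`/`no`/missing), and exposure positivity.  Issues are
#' returned, not raised, so a caller can report all problems at once.
#'
#' @param x a cohort `data.frame` or a path to a cohort CSV.
#' @return a `data.frame` with columns `row` (NA for table-level issues),
#'   `column` and `problem`; zero rows means the table is valid.
#' @export
validate_schema <- function(x) {
  cohort <- if (is.character(x)) read_cohort_csv(x) else x
  issues <- list()
  add <- function(row, column, problem) {
    issues[[length(issues) + 1L]] <<- data.frame(
      row = row, column = column, problem = problem,
      stringsAsFactors = FALSE)
  }
  required <- c("participant_id", "sex", "age", SNP_COLUMNS, "vitd",
                OUTCOME_COLUMNS)
  absent <- setdiff(required, names(cohort))
  for (col in absent) add(NA_integer_, col, "required column missing")
  for (col in intersect(SNP_COLUMNS, names(cohort))) {
    g <- cohort[[col]]
    bad <- which(!is.na(g) & !(g %in% c(0, 1, 2)))
    for (r in bad) add(r, col, paste0("genotype value ", g[r],
                                      " outside {0,1,2}"))
  }
  if ("vitd" %in% names(cohort)) {
    v <- cohort$vitd
    bad <- which(!is.na(v) & (!is.finite(v) | v <= 0))
    for (r in bad) add(r, "vitd", "non-positive 25(OH)D")
  }
  if ("sex" %in% names(cohort)) {
    s <- cohort$sex
    bad <- which(!is.na(s) & !(s %in% c("male", "female")))
    for (r in bad) add(r, "sex", paste0("sex value '", s[r],
                                        "' not male/female"))
  }
  for (col in intersect(OUTCOME_COLUMNS, names(cohort))) {
    o <- as.character(cohort[[col]])
    bad <- which(!is.na(o) & !(o %in% c("yes", "no")))
    for (r in bad) add(r, col, paste0("outcome value '", o[r],
                                      "' not yes/no/missing"))
  }
  if (length(issues) == 0L) {
    return(data.frame(row = integer(), column = character(),
                      problem = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}

format_ci <- function(ci) sprintf("%.2f-%.2f", ci[1], ci[2])

safe_stage <- function(expr) {
  tryCatch(expr, error = function(e) structure(
    list(message = conditionMessage(e)), class = "stage_error"))
}

stage_failed <- function(x) inherits(x, "stage_error")

# One observational + MR sweep over the outcome grid for one (sub)sample.
analyse_sample <- function(cohort, config, sample_label, log_line) {
  obs_cov <- config$obs_covariates
  mr_cov <- config$mr_covariates
  if (sample_label != "total") {
    obs_cov <- setdiff(obs_cov, "sex")
    mr_cov <- setdiff(mr_cov, "sex")
  }
  grid <- expand.grid(trait = config$traits, horizon = config$horizons,
                      stringsAsFactors = FALSE)
  t2 <- list(); t3 <- list(); t4 <- list(); diag <- list()
  for (i in seq_len(nrow(grid))) {
    tr <- grid$trait[i]; hz <- grid$horizon[i]
    label <- paste0(toupper(tr), "/", hz)
    log_line(sprintf("[%s] outcome %s", sample_label, label))
    aset <- safe_stage(build_outcomes(cohort, tr, hz))
    if (stage_failed(aset)) next

    cont <- safe_stage(fit_continuous(aset, covariates = obs_cov))
    fp <- safe_stage(fp_nonlinearity_test(aset, covariates = obs_cov))
    row2 <- data.frame(sample = sample_label, trait = toupper(tr),
                       horizon = hz,
                       n = nrow(aset), cases = sum(aset$outcome),
                       or_per_ngml = NA_real_, ci95 = NA_character_,
                       p_linear = NA_real_, p_overall = NA_real_,
                       p_nonlinear = NA_real_, note = "",
                       stringsAsFactors = FALSE)
    if (!stage_failed(cont)) {
      ex <- cont$table[cont$table$term == "vitd", ]
      row2$or_per_ngml <- ex$or
      row2$ci95 <- format_ci(c(ex$ci_lower, ex$ci_upper))
      row2$p_linear <- ex$p
    } else row2$note <- cont$message
    if (!stage_failed(fp)) {
      row2$p_overall <- fp$p_overall
      row2$p_nonlinear <- fp$p_nonlinear
    } else if (row2$note == "") row2$note <- fp$message
    t2[[i]] <- row2

    cat3 <- safe_stage(fit_categorical(aset, covariates = obs_cov))
    row3 <- data.frame(sample = sample_label, trait = toupper(tr),
                       horizon = hz,
                       or_insufficiency = NA_real_,
                       ci_insufficiency = NA_character_,
                       p_insufficiency = NA_real_,
                       or_sufficiency = NA_real_,
                       ci_sufficiency = NA_character_,
                       p_sufficiency = NA_real_, note = "",
                       stringsAsFactors = FALSE)
    if (!stage_failed(cat3)) {
      for (lev in c("insufficiency", "sufficiency")) {
        rowname <- paste0("vitd_cat", lev)
        hit <- cat3$table[cat3$table$term == rowname, ]
        if (nrow(hit) == 1L) {
          row3[[paste0("or_", lev)]] <- hit$or
          row3[[paste0("ci_", lev)]] <- format_ci(c(hit$ci_lower,
                                                    hit$ci_upper))
          row3[[paste0("p_", lev)]] <- hit$p
        }
      }
    } else row3$note <- cat3$message
    t3[[i]] <- row3

    lin <- safe_stage(ratio_mr(cohort, tr, hz, covariates = mr_cov))
    nl <- safe_stage(nonlinear_mr(cohort, tr, hz, K = config$K,
                                  covariates = mr_cov))
    row4 <- data.frame(sample = sample_label, trait = toupper(tr),
                       horizon = hz, n = NA_integer_,
                       or_iv = NA_real_, ci95 = NA_character_,
                       p_linear = NA_real_, p_fp = NA_real_,
                       p_quadratic = NA_real_, p_cochranQ = NA_real_,
                       p_Q_instrument = NA_real_,
                       p_trend_instrument = NA_real_, note = "",
                       stringsAsFactors = FALSE)
    if (!stage_failed(lin)) {
      row4$n <- lin$n
      row4$or_iv <- lin$or_iv
      row4$ci95 <- format_ci(lin$ci95)
      row4$p_linear <- lin$p_linear
    } else row4$note <- lin$message
    if (!stage_failed(nl)) {
      row4$p_fp <- nl$p_fp
      row4$p_quadratic <- nl$p_quadratic
      row4$p_cochranQ <- nl$p_cochranQ
      row4$p_Q_instrument <- nl$p_Q_instrument
      row4$p_trend_instrument <- nl$p_trend_instrument
      st <- nl$strata
      st$sample <- sample_label; st$trait <- toupper(tr); st$horizon <- hz
      diag[[i]] <- as.data.frame(st)
    } else if (row4$note == "") row4$note <- nl$message
    t4[[i]] <- row4
  }
  list(table2 = do.call(rbind, t2), table3 = do.call(rbind, t3),
       table4 = do.call(rbind, t4),
       diagnostics = if (length(diag)) do.call(rbind, diag) else NULL)
}

#' Run the full analysis pipeline
#'
#' Executes, for every requested outcome (trait x horizon), the
#' observational models (continuous and categorical exposure, FP
#' non-linearity test), linear MR and non-linear MR; optionally repeats
#' everything on male-only and female-only subsets; and writes the report
#' bundle to `out_dir`: `table2_observational_continuous.tsv`,
#' `table3_observational_categorical.tsv`, `table4_mr.tsv`,
#' `strata_diagnostics.tsv`, `instrument.tsv`, `manifest.json` and
#' `run.log`.  A stage failure for one outcome is recorded in the report's
#' `note` column without aborting the other outcomes.  Identical input and
#' config produce identical outputs.
#'
#' @param cohort a cohort `data.frame` or path to a cohort CSV.
#' @param config an [analysis_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @return invisibly, a list with `instrument`, `pleiotropy`, `screen`,
#'   `table2`, `table3`, `table4`, `diagnostics`, `power` and `manifest`.
#' @export
run_all <- function(cohort, config = analysis_config(), out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  issues <- validate_schema(cohort)
  if (nrow(issues) > 0L) {
    stop("cohort fails schema validation (", nrow(issues), " issue(s)); ",
         "first: row ", issues$row[1], ", column ", issues$column[1], ": ",
         issues$problem[1])
  }
  have_cov <- setdiff(c(config$obs_covariates, config$mr_covariates),
                      names(cohort))
  if (length(have_cov) > 0L) {
    stop("configured covariates absent from input: ",
         paste(have_cov, collapse = ", "))
  }
  log_lines <- character()
  log_line <- function(msg) {
    log_lines <<- c(log_lines, paste0(format(Sys.time(),
                                             "%Y-%m-%d %H:%M:%S "), msg))
  }
  log_line("pipeline start")

  cohort <- ensure_pgs(cohort)
  screen <- screen_snps(cohort, alpha = config$alpha)
  inst <- fit_instrument(cohort, covariates = config$mr_covariates)
  pleio_cov <- setdiff(config$obs_covariates, config$mr_covariates)
  pleio <- check_pleiotropy(cohort, pleio_cov)
  log_line(sprintf("instrument: R^2 = %.4f, F = %.2f, n = %d",
                   inst$r_squared, inst$f_statistic, inst$n))

  samples <- list(total = cohort)
  if (config$stratify_sex) {
    samples$male <- cohort[cohort$sex == "male", , drop = FALSE]
    samples$female <- cohort[cohort$sex == "female", , drop = FALSE]
  }
  parts <- lapply(names(samples), function(lab) {
    analyse_sample(samples[[lab]], config, lab, log_line)
  })
  bind_part <- function(name) {
    do.call(rbind, Filter(Negate(is.null), lapply(parts, `[[`, name)))
  }
  table2 <- bind_part("table2")
  table3 <- bind_part("table3")
  table4 <- bind_part("table4")
  diagnostics <- bind_part("diagnostics")

  power <- NULL
  if (config$power) {
    base_prev <- mean(build_outcomes(cohort, "si", "baseline")$outcome)
    power <- mr_power_binary(inst$n, inst$r_squared, base_prev,
                             config$power_or, config$alpha)
  }
  log_line("pipeline done")

  manifest <- list(package = "vitdmr",
                   version = as.character(utils::packageVersion("vitdmr")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = config$seed,
                   n_input = nrow(cohort),
                   config = unclass(config))

  result <- list(instrument = inst, screen = screen, pleiotropy = pleio,
                 table2 = table2, table3 = table3, table4 = table4,
                 diagnostics = diagnostics, power = power,
                 manifest = manifest, log = log_lines)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, file) {
      write.table(df, file.path(out_dir, file), sep = "\t",
                  row.names = FALSE, quote = FALSE, na = "")
    }
    wt(table2, "table2_observational_continuous.tsv")
    wt(table3, "table3_observational_categorical.tsv")
    wt(table4, "table4_mr.tsv")
    if (!is.null(diagnostics)) wt(diagnostics, "strata_diagnostics.tsv")
    inst_df <- data.frame(beta_gx = inst$beta_gx, se_gx = inst$se_gx,
                          p_gx = inst$p_gx, r_squared = inst$r_squared,
                          f_statistic = inst$f_statistic, n = inst$n)
    wt(inst_df, "instrument.tsv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  invisible(result)
}
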