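# Small cohorts shared across tests; all generated in code under fixed seeds.

small_config <- function(n = 400, seed = 1, ...) {
  generator_config(n_participants = n, seed = seed, ...)
}

small_cohort <- function(n = 400, seed = 1, ...) {
  generate_cohort(small_config(n = n, seed = seed, ...))
}

# Hand-coded genotype frame for score arithmetic.
geno_frame <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(g_rs10741657 = r[1], g_rs4588 = r[2], g_rs7041 = r[3])
  }))
  out
}

# A 12-row three-wave table with a known outcome pattern, enumerable by hand.
toy_wave_table <- function() {
  data.frame(
    participant_id = sprintf("T%02d", 1:12),
    vitd = c(15, 25, 35, 19.9, 20, 30, 10, 28, 31, 22, 18, 26),
    si_w1 = c("no", "no", "no", "no", "yes", "yes", "no", "no", "no", "no",
              "no", NA),
    si_w2 = c("yes", "no", "no", "yes", "yes", "no", NA, "no", "yes", "no",
              "no", "no"),
    si_w3 = c("no", "yes", "no", "no", "no", "yes", "yes", NA, "yes", "no",
              NA, "no"),
    stringsAsFactors = FALSE)
}

ensure_pgs_test <- function(cohort) vitdmr:::ensure_pgs(cohort)
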