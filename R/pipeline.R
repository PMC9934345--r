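# End-to-end pipeline: simulate -> align -> evaluate -> write reports.
# Used by the command-line front end and for reproducibility checks.

#' Run the full simulate-and-evaluate pipeline
#'
#' Simulates a cohort, aligns it to birthdays, builds the reference library,
#' and writes the evaluation products to `outdir`: the raw cohort and truth
#' tables, the per-method MAE comparison (`compare.csv`), the GCC
#' first-age-by-last-age error matrices (`errors_male.csv`,
#' `errors_female.csv`), the CI tables (`ci_male.csv`, `ci_female.csv`) and
#' the PHV labels (`phv_labels.csv`).  Everything is deterministic given
#' `seed`.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed driving simulation, folds and boosting.
#' @param n_per_sex Children per sex (default 200).
#' @param methods Methods for the comparison report.
#' @param config A [gcc_config()].
#' @return Invisibly, a list with the cohort, truth table, comparison
#'   data.frame, error matrices and CI tables.
#' @export
run_pipeline <- function(outdir, seed = 17L, n_per_sex = 200L,
                         methods = c("gcc", "percentile", "linear", "tree",
                                     "xgb", "xgb_phv"),
                         config = gcc_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  params <- sim_params(n_per_sex = n_per_sex, seed = seed)
  sim <- simulate_cohort(params, dir = outdir)
  aligned <- align_cohort(sim$cohort)
  cohort <- build_reference_cohort(aligned)

  cmp <- compare_methods(cohort, methods, seed = seed, config = config)
  utils::write.csv(cmp, file.path(outdir, "compare.csv"), row.names = FALSE,
                   quote = FALSE)

  errmats <- cimats <- list()
  for (sex in c("male", "female")) {
    df <- evaluate_method(cohort, "gcc", sex, first_ages = 8:17,
                          last_ages = 8:17, seed = seed, config = config)
    errmats[[sex]] <- error_matrix(df)
    write_error_matrix(errmats[[sex]],
                       file.path(outdir, paste0("errors_", sex, ".csv")))
    cimats[[sex]] <- evaluate_ci_table(cohort, sex, config = config)
    write_error_matrix(cimats[[sex]],
                       file.path(outdir, paste0("ci_", sex, ".csv")))
  }
  labels <- label_phv_cohort(cohort)
  utils::write.csv(labels, file.path(outdir, "phv_labels.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(list(cohort = cohort, truth = sim$truth, compare = cmp,
                 errors = errmats, ci = cimats, phv_labels = labels))
}

#' Write an error matrix as CSV (ages as row/column labels)
#'
#' @param m An `error_matrix`.
#' @param path Output path.
#' @export
write_error_matrix <- function(m, path) {
  M <- unclass(m); attributes(M) <- attributes(m)[c("dim", "dimnames")]
  df <- data.frame(age = rownames(M), M, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
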