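# Evaluation protocol: per-age MAE curves, first-age x last-age error
# matrices, CI tables, and method comparison reports.
#
# Percentile and GCC are evaluated leave-the-query-out over all individuals
# (the query is excluded from the neighbour pool / norms); the regression
# baselines use 5-fold cross-validation with folds assigned by child.

#' Seed-reproducible k-fold assignment by child
#'
#' @param ids Child ids.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold labels (1..k) named by id; a true partition.
#' @export
make_folds <- function(ids, k = 5L, seed = 1L) {
  n <- length(ids)
  if (k > n) stop("more folds than children", call. = FALSE)
  f <- withr::with_seed(as.integer(seed), sample(rep_len(seq_len(k), n)))
  setNames(as.integer(f), ids)
}

regressor_kinds <- c("linear", "tree", "xgb", "xgb_phv")

# Earliest interval (starting age) with occurrence probability >= threshold,
# using only intervals fully observed within the 8..B prefix.
est_phv_from_probs <- function(probs, B, threshold = 0.5) {
  usable <- as.integer(colnames(probs)) <= B - 1L
  P <- probs[, usable, drop = FALSE]
  hit <- P >= threshold
  first <- apply(hit, 1, function(z) {
    w <- which(z)
    if (length(w)) as.integer(colnames(P))[w[1]] else NA_integer_
  })
  as.integer(first)
}

# Cross-validated absolute errors (cm) for one regressor kind over the
# last-age grid.  Returns a list of per-B error vectors over all children.
eval_regressor_cv <- function(H, sex, kind, last_ages, k_folds, seed) {
  folds <- make_folds(rownames(H), k_folds, seed)
  n <- nrow(H)
  per_fold <- lapply(seq_len(k_folds), function(f) {
    tr <- H[folds != f, , drop = FALSE]
    ref <- pop_stats(tr)
    probs <- NULL
    if (kind == "xgb_phv") {
      clf <- fit_phv_classifier(phv_rows_from_matrix(tr, sex),
                                seed = seed + f)
      probs <- phv_prob_matrix(clf, H, sex)
    }
    list(test = rownames(H)[folds == f], tr = tr, ref = ref, probs = probs,
         f = f)
  })
  errs <- list()
  for (B in as.integer(last_ages)) {
    ev <- rep(NA_real_, n); names(ev) <- rownames(H)
    for (pf in per_fold) {
      phv_tr <- phv_te <- NULL
      if (!is.null(pf$probs)) {
        est <- est_phv_from_probs(pf$probs, B)
        names(est) <- rownames(H)
        phv_tr <- est[rownames(pf$tr)]
        phv_te <- est[pf$test]
      }
      ft_tr <- feature_table(pf$tr, B, pf$ref, phv_ages = phv_tr)
      ft_te <- feature_table(H[pf$test, , drop = FALSE], B, pf$ref,
                             phv_ages = phv_te)
      fit <- fit_regressor(ft_tr, kind, seed = seed + pf$f)
      pred <- predict(fit, ft_te)
      ev[pf$test] <- abs(pred - ft_te$target_adult_height)
    }
    errs[[as.character(B)]] <- ev
  }
  errs
}

#' Evaluate a forecasting method over the (first age, last age) grid
#'
#' For each window of ages `A..B` the method predicts height at 18 for every
#' child of the stratum, and the mean absolute error is reported in
#' millimetres.  GCC and the percentile method are evaluated
#' leave-the-query-out over all individuals; the regression baselines use
#' child-level k-fold cross-validation and support only windows starting at
#' age 8 (other cells are returned as `NA`).  The percentile method reads
#' only the height at `B`, so its cells are constant along `A`.
#'
#' @param cohort A `reference_cohort`.
#' @param method One of `"gcc"`, `"percentile"`, `"linear"`, `"tree"`,
#'   `"xgb"`, `"xgb_phv"`, or a function `f(H, B, sex)` returning age-18
#'   predictions for every row of the stratum matrix `H` from the window
#'   ending at `B` (used for custom/oracle methods in testing).
#' @param sex `"male"` or `"female"`.
#' @param first_ages,last_ages Integer grids for `A` and `B` (defaults 8 and
#'   8..17).
#' @param k_folds,seed Cross-validation folds and seed (regressors).
#' @param config A [gcc_config()] (GCC only).
#' @return A data.frame `sex, method, first_age, last_age, mae_mm, n`.
#' @export
evaluate_method <- function(cohort, method, sex, first_ages = 8L,
                            last_ages = 8:17, k_folds = 5L, seed = 1L,
                            config = gcc_config()) {
  H <- cohort_stratum(cohort, sex)
  adult <- H[, ncol(H)]
  first_ages <- as.integer(first_ages); last_ages <- as.integer(last_ages)
  label <- if (is.function(method)) "custom" else method
  rows <- list()
  add <- function(A, B, errs_cm) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sex = sex, method = label, first_age = A, last_age = B,
      mae_mm = mean(errs_cm) * 10, n = length(errs_cm))
  }
  if (is.function(method)) {
    for (B in last_ages) for (A in first_ages[first_ages <= B])
      add(A, B, abs(method(H, B, sex) - adult))
  } else if (method == "gcc") {
    for (B in last_ages) for (A in first_ages[first_ages <= B]) {
      win <- A:B
      if (length(win) < 2L && config$similarity_basis == "increments") {
        add(A, B, NA_real_); next
      }
      preds <- gcc_batch_predict(
        H, rownames(H), H[, match(win, ALL_AGES), drop = FALSE],
        win, config, exclude_self = TRUE)
      add(A, B, abs(preds[, ncol(preds)] - adult))
    }
  } else if (method == "percentile") {
    for (B in last_ages) {
      errs <- abs(percentile_loo_predict(H, B) - adult)
      for (A in first_ages[first_ages <= B]) add(A, B, errs)
    }
  } else if (method %in% regressor_kinds) {
    if (!identical(first_ages, 8L))
      warning("regression baselines require windows starting at age 8; ",
              "other first ages are reported as NA", call. = FALSE)
    errs <- eval_regressor_cv(H, sex, method, last_ages, k_folds, seed)
    for (B in last_ages) {
      for (A in first_ages[first_ages <= B]) {
        if (A == 8L) add(A, B, errs[[as.character(B)]])
        else rows[[length(rows) + 1L]] <- data.frame(
          sex = sex, method = label, first_age = A, last_age = B,
          mae_mm = NA_real_, n = 0L)
      }
    }
  } else {
    stop("unknown method: ", method, call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$first_age, out$last_age), , drop = FALSE]
}

#' Pivot an evaluation data.frame into an upper-triangular error matrix
#'
#' @param df Output of [evaluate_method()] (one sex, one method).
#' @param value Column to place in the cells (default `"mae_mm"`).
#' @return A first-age x last-age matrix of class `error_matrix` (mm).
#' @export
error_matrix <- function(df, value = "mae_mm") {
  rows <- sort(unique(df$first_age)); cols <- sort(unique(df$last_age))
  M <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(A = rows, B = cols))
  M[cbind(match(df$first_age, rows), match(df$last_age, cols))] <- df[[value]]
  structure(M, class = c("error_matrix", "matrix"),
            sex = df$sex[1], metric = value, method = df$method[1])
}

#' @export
print.error_matrix <- function(x, ...) {
  cat(sprintf("<error_matrix> %s, %s, %s (mm)\n", attr(x, "method"),
              attr(x, "sex"), attr(x, "metric")))
  M <- x; attributes(M) <- attributes(x)[c("dim", "dimnames")]
  print(round(M, 1), na.print = "")
  invisible(x)
}

#' Confidence-interval table by (last age B, target age C)
#'
#' Delegates to [calibrate_ci()] and lays the 2-SD half-widths out as a
#' `B x C` matrix in millimetres (rows `B` = 9..17, columns `C` = `B+1`..18).
#'
#' @param cohort A `reference_cohort`.
#' @param sex Stratum.
#' @param config A [gcc_config()].
#' @param last_ages Which `B` rows to compute.
#' @return A matrix of class `error_matrix` (metric `ci_half_width_mm`).
#' @export
evaluate_ci_table <- function(cohort, sex, config = gcc_config(),
                              last_ages = 9:17) {
  ci <- calibrate_ci(cohort, config, last_ages = last_ages, sexes = sex)
  rows <- sort(unique(ci$last_age)); cols <- sort(unique(ci$target_age))
  M <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(B = rows, C = cols))
  M[cbind(match(ci$last_age, rows), match(ci$target_age, cols))] <-
    ci$ci_half_width_cm * 10
  structure(M, class = c("error_matrix", "matrix"),
            sex = sex, metric = "ci_half_width_mm", method = "gcc")
}

#' Compare forecasting methods across last observed ages
#'
#' Runs [evaluate_method()] for each method and sex over windows `8..B`,
#' producing the long-format per-age MAE report (the per-method error curve
#' as a function of the age up to which heights are available).
#'
#' @param cohort A `reference_cohort`.
#' @param methods Character vector of method names.
#' @param seed Seed for fold assignment and boosting.
#' @param upto_ages Last observed ages `B` (default 8..17).
#' @param config A [gcc_config()].
#' @param sexes Strata to evaluate.
#' @return A data.frame `sex, method, upto_age, mae_mm, n`.
#' @export
compare_methods <- function(cohort,
                            methods = c("gcc", "percentile", "linear",
                                        "tree", "xgb", "xgb_phv"),
                            seed = 1L, upto_ages = 8:17,
                            config = gcc_config(),
                            sexes = c("male", "female")) {
  if (length(methods) < 1L) stop("no methods given", call. = FALSE)
  out <- list()
  for (sex in sexes) for (m in methods) {
    df <- evaluate_method(cohort, m, sex, first_ages = 8L,
                          last_ages = upto_ages, seed = seed,
                          config = config)
    out[[length(out) + 1L]] <- data.frame(
      sex = df$sex, method = df$method, upto_age = df$last_age,
      mae_mm = df$mae_mm, n = df$n)
  }
  do.call(rbind, out)
}
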