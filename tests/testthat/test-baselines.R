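# Percentile rank-preservation and the regression baselines.

test_that("percentile norms: degenerate and rank-preserving cases", {
  # identical children: every percentile bin predicts the common adult height
  base <- c(seq(120, 165, 5), 168)
  M <- do.call(rbind, lapply(1:20, function(i) base))
  rownames(M) <- sprintf("c%02d", 1:20); colnames(M) <- 8:18
  norms <- fit_percentile_norms(cohort_from_matrices(male = M), "male")
  expect_equal(predict_percentile(norms, base[3], 10), 168)

  # strictly rank-preserving cohort (constant per-child offset): predictions
  # are exact up to bin discretisation
  offs <- seq(-12, 12, length.out = 120)
  Mrp <- t(vapply(offs, function(o) base + o, numeric(11)))
  rownames(Mrp) <- sprintf("r%03d", seq_along(offs)); colnames(Mrp) <- 8:18
  co <- cohort_from_matrices(female = Mrp)
  normsf <- fit_percentile_norms(co, "female")
  preds <- vapply(seq_along(offs), function(i)
    predict_percentile(normsf, Mrp[i, 3], 10), numeric(1))
  expect_lt(mean(abs(preds - Mrp[, 11])), 0.5)
  # a child keeping its rank gets the same prediction at every age
  p_by_age <- vapply(8:17, function(a)
    predict_percentile(normsf, Mrp[60, a - 7], a), numeric(1))
  expect_equal(max(p_by_age) - min(p_by_age), 0, tolerance = 1e-9)
})

test_that("percentile edge rules: boundary bins, ties down, clamping", {
  M <- random_stratum(100, seed = 31)
  co <- cohort_from_matrices(male = M)
  norms <- fit_percentile_norms(co, "male")
  tallest <- which.max(M[, 2])
  expect_equal(predict_percentile(norms, M[tallest, 2], 9),
               unname(norms$bin_means[100, "9"]))
  # a height exactly at a bin edge falls in the lower bin: with 100 members
  # the bin index equals the count of members at or below the height, so a
  # height equal to the 50th member sits in bin 50, epsilon above it in 51
  h <- sort(M[, 3])[50]
  expect_equal(predict_percentile(norms, h, 10),
               unname(norms$bin_means[50, "10"]))
  expect_equal(predict_percentile(norms, h + 1e-9, 10),
               unname(norms$bin_means[50, "10"]))  # still 50 at/below
  expect_warning(predict_percentile(norms, max(M[, 4]) + 5, 11), "clamped")
  expect_error(predict_percentile(norms, 150, 18))
})

test_that("feature extraction matches hand arithmetic", {
  M <- random_stratum(50, seed = 7)
  co <- cohort_from_matrices(male = M)
  q <- make_aligned("q", "M", c(130, 136, 145), ages = 8:10)
  f <- extract_features(q, co, 10)
  expect_equal(f$height_current, 145)
  expect_equal(f$height_previous, 136)
  expect_equal(f$growth_last, 9)
  expect_equal(f$growth_second_last, 6)
  expect_equal(f$growth_trend, 3)
  expect_equal(f$growth_diff_last_two, 3)
  expect_equal(f$mean_growth, 7.5)
  expect_equal(f$max_growth, 9)
  expect_equal(f$growth_variance, var(c(6, 9)))
  expect_equal(f$years_to_18, 8L)
  expect_false(f$flag_short_prefix)

  # constant growth: variance and trend vanish
  qc <- make_aligned("qc", "M", seq(130, 150, 5), ages = 8:12)
  fc <- extract_features(qc, co, 12)
  expect_equal(fc$growth_variance, 0)
  expect_equal(fc$growth_trend, 0)
  expect_equal(fc$mean_growth, 5)
  expect_equal(fc$max_growth, 5)
  expect_equal(fc$years_to_18, 6L)

  # single-age prefix: growth features zero-filled and flagged
  q1 <- make_aligned("q1", "M", 131, ages = 8)
  f1 <- extract_features(q1, co, 8)
  expect_true(f1$flag_short_prefix)
  expect_equal(f1$growth_last, 0)
  expect_equal(f1$mean_growth, 0)
})

test_that("features never read beyond the window (no target leakage)", {
  M <- random_stratum(40, seed = 8)
  co <- cohort_from_matrices(female = M)
  q <- make_aligned("q", "F", M[5, ])
  f_before <- extract_features(q, co, 12)
  mutated <- M[5, ]; mutated[6:11] <- mutated[6:11] + 25
  q2 <- make_aligned("q", "F", mutated)
  f_after <- extract_features(q2, co, 12)
  expect_identical(f_before, f_after)
})

test_that("regressors fit their realizable targets and reproduce under a seed", {
  M <- random_stratum(120, seed = 77)
  ref <- growthcast:::pop_stats(M)
  rows <- growthcast:::feature_table(M, 12, ref)
  # linear target exactly realizable by the linear model
  rows_lin <- rows
  rows_lin$target_adult_height <- 30 + 0.9 * rows$height_current
  fit <- fit_regressor(rows_lin, "linear")
  expect_lt(max(abs(predict(fit, rows_lin) -
                      rows_lin$target_adult_height)), 1e-6)
  # identical duplicated rows: the tree memorises the common target
  dup <- rows_lin[rep(1, 60), ]
  dup$target_adult_height <- 177
  expect_warning(ft <- fit_regressor(dup, "tree"), "constant")
  expect_equal(unname(predict(ft, dup[1, ])), 177)
  # boosting is bit-reproducible under a fixed seed
  f1 <- fit_regressor(rows, "xgb", seed = 42)
  f2 <- fit_regressor(rows, "xgb", seed = 42)
  expect_identical(predict(f1, rows), predict(f2, rows))
})

test_that("boosting fits the training data at least as well as least squares", {
  sc <- sim_cohort(250, seed = 33)
  H <- cohort_stratum(sc$cohort, "male")
  tr <- H[1:160, ]; te <- H[161:nrow(H), ]
  ref <- growthcast:::pop_stats(tr)
  rows_tr <- growthcast:::feature_table(tr, 11, ref)
  rows_te <- growthcast:::feature_table(te, 11, ref)
  flin <- fit_regressor(rows_tr, "linear", seed = 5)
  fxgb <- fit_regressor(rows_tr, "xgb", seed = 5)
  mae <- function(fit, rows) mean(abs(predict(fit, rows) -
                                        rows$target_adult_height))
  expect_lte(mae(fxgb, rows_tr), mae(flin, rows_tr))
  # and its generalisation gap is the larger one (the overfitting pattern)
  expect_gt(mae(fxgb, rows_te) - mae(fxgb, rows_tr),
            mae(flin, rows_te) - mae(flin, rows_tr))
})

test_that("constant training targets warn and predict the constant", {
  M <- random_stratum(60, seed = 13)
  rows <- growthcast:::feature_table(M, 10, growthcast:::pop_stats(M))
  rows$target_adult_height <- 170
  expect_warning(fit <- fit_regressor(rows, "linear"), "constant")
  expect_equal(unname(predict(fit, rows[1, ])), 170, tolerance = 1e-9)
})
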