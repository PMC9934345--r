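# Comparison forecasters: the percentile (rank-preservation) method and the
# regression baselines (linear, decision tree, gradient boosting with and
# without a PHV feature) over the engineered growth-curve feature set.

# ---- percentile method -----------------------------------------------------

# Empirical population statistics of a (training) stratum height matrix:
# sorted heights per age for percentile lookup, and mean annual growth per
# interval for the growth-vs-population feature.
pop_stats <- function(H) {
  list(n = nrow(H),
       heights_sorted = apply(H, 2, sort),
       mean_growth = colMeans(H[, -1L, drop = FALSE] -
                                H[, -ncol(H), drop = FALSE]))
}

# Fill empty percentile bins with the nearest non-empty bin (ties: lower bin).
fill_nearest_bin <- function(v) {
  filled <- which(!is.na(v))
  if (!length(filled)) return(v)
  idx <- vapply(seq_along(v), function(b) {
    filled[which.min(abs(filled - b))]
  }, integer(1))
  v[idx]
}

#' Fit percentile (rank-preservation) norms for one sex stratum
#'
#' The percentile method assumes a child keeps the same population rank from
#' the current age through to 18: the predicted adult height for a child at
#' the Nth percentile at a given age is the mean age-18 height of the
#' children occupying that percentile bin at that age.  Heights are binned
#' into 100 integer percentile bins; ties at bin edges fall to the lower bin.
#'
#' @param cohort A `reference_cohort`.
#' @param sex `"male"` or `"female"`.
#' @return An object of class `percentile_norms`.
#' @export
fit_percentile_norms <- function(cohort, sex) {
  H <- cohort_stratum(cohort, sex)
  n <- nrow(H)
  adult <- H[, ncol(H)]
  ages <- ALL_AGES[-length(ALL_AGES)]  # 8..17
  bin_means <- matrix(NA_real_, 100L, length(ages),
                      dimnames = list(NULL, ages))
  bins <- matrix(NA_integer_, n, length(ages), dimnames = list(rownames(H),
                                                               ages))
  for (j in seq_along(ages)) {
    cnt <- rank(H[, j], ties.method = "max")
    b <- pmin(100L, pmax(1L, as.integer(ceiling(100 * cnt / n))))
    bins[, j] <- b
    s <- tapply(adult, factor(b, levels = 1:100), mean)
    bin_means[, j] <- fill_nearest_bin(as.numeric(s))
  }
  structure(list(sex = normalize_sex(sex), n = n,
                 heights_sorted = apply(H[, seq_along(ages), drop = FALSE],
                                        2, sort),
                 bins = bins, adult = adult, bin_means = bin_means),
            class = "percentile_norms")
}

#' Predict adult height by percentile rank preservation
#'
#' @param norms A [fit_percentile_norms()] object.
#' @param height Observed height (cm) at `age`.
#' @param age Integer age in 8..17.
#' @return Predicted height at 18 (cm).  Heights outside the stratum's
#'   observed range at that age are clamped to the extreme bin with a warning.
#' @export
predict_percentile <- function(norms, height, age) {
  stopifnot(inherits(norms, "percentile_norms"))
  age <- as.integer(age)
  if (age < AGE_MIN || age > 17L)
    stop("age must be in 8..17", call. = FALSE)
  j <- age - AGE_MIN + 1L
  v <- norms$heights_sorted[, j]
  if (height < v[1] || height > v[length(v)])
    warning("height ", height, " cm outside the stratum range at age ", age,
            "; clamped to the nearest percentile bin", call. = FALSE)
  cnt <- findInterval(height, v)  # members with height <= query
  b <- pmin(100L, pmax(1L, as.integer(ceiling(100 * cnt / norms$n))))
  unname(norms$bin_means[b, j])
}

# Leave-the-query-out percentile predictions for every member of a stratum at
# last age B: the query's rank is taken among the other n-1 members and its
# own adult height is removed from the bin mean.
percentile_loo_predict <- function(H, B) {
  n <- nrow(H)
  j <- match(B, ALL_AGES)
  adult <- H[, ncol(H)]
  v <- H[, j]
  cnt <- rank(v, ties.method = "max")          # includes self
  bin_full <- pmin(100L, pmax(1L, as.integer(ceiling(100 * cnt / n))))
  S <- tapply(adult, factor(bin_full, levels = 1:100), sum)
  C <- tapply(rep(1, n), factor(bin_full, levels = 1:100), sum)
  S[is.na(S)] <- 0; C[is.na(C)] <- 0
  p_loo <- (cnt - 1L) / (n - 1L)
  b_loo <- pmin(100L, pmax(1L, as.integer(ceiling(100 * p_loo))))
  num <- S[b_loo] - ifelse(b_loo == bin_full, adult, 0)
  den <- C[b_loo] - (b_loo == bin_full)
  pred <- ifelse(den > 0, num / den, NA_real_)
  if (anyNA(pred)) {
    # singleton bin: fall back to the nearest bin with other members
    for (i in which(is.na(pred))) {
      Ci <- C; Si <- S
      Ci[bin_full[i]] <- Ci[bin_full[i]] - 1
      Si[bin_full[i]] <- Si[bin_full[i]] - adult[i]
      ok <- which(Ci > 0)
      b <- ok[which.min(abs(ok - b_loo[i]))]
      pred[i] <- Si[b] / Ci[b]
    }
  }
  unname(pred)
}

# ---- engineered features ---------------------------------------------------

base_feature_names <- c(
  "height_current", "height_previous", "growth_last", "growth_second_last",
  "mean_growth", "max_growth", "growth_variance", "percentile_current",
  "growth_vs_population", "growth_diff_last_two", "growth_trend",
  "years_to_18")
phv_extra_names <- c("phv_age_feat", "has_phv")

# Vectorised feature table from a prefix of a height matrix (ages 8..B).
# `ref` is pop_stats() of the training stratum (percentiles and population
# growth must come from data the model may see).  `phv_ages` is an integer
# vector (NA = not yet occurred) enabling the PHV feature pair.
feature_table <- function(H, B, ref, phv_ages = NULL, target = TRUE) {
  p <- B - AGE_MIN + 1L
  P <- H[, seq_len(p), drop = FALSE]
  n <- nrow(P)
  if (p >= 2L) {
    G <- P[, -1L, drop = FALSE] - P[, -p, drop = FALSE]
    growth_last <- G[, ncol(G)]
    mean_growth <- rowMeans(G)
    max_growth <- apply(G, 1, max)
    growth_variance <- if (ncol(G) >= 2L) apply(G, 1, var) else rep(0, n)
    height_previous <- P[, p - 1L]
  } else {
    growth_last <- mean_growth <- max_growth <- growth_variance <- rep(0, n)
    height_previous <- P[, p]
  }
  growth_second_last <- if (p >= 3L) {
    G[, ncol(G) - 1L]
  } else rep(0, n)
  trend <- if (p >= 3L) growth_last - growth_second_last else rep(0, n)
  vB <- ref$heights_sorted[, B - AGE_MIN + 1L]
  pct <- 100 * findInterval(P[, p], vB) / ref$n
  gvp <- if (p >= 2L) growth_last - ref$mean_growth[p - 1L] else rep(0, n)
  out <- data.frame(
    height_current = P[, p], height_previous = height_previous,
    growth_last = growth_last, growth_second_last = growth_second_last,
    mean_growth = mean_growth, max_growth = max_growth,
    growth_variance = growth_variance, percentile_current = pct,
    growth_vs_population = gvp, growth_diff_last_two = trend,
    growth_trend = trend, years_to_18 = rep(18L - B, n),
    flag_short_prefix = rep(p < 3L, n), row.names = rownames(H))
  if (!is.null(phv_ages)) {
    out$phv_age_feat <- ifelse(is.na(phv_ages), 0, phv_ages)
    out$has_phv <- as.integer(!is.na(phv_ages))
  }
  if (target) out$target_adult_height <- H[, ncol(H)]
  out
}

#' Extract the regression feature row for one child
#'
#' Computes the engineered features of the growth-curve prefix up to
#' `upto_age`: current and previous height, last and second-to-last annual
#' growth (first derivative), mean/max/variance of annual growth, current
#' population percentile, growth relative to the population mean, growth
#' trend (second derivative, two equivalent encodings), and distance from
#' age 18.  With `with_phv`, the estimated PHV age (sentinel 0 plus a
#' has-occurred indicator) is appended.  Only ages at or below `upto_age` are
#' read — never the future.
#'
#' A single-age prefix zero-fills all growth features; prefixes shorter than
#' three ages zero-fill the second-derivative features; both set
#' `flag_short_prefix`.
#'
#' @param query An `aligned_series` with contiguous ages 8..`upto_age`.
#' @param cohort A `reference_cohort` supplying population statistics.
#' @param upto_age Integer age in 8..17.
#' @param with_phv Append the PHV feature pair?
#' @param phv_age Estimated PHV starting age (`NA` = not yet); required when
#'   `with_phv` is `TRUE`.
#' @return A one-row data.frame of features.
#' @export
extract_features <- function(query, cohort, upto_age, with_phv = FALSE,
                             phv_age = NULL) {
  stopifnot(inherits(query, "aligned_series"))
  upto_age <- as.integer(upto_age)
  want <- AGE_MIN:upto_age
  if (!all(want %in% query$ages))
    stop_gc("regression features require a contiguous prefix of ages 8..",
            upto_age, class = "gc_incomplete_series")
  H <- matrix(query$heights[match(want, query$ages)], nrow = 1,
              dimnames = list(query$child_id, want))
  ref <- pop_stats(cohort_stratum(cohort, query$sex))
  feature_table(H, upto_age, ref,
                phv_ages = if (with_phv) phv_age %||% NA_integer_,
                target = FALSE)
}

# ---- regressors ------------------------------------------------------------

#' Fit an adult-height regression baseline
#'
#' Fits one model per (sex, last-age) slice of the evaluation grid, predicting
#' height at 18 from the engineered feature row.  `"linear"` uses ordinary
#' least squares; `"tree"` a depth-limited CART regression tree; `"xgb"` and
#' `"xgb_phv"` gradient boosting (the latter additionally consumes the PHV
#' feature pair).  Training is deterministic given `seed` (boosting is
#' single-threaded).
#'
#' @param rows A feature data.frame with a `target_adult_height` column (from
#'   [feature_table()]/[extract_features()] with targets attached).
#' @param model_kind One of `"linear"`, `"tree"`, `"xgb"`, `"xgb_phv"`.
#' @param seed Integer seed.
#' @param nrounds,max_depth,learning_rate Boosting hyperparameters (ignored
#'   for linear/tree).
#' @return An object of class `growth_regressor` supporting [predict()].
#' @export
fit_regressor <- function(rows,
                          model_kind = c("linear", "tree", "xgb", "xgb_phv"),
                          seed = 1L, nrounds = 150L, max_depth = 4L,
                          learning_rate = 0.1) {
  model_kind <- match.arg(model_kind)
  if (nrow(rows) < 2L) stop("need at least two training rows", call. = FALSE)
  feats <- base_feature_names
  if (model_kind == "xgb_phv") {
    if (!all(phv_extra_names %in% names(rows)))
      stop("xgb_phv requires the PHV feature pair in `rows`", call. = FALSE)
    feats <- c(feats, phv_extra_names)
  }
  y <- rows$target_adult_height
  if (is.null(y)) stop("rows must contain target_adult_height", call. = FALSE)
  if (var(y) == 0)
    warning("constant training target; model will predict the constant",
            call. = FALSE)
  X <- rows[, feats, drop = FALSE]
  model <- switch(
    model_kind,
    linear = stats::lm(y ~ ., data = cbind(X, y = y)),
    tree = rpart::rpart(
      y ~ ., data = cbind(X, y = y), method = "anova",
      control = rpart::rpart.control(maxdepth = 6, cp = 0.001,
                                     xval = 0)),
    xgb = ,
    xgb_phv = xgboost::xgboost(
      as.matrix(X), y, nrounds = nrounds, max_depth = max_depth,
      learning_rate = learning_rate, nthreads = 1L,
      seed = as.integer(seed), verbosity = 0L))
  structure(list(kind = model_kind, model = model, features = feats),
            class = "growth_regressor")
}

#' Predict adult height from feature rows
#'
#' @param object A `growth_regressor`.
#' @param newdata Feature data.frame (as produced by [extract_features()] or
#'   [feature_table()]).
#' @param ... Unused.
#' @return Numeric vector of predicted age-18 heights (cm).
#' @export
predict.growth_regressor <- function(object, newdata, ...) {
  X <- newdata[, object$features, drop = FALSE]
  if (object$kind %in% c("xgb", "xgb_phv")) {
    as.numeric(predict(object$model, as.matrix(X)))
  } else {
    as.numeric(predict(object$model, X))
  }
}
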