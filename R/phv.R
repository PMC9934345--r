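# Peak height velocity (PHV): discrete labelling from annual increments and a
# per-year occurrence classifier usable as a forecasting feature.
#
# PHV age is operationalised as the starting age of the annual interval with
# the largest height increment (ties: earliest interval), matching the
# reading "age at which PHV begins".

#' Label the PHV interval of a complete growth curve
#'
#' @param series An `aligned_series` with all ages 8..18.
#' @return A list of class `phv_label`: `child_id`, `phv_age` (starting age of
#'   the maximal annual interval, 8..17) and `max_annual_growth` (cm/yr).
#' @examples
#' a <- aligned_series("x", "M", 8:18,
#'                     cumsum(c(130, 5, 5, 5, 6, 9, 7, 5, 3, 2, 1)))
#' label_phv(a)$phv_age  # 12: the 9 cm interval starts at age 12
#' @export
label_phv <- function(series) {
  stopifnot(inherits(series, "aligned_series"))
  if (!identical(series$ages, ALL_AGES))
    stop_gc("PHV labelling requires a complete age-8..18 series",
            class = "gc_incomplete_series")
  inc <- diff(series$heights)
  j <- which.max(inc)  # earliest maximal interval
  structure(list(child_id = series$child_id,
                 phv_age = ALL_AGES[j],
                 max_annual_growth = inc[j]),
            class = "phv_label")
}

#' @export
print.phv_label <- function(x, ...) {
  cat(sprintf("<phv_label> %s: PHV begins at age %d (%.2f cm/yr)\n",
              x$child_id, x$phv_age, x$max_annual_growth))
  invisible(x)
}

# Vectorised PHV labels for a stratum height matrix: starting ages 8..17.
phv_ages_matrix <- function(H) {
  INC <- H[, -1L, drop = FALSE] - H[, -ncol(H), drop = FALSE]
  ALL_AGES[max.col(INC, ties.method = "first")]
}

#' Label PHV for every member of a reference cohort
#'
#' @param cohort A `reference_cohort`.
#' @return A data.frame `child_id, sex, phv_age, max_annual_growth_cm`.
#' @export
label_phv_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "reference_cohort"))
  out <- lapply(c("male", "female"), function(sex) {
    H <- cohort$heights[[sex]]
    if (nrow(H) == 0L) return(NULL)
    INC <- H[, -1L, drop = FALSE] - H[, -ncol(H), drop = FALSE]
    j <- max.col(INC, ties.method = "first")
    data.frame(child_id = rownames(H), sex = sex,
               phv_age = ALL_AGES[j],
               max_annual_growth_cm = INC[cbind(seq_len(nrow(INC)), j)],
               row.names = NULL)
  })
  do.call(rbind, out)
}

# Per-interval growth-change features for interval starting at age a
# (increment a -> a+1).  All features use only heights at ages <= a+1, so a
# prefix ending at age B supports intervals with a <= B-1 (no lookahead).
phv_interval_features <- function(H, pop_mean_inc) {
  INC <- H[, -1L, drop = FALSE] - H[, -ncol(H), drop = FALSE]
  n <- nrow(INC); p <- ncol(INC)
  prev <- cbind(0, INC[, -p, drop = FALSE])
  has_prev <- matrix(rep(c(0, rep(1, p - 1L)), each = n), n, p)
  rel <- INC - rep(pop_mean_inc, each = n)
  list(increment = INC, prev_increment = prev, has_prev = has_prev,
       increment_diff = (INC - prev) * has_prev, increment_rel_pop = rel)
}

#' Build the per-(child, interval) PHV occurrence dataset
#'
#' One binary-labelled row per child per annual interval (10 intervals per
#' complete series, exactly one labelled positive).  Features describe the
#' local change in growth: the interval's increment, the previous increment,
#' their difference, and the increment relative to the same-sex same-age
#' population mean.
#'
#' @param cohort A `reference_cohort`.
#' @return A data.frame with columns `child_id`, `sex`, `interval_start_age`,
#'   the features, and `label` (1 = PHV starts at this interval).  The
#'   per-sex population mean increments are attached as attribute
#'   `pop_mean_increments`.
#' @export
phv_occurrence_dataset <- function(cohort) {
  stopifnot(inherits(cohort, "reference_cohort"))
  pop <- list()
  rows <- lapply(c("male", "female"), function(sex) {
    H <- cohort$heights[[sex]]
    if (nrow(H) == 0L) return(NULL)
    r <- phv_rows_from_matrix(H, sex)
    pop[[sex]] <<- attr(r, "pop_mean_increments")[[sex]]
    r
  })
  out <- do.call(rbind, rows)
  attr(out, "pop_mean_increments") <- pop
  out
}

# Occurrence rows for one stratum height matrix (internal building block; the
# population mean increments come from this matrix only, so per-fold training
# stays free of test-fold information).
phv_rows_from_matrix <- function(H, sex) {
  INC <- H[, -1L, drop = FALSE] - H[, -ncol(H), drop = FALSE]
  pop <- colMeans(INC)
  f <- phv_interval_features(H, pop)
  phv <- ALL_AGES[max.col(INC, ties.method = "first")]
  p <- ncol(INC)
  out <- data.frame(
    child_id = rep(rownames(H), times = p),
    sex = sex,
    interval_start_age = rep(ALL_AGES[seq_len(p)], each = nrow(H)),
    increment = as.vector(f$increment),
    prev_increment = as.vector(f$prev_increment),
    has_prev = as.vector(f$has_prev),
    increment_diff = as.vector(f$increment_diff),
    increment_rel_pop = as.vector(f$increment_rel_pop),
    label = as.integer(rep(phv, times = p) ==
                         rep(ALL_AGES[seq_len(p)], each = nrow(H))),
    row.names = NULL)
  attr(out, "pop_mean_increments") <- setNames(list(pop), sex)
  out
}

phv_feature_names <- c("increment", "prev_increment", "has_prev",
                       "increment_diff", "increment_rel_pop")

#' Fit the per-year PHV occurrence classifier
#'
#' A gradient-boosted binary classifier predicting, for each annual interval
#' of a growth curve, whether the PHV interval is this one.
#'
#' @param rows Output of [phv_occurrence_dataset()].
#' @param seed Integer seed; training is deterministic given the seed
#'   (single-threaded boosting).
#' @param nrounds,max_depth,learning_rate Boosting hyperparameters.
#' @return An object of class `phv_classifier`.
#' @export
fit_phv_classifier <- function(rows, seed = 1L, nrounds = 100L,
                               max_depth = 3L, learning_rate = 0.2) {
  X <- as.matrix(rows[, phv_feature_names])
  y <- factor(rows$label, levels = c(0, 1))
  model <- xgboost::xgboost(
    X, y, objective = "binary:logistic", nrounds = nrounds,
    max_depth = max_depth, learning_rate = learning_rate,
    nthreads = 1L, seed = as.integer(seed), verbosity = 0L)
  structure(list(model = model,
                 pop_mean_increments = attr(rows, "pop_mean_increments"),
                 threshold = 0.5),
            class = "phv_classifier")
}

# Probability that each interval is the PHV interval, for every member of a
# height matrix (children x intervals 8..17).
phv_prob_matrix <- function(clf, H, sex) {
  pop <- clf$pop_mean_increments[[sex]]
  f <- phv_interval_features(H, pop)
  X <- cbind(increment = as.vector(f$increment),
             prev_increment = as.vector(f$prev_increment),
             has_prev = as.vector(f$has_prev),
             increment_diff = as.vector(f$increment_diff),
             increment_rel_pop = as.vector(f$increment_rel_pop))
  p <- predict_phv_prob(clf, X)
  matrix(p, nrow = nrow(H), ncol = ncol(H) - 1L,
         dimnames = list(rownames(H), ALL_AGES[-length(ALL_AGES)]))
}

predict_phv_prob <- function(clf, X) {
  pr <- predict(clf$model, X)
  if (is.matrix(pr)) pr <- pr[, ncol(pr)]  # prob of the positive class
  as.numeric(pr)
}

#' Estimate PHV age from an observed prefix of a growth curve
#'
#' Scores every fully observed annual interval of the prefix with the
#' occurrence classifier and returns the starting age of the earliest
#' interval whose probability exceeds the threshold, or `NA` when the
#' classifier believes PHV has not yet occurred.  Only past-and-current
#' intervals are used — no lookahead.
#'
#' @param clf A [fit_phv_classifier()] handle.
#' @param prefix An `aligned_series` with contiguous ages from 8.
#' @return Integer PHV starting age, or `NA_integer_` for "not yet".
#' @export
predict_phv_age <- function(clf, prefix) {
  stopifnot(inherits(clf, "phv_classifier"),
            inherits(prefix, "aligned_series"))
  if (prefix$ages[1] != AGE_MIN ||
      !identical(prefix$ages, seq(AGE_MIN, max(prefix$ages))))
    stop_gc("prefix must cover contiguous ages from 8",
            class = "gc_incomplete_series")
  if (length(prefix$ages) < 2L) return(NA_integer_)
  H <- matrix(prefix$heights, nrow = 1,
              dimnames = list(prefix$child_id, prefix$ages))
  pop <- clf$pop_mean_increments[[prefix$sex]][seq_len(ncol(H) - 1L)]
  f <- phv_interval_features(H, pop)
  X <- cbind(increment = as.vector(f$increment),
             prev_increment = as.vector(f$prev_increment),
             has_prev = as.vector(f$has_prev),
             increment_diff = as.vector(f$increment_diff),
             increment_rel_pop = as.vector(f$increment_rel_pop))
  p <- predict_phv_prob(clf, X)
  hit <- which(p >= clf$threshold)
  if (!length(hit)) NA_integer_ else ALL_AGES[hit[1]]
}
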