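# Growth Curve Comparison (GCC): cosine-similarity retrieval of the most
# similar reference growth curves, forecasting by summing the neighbours'
# mean annual increments on top of the query's last observed height, and
# empirical 2-SD confidence-interval calibration.

#' GCC configuration
#'
#' @param k_neighbors Number of most-similar reference children to retrieve
#'   (default 100; the useful range is roughly 75-150, beyond which accuracy
#'   gains are negligible).
#' @param similarity_basis What the cosine similarity is computed on:
#'   `"heights"` (the growth-curve vector itself, the default) or
#'   `"increments"` (year-on-year growth vector, more discriminative because
#'   raw height curves are all nearly parallel).
#' @param min_overlap_ages Minimum number of observed query ages required for
#'   retrieval (default 2; the method always needs at least two measurements).
#' @param on_insufficient What to do when fewer than `k_neighbors` eligible
#'   reference members exist: `"error"` (default) or `"all"` (degrade to using
#'   every eligible member).
#' @return A list of class `gcc_config`.
#' @export
gcc_config <- function(k_neighbors = 100L,
                       similarity_basis = c("heights", "increments"),
                       min_overlap_ages = 2L,
                       on_insufficient = c("error", "all")) {
  k_neighbors <- as.integer(k_neighbors)
  stopifnot(k_neighbors >= 1L, min_overlap_ages >= 1L)
  structure(list(k_neighbors = k_neighbors,
                 similarity_basis = match.arg(similarity_basis),
                 min_overlap_ages = as.integer(min_overlap_ages),
                 on_insufficient = match.arg(on_insufficient)),
            class = "gcc_config")
}

#' Cosine similarity between two vectors
#'
#' `k(x, y) = <x, y> / (||x|| ||y||)`, the retrieval metric used to compare
#' growth curves.
#'
#' @param x,y Numeric vectors of equal length, neither all-zero.
#' @return A score in `[-1, 1]`.
#' @examples
#' cosine_similarity(c(3, 4), c(4, 3))  # 24/25
#' @export
cosine_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 1L) stop("vectors must be non-empty", call. = FALSE)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop_gc("cosine similarity undefined for a zero-norm vector",
            class = "gc_zero_norm")
  min(1, max(-1, sum(x * y) / (nx * ny)))
}

# Row-normalised basis vectors for similarity, from a heights matrix restricted
# to the window columns.  For the increments basis, per-year growth rates
# between consecutive observed ages.
basis_matrix <- function(H, win_ages, basis) {
  cols <- match(as.character(win_ages), colnames(H))
  if (anyNA(cols))
    stop("height matrix lacks columns for ages ",
         paste(win_ages[is.na(cols)], collapse = ","), call. = FALSE)
  W <- H[, cols, drop = FALSE]
  if (basis == "increments") {
    if (length(cols) < 2L)
      stop_gc("increments basis needs at least two observed ages",
              class = "gc_insufficient_data")
    gaps <- diff(win_ages)
    W <- (W[, -1L, drop = FALSE] - W[, -ncol(W), drop = FALSE]) /
      rep(gaps, each = nrow(W))
  }
  W
}

row_unit <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  nrm[nrm == 0] <- NA_real_  # all-zero vector: similarity undefined
  M / nrm
}

#' Retrieve the most similar reference growth curves
#'
#' Computes the cosine similarity between the query's observed growth curve up
#' to `upto_age` and every same-sex reference member (restricted to the ages
#' the query has observed), and returns the top `k_neighbors`.  Ties in
#' similarity are broken by smaller absolute height difference at the anchor
#' age, then by child id; the query itself is excluded when present in the
#' cohort.
#'
#' @param query An `aligned_series`.
#' @param cohort A `reference_cohort`.
#' @param upto_age Last age (integer, 8..17) of the observation window.
#' @param config A [gcc_config()].
#' @return An object of class `neighbor_set`: list with `query_id`,
#'   `neighbor_ids`, `similarities` (non-increasing), `upto_age`.
#' @export
find_neighbors <- function(query, cohort, upto_age, config = gcc_config()) {
  stopifnot(inherits(query, "aligned_series"))
  upto_age <- as.integer(upto_age)
  obs <- query$ages[query$ages <= upto_age]
  if (length(obs) < config$min_overlap_ages)
    stop_gc("query has fewer than ", config$min_overlap_ages,
            " observed ages at or below age ", upto_age,
            class = "gc_insufficient_data")
  H <- cohort_stratum(cohort, query$sex)
  qh <- query$heights[match(obs, query$ages)]
  anchor_age <- max(obs)
  res <- gcc_rank(H, qh, obs, anchor_age,
                  exclude_id = query$child_id, config = config)
  structure(list(query_id = query$child_id,
                 neighbor_ids = res$ids,
                 similarities = res$sims,
                 upto_age = upto_age,
                 anchor_age = anchor_age),
            class = "neighbor_set")
}

#' @export
print.neighbor_set <- function(x, ...) {
  cat(sprintf("<neighbor_set> query %s, %d neighbours (sim %.4f .. %.4f)\n",
              x$query_id, length(x$neighbor_ids),
              max(x$similarities), min(x$similarities)))
  invisible(x)
}

# Rank one query against a stratum matrix; shared by find_neighbors and the
# batch evaluation path so both apply the identical tie rule.
gcc_rank <- function(H, q_heights, win_ages, anchor_age, exclude_id,
                     config) {
  Vr <- row_unit(basis_matrix(H, win_ages, config$similarity_basis))
  qv <- basis_matrix(matrix(q_heights, nrow = 1,
                            dimnames = list(NULL, win_ages)),
                     win_ages, config$similarity_basis)[1, ]
  qn <- sqrt(sum(qv^2))
  if (is.na(qn) || qn == 0)
    stop_gc("query growth-curve vector has zero norm",
            class = "gc_zero_norm")
  sims <- as.vector(Vr %*% (qv / qn))
  sims[is.na(sims)] <- -Inf
  ids <- rownames(H)
  elig <- ids != exclude_id
  k <- config$k_neighbors
  n_elig <- sum(elig)
  if (n_elig < k) {
    if (config$on_insufficient == "error")
      stop_gc("only ", n_elig, " eligible reference members for k = ", k,
              class = "gc_insufficient_cohort")
    k <- n_elig
  }
  anchor_col <- match(anchor_age, ALL_AGES)
  adiff <- abs(H[, anchor_col] - q_heights[match(anchor_age, win_ages)])
  sims[!elig] <- -Inf
  ord <- order(-sims, adiff, ids)[seq_len(k)]
  list(ids = ids[ord], sims = pmin(1, sims[ord]), idx = ord)
}

#' Forecast heights by summing neighbours' mean annual increments
#'
#' For each target age `a` in `(upto_age, 18]` the neighbours' mean annual
#' increment `mean(height(a) - height(a - 1))` is computed, and the forecast
#' is the query's own observed height at `upto_age` plus the running sum of
#' these mean increments.  Anchoring on the query's last height (rather than
#' on the neighbours' median height) keeps the forecast unbiased for very
#' tall or very short children, whose neighbours are systematically shorter
#' or taller than they are.
#'
#' @param query An `aligned_series` with an observed height at `upto_age`.
#' @param neighbors A `neighbor_set` from [find_neighbors()].
#' @param cohort The `reference_cohort` the neighbours came from.
#' @param upto_age Anchor age (height observed).
#' @param ci Optional calibration table from [calibrate_ci()]; when supplied,
#'   the matching `(last_age = upto_age, target_age)` half-widths are attached.
#' @return An object of class `gcc_forecast`: list with `child_id`,
#'   `last_observed_age`, `predictions` (named by target age, cm) and
#'   `ci_half_width` (named, cm, or `NULL`).
#' @export
forecast_heights <- function(query, neighbors, cohort, upto_age, ci = NULL) {
  stopifnot(inherits(neighbors, "neighbor_set"))
  upto_age <- as.integer(upto_age)
  pos <- match(upto_age, query$ages)
  if (is.na(pos))
    stop_gc("query has no observed height at age ", upto_age,
            class = "gc_missing_anchor")
  if (!length(neighbors$neighbor_ids))
    stop_gc("empty neighbour set", class = "gc_insufficient_cohort")
  H <- cohort_stratum(cohort, query$sex)
  N <- H[neighbors$neighbor_ids, , drop = FALSE]
  b <- match(upto_age, ALL_AGES)
  target_ages <- seq(upto_age + 1L, AGE_MAX)
  if (upto_age >= AGE_MAX)
    stop("upto_age must be below 18", call. = FALSE)
  inc <- N[, (b + 1L):ncol(N), drop = FALSE] - N[, b:(ncol(N) - 1L),
                                                 drop = FALSE]
  mean_inc <- colMeans(inc)
  preds <- query$heights[pos] + cumsum(mean_inc)
  names(preds) <- target_ages
  hw <- NULL
  if (!is.null(ci)) {
    sel <- ci$sex == query$sex & ci$last_age == upto_age
    hw <- setNames(ci$ci_half_width_cm[sel][match(target_ages,
                                                  ci$target_age[sel])],
                   target_ages)
  }
  structure(list(child_id = query$child_id, last_observed_age = upto_age,
                 predictions = preds, ci_half_width = hw),
            class = "gcc_forecast")
}

#' @export
print.gcc_forecast <- function(x, ...) {
  cat(sprintf("<gcc_forecast> %s from age %d\n", x$child_id,
              x$last_observed_age))
  df <- data.frame(age = as.integer(names(x$predictions)),
                   predicted_cm = round(x$predictions, 1))
  if (!is.null(x$ci_half_width))
    df$ci_half_width_cm <- round(x$ci_half_width, 1)
  print(df, row.names = FALSE)
  invisible(x)
}

# Batch leave-one-out GCC predictions for every member of a stratum, using
# the window 8..B (or A..B).  Returns an m x (18-B) matrix of predicted
# heights at ages B+1..18 for the query rows.
gcc_batch_predict <- function(H, q_ids, Q, win_ages, config,
                              exclude_self = TRUE) {
  B <- max(win_ages)
  bcol <- match(B, ALL_AGES)
  Vr <- row_unit(basis_matrix(H, win_ages, config$similarity_basis))
  Vq <- row_unit(basis_matrix(Q, win_ages, config$similarity_basis))
  S <- Vq %*% t(Vr)
  S[is.na(S)] <- -Inf
  ids <- rownames(H)
  k <- config$k_neighbors
  Finc <- H[, (bcol + 1L):ncol(H), drop = FALSE] -
    H[, bcol:(ncol(H) - 1L), drop = FALSE]
  anchor_ref <- H[, bcol]
  anchor_q <- Q[, match(B, win_ages)]
  m <- nrow(Q)
  out <- matrix(NA_real_, m, ncol(Finc),
                dimnames = list(q_ids, (B + 1L):AGE_MAX))
  n_members <- nrow(H)
  for (i in seq_len(m)) {
    s <- S[i, ]
    if (exclude_self) {
      j <- match(q_ids[i], ids)
      if (!is.na(j)) s[j] <- -Inf
    }
    n_elig <- if (exclude_self && !is.na(match(q_ids[i], ids)))
      n_members - 1L else n_members
    kk <- k
    if (n_elig < k) {
      if (config$on_insufficient == "error")
        stop_gc("only ", n_elig, " eligible reference members for k = ", k,
                class = "gc_insufficient_cohort")
      kk <- n_elig
    }
    ord <- order(-s, abs(anchor_ref - anchor_q[i]), ids)[seq_len(kk)]
    out[i, ] <- anchor_q[i] + cumsum(colMeans(Finc[ord, , drop = FALSE]))
  }
  out
}

#' Calibrate empirical 95% prediction intervals for GCC forecasts
#'
#' For every combination of last observed age `B` and forecast target age
#' `C > B`, forecasts are made for every cohort member from the window
#' `8..B` with the member itself left out of the neighbour pool; the interval
#' half-width is twice the sample standard deviation of the residuals
#' (actual minus predicted height at `C`), the empirical 95% band.
#'
#' @param cohort A `reference_cohort`.
#' @param config A [gcc_config()].
#' @param last_ages Which last-observed ages `B` to calibrate (default 9..17).
#' @param sexes Which strata (default both).
#' @return A data.frame of class `gcc_ci` with columns `sex`, `last_age`,
#'   `target_age`, `ci_half_width_cm`, `n`.
#' @export
calibrate_ci <- function(cohort, config = gcc_config(),
                         last_ages = 9:17,
                         sexes = c("male", "female")) {
  out <- list()
  for (sex in sexes) {
    H <- cohort_stratum(cohort, sex)
    if (nrow(H) < config$k_neighbors + 1L)
      stop_gc("stratum '", sex, "' has ", nrow(H),
              " members; need at least k + 1 = ", config$k_neighbors + 1L,
              class = "gc_insufficient_cohort")
    for (B in as.integer(last_ages)) {
      win <- AGE_MIN:B
      preds <- gcc_batch_predict(H, rownames(H), H[, seq_along(win),
                                                   drop = FALSE],
                                 win, config, exclude_self = TRUE)
      actual <- H[, match((B + 1L):AGE_MAX, ALL_AGES), drop = FALSE]
      res <- actual - preds
      out[[length(out) + 1L]] <- data.frame(
        sex = sex, last_age = B, target_age = (B + 1L):AGE_MAX,
        ci_half_width_cm = 2 * apply(res, 2, sd), n = nrow(H),
        row.names = NULL)
    }
  }
  structure(do.call(rbind, out), class = c("gcc_ci", "data.frame"))
}
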