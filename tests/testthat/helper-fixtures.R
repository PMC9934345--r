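# Fixture builders shared across test files.  Everything is generated in code
# under fixed seeds; no stored data.

# A complete aligned series from a full 8..18 height vector.
make_aligned <- function(id, sex, heights, ages = 8:18) {
  aligned_series(id, sex, ages, heights)
}

# Reference cohort straight from per-sex height matrices (rownames = ids).
cohort_from_matrices <- function(male = NULL, female = NULL) {
  empty <- matrix(numeric(0), 0, 11, dimnames = list(NULL, 8:18))
  structure(list(ages = 8:18,
                 heights = list(male = male %||% empty,
                                female = female %||% empty)),
            class = "reference_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random growth-curve-like height matrix: positive start, positive annual
# increments with one inflated interval, so curves resemble real ones.
random_stratum <- function(n, seed, prefix = "r") {
  withr::with_seed(seed, {
    inc <- matrix(runif(n * 10, 1, 8), n, 10)
    h8 <- runif(n, 115, 140)
    M <- cbind(h8, h8 + t(apply(inc, 1, cumsum)))
    dimnames(M) <- list(sprintf("%s%04d", prefix, seq_len(n)), 8:18)
    M
  })
}

# Simulated, aligned, complete reference cohort plus the truth table.
sim_cohort <- function(n_per_sex, seed, ...) {
  params <- sim_params(n_per_sex = n_per_sex, seed = seed, ...)
  sim <- simulate_cohort(params)
  cohort <- suppressMessages(
    build_reference_cohort(suppressMessages(align_cohort(sim$cohort))))
  list(cohort = cohort, truth = sim$truth, params = params)
}

# Brute-force neighbour oracle: exhaustive cosine similarity with the
# documented tie rule (similarity desc, |height diff at anchor| asc, id asc),
# computed one member at a time via the scalar cosine_similarity().
oracle_neighbors <- function(H, q_heights, win_ages, k, exclude_id,
                             basis = "heights") {
  vecify <- function(h) if (basis == "heights") h else diff(h) / diff(win_ages)
  qv <- vecify(q_heights)
  cols <- match(win_ages, 8:18)
  sims <- vapply(seq_len(nrow(H)), function(i)
    cosine_similarity(vecify(H[i, cols]), qv), numeric(1))
  anchor <- max(win_ages)
  adiff <- abs(H[, match(anchor, 8:18)] - q_heights[length(q_heights)])
  ids <- rownames(H)
  keep <- ids != exclude_id
  ord <- order(-sims, adiff, ids)
  ord <- ord[keep[ord]]
  ids[ord[seq_len(k)]]
}
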