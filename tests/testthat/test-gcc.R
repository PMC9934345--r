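# Growth Curve Comparison: cosine retrieval, increment-sum forecasting and
# empirical confidence-interval calibration.

test_that("cosine similarity matches hand-computed values and errors", {
  expect_equal(cosine_similarity(c(140, 146, 151), c(140, 146, 151)), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(3, 4), c(4, 3)), 24 / 25)
  expect_error(cosine_similarity(c(0, 0), c(1, 2)), class = "gc_zero_norm")
  expect_error(cosine_similarity(1:3, 1:2))
})

test_that("a member identical to the query ranks first with similarity 1", {
  M <- random_stratum(60, seed = 4)
  co <- cohort_from_matrices(male = M)
  q <- make_aligned("query", "M", M["r0007", ])
  ns <- find_neighbors(q, co, upto_age = 13, gcc_config(k_neighbors = 10))
  expect_equal(ns$neighbor_ids[1], "r0007")
  expect_equal(ns$similarities[1], 1.0, tolerance = 1e-12)
  expect_true(all(diff(ns$similarities) <= 1e-12))
  expect_false(ns$query_id %in% ns$neighbor_ids)
})

test_that("a cohort of exactly k members is returned whole, ranked", {
  M <- random_stratum(15, seed = 9)
  co <- cohort_from_matrices(male = M)
  q <- make_aligned("query", "M", M[1, ] + 2)
  ns <- find_neighbors(q, co, 12, gcc_config(k_neighbors = 15))
  expect_setequal(ns$neighbor_ids, rownames(M))
  expect_true(all(diff(ns$similarities) <= 1e-12))
  # one member short of k: error by default, degrade when configured
  expect_error(find_neighbors(q, co, 12, gcc_config(k_neighbors = 16)),
               class = "gc_insufficient_cohort")
  ns2 <- find_neighbors(q, co, 12, gcc_config(k_neighbors = 16,
                                              on_insufficient = "all"))
  expect_length(ns2$neighbor_ids, 15L)
})

test_that("retrieval equals the exhaustive-sort oracle (both bases)", {
  for (seed in 1:8) {
    n <- withr::with_seed(seed, sample(25:120, 1))
    M <- random_stratum(n, seed = 100 + seed)
    co <- cohort_from_matrices(female = M)
    upto <- withr::with_seed(seed + 50, sample(10:17, 1))
    win <- 8:upto
    q_heights <- M[3, seq_along(win)] * 1.01
    q <- make_aligned("probe", "F", q_heights, win)
    k <- min(n - 1L, 30L)
    for (basis in c("heights", "increments")) {
      ns <- find_neighbors(q, co, upto,
                           gcc_config(k_neighbors = k,
                                      similarity_basis = basis))
      expect_identical(ns$neighbor_ids,
                       oracle_neighbors(M, q_heights, win, k, "probe",
                                        basis = basis))
    }
  }
})

test_that("tie-breaking prefers the closer anchor height, then the id", {
  base <- seq(130, 180, 5)
  # za/zb are byte-identical curves: similarity and anchor distance tie
  # exactly, so the id decides; zc is visibly less similar and ranks last
  M <- rbind(zb = base * 1.04, za = base * 1.04,
             zc = base + c(12, rep(0, 10)))
  colnames(M) <- 8:18
  co <- cohort_from_matrices(male = M)
  q <- make_aligned("q", "M", base)
  ns <- find_neighbors(q, co, 17, gcc_config(k_neighbors = 3))
  expect_equal(ns$neighbor_ids, c("za", "zb", "zc"))

  # increments basis: identical growth vectors at different absolute heights
  # are an exact similarity tie, resolved by the smaller anchor difference
  M2 <- rbind(far = base + 10, near = base + 2,
              off = base + c(0, 6, rep(0, 9)))
  colnames(M2) <- 8:18
  co2 <- cohort_from_matrices(male = M2)
  ns2 <- find_neighbors(q, co2, 17,
                        gcc_config(k_neighbors = 3,
                                   similarity_basis = "increments"))
  expect_equal(ns2$neighbor_ids[1:2], c("near", "far"))
})

test_that("forecast sums the neighbours' mean increments from the anchor", {
  # neighbours with tabulated increments after age 15
  filler <- seq(120, 155, 5)  # ages 8..15
  M <- rbind(n1 = c(filler, 173, 175, 176),
             n2 = c(filler, 172, 174, 175),
             n3 = c(filler, 174, 175, 175.5))
  colnames(M) <- 8:18
  co <- cohort_from_matrices(female = M)
  q <- make_aligned("q", "F", c(150, 160, 171), ages = c(13, 14, 15))
  ns <- find_neighbors(q, co, 15, gcc_config(k_neighbors = 3))
  fc <- forecast_heights(q, ns, co, 15)
  # hand-summed cumulative mean increments on the anchor 171:
  #   16: (18+17+19)/3 - 155 ... increments from 155: (18,17,19) -> mean 18
  #   17: (2+2+1)/3 = 5/3 ; 18: (1+1+0.5)/3 = 5/6
  expect_equal(unname(fc$predictions),
               c(171 + 18, 171 + 18 + 5 / 3, 171 + 18 + 5 / 3 + 5 / 6),
               tolerance = 1e-12)
  expect_equal(as.integer(names(fc$predictions)), 16:18)
})

test_that("constant and zero neighbour growth give the closed-form forecast", {
  ages <- 8:18
  grow5 <- function(h13) h13 + (ages - 13) * 5
  M <- rbind(a = grow5(148), b = grow5(152), c = grow5(155))
  colnames(M) <- ages
  co <- cohort_from_matrices(male = M)
  q <- make_aligned("q", "M", c(145, 150), ages = c(12, 13))
  ns <- find_neighbors(q, co, 13, gcc_config(k_neighbors = 3))
  fc <- forecast_heights(q, ns, co, 13)
  expect_equal(unname(fc$predictions[["18"]]), 150 + 5 * 5)
  expect_true(all(diff(fc$predictions) > 0))

  Mz <- M; Mz[, 7:11] <- Mz[, 6]  # flat after age 13
  coz <- cohort_from_matrices(male = Mz)
  nsz <- find_neighbors(q, coz, 13, gcc_config(k_neighbors = 3))
  fcz <- forecast_heights(q, nsz, coz, 13)
  expect_equal(unname(fcz$predictions), rep(150, 5))
})

test_that("translating the query moves the forecast rigidly (fixed neighbours)", {
  M <- random_stratum(20, seed = 12)
  co <- cohort_from_matrices(male = M)
  q1 <- make_aligned("q", "M", c(140, 147, 153), ages = 10:12)
  q2 <- make_aligned("q", "M", c(140, 147, 153) + 7, ages = 10:12)
  cfg <- gcc_config(k_neighbors = 20)  # whole cohort: neighbour set fixed
  f1 <- forecast_heights(q1, find_neighbors(q1, co, 12, cfg), co, 12)
  f2 <- forecast_heights(q2, find_neighbors(q2, co, 12, cfg), co, 12)
  expect_equal(unname(f2$predictions - f1$predictions), rep(7, 6),
               tolerance = 1e-12)
})

test_that("forecasting without an observed anchor height errors", {
  M <- random_stratum(10, seed = 3)
  co <- cohort_from_matrices(male = M)
  q <- make_aligned("q", "M", c(140, 147), ages = c(10, 11))
  ns <- find_neighbors(q, co, 11, gcc_config(k_neighbors = 5))
  expect_error(forecast_heights(q, ns, co, 12), class = "gc_missing_anchor")
})

test_that("CI calibration: clones give zero width; 2-member case is exact", {
  base <- c(seq(120, 165, 5), 168)
  M <- do.call(rbind, lapply(1:8, function(i) base))
  rownames(M) <- paste0("k", 1:8); colnames(M) <- 8:18
  ci <- calibrate_ci(cohort_from_matrices(male = M),
                     gcc_config(k_neighbors = 5), last_ages = c(12, 15),
                     sexes = "male")
  expect_true(all(abs(ci$ci_half_width_cm) < 1e-9))

  # two members identical through 17, adult heights 2 cm above/below the
  # neighbour's increment path: leave-one-out residuals are {-2, +2}
  shared <- seq(125, 170, 5)  # ages 8..17
  M2 <- rbind(p = c(shared, 171), q = c(shared, 173))
  colnames(M2) <- 8:18
  ci2 <- calibrate_ci(cohort_from_matrices(female = M2),
                      gcc_config(k_neighbors = 1), last_ages = 17,
                      sexes = "female")
  expect_equal(ci2$ci_half_width_cm, 2 * sd(c(-2, 2)), tolerance = 1e-12)
})

test_that("CI half-widths grow with the forecast horizon on smooth cohorts", {
  sc <- sim_cohort(150, seed = 21)
  ci <- calibrate_ci(sc$cohort, gcc_config(k_neighbors = 50),
                     last_ages = c(10, 13, 16))
  for (sex in c("male", "female")) {
    for (B in c(10, 13, 16)) {
      hw <- ci$ci_half_width_cm[ci$sex == sex & ci$last_age == B]
      expect_lt(hw[1], hw[length(hw)])  # C = B+1 narrower than C = 18
    }
  }
})
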