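# Parametric growth-curve simulator: school-cohort-like longitudinal height
# data with analytic ground truth (true adult height, true PHV age).
#
# Functional form: childhood linear trend plus a logistic pubertal spurt,
#   h(t) = h8 + c (t - 8) + A [s(t) - s(8)],   s(t) = 1 / (1 + e^{-b (t - tp)})
# with c the childhood velocity (cm/yr), A the spurt amplitude (cm), b the
# spurt tempo (1/yr) and tp the spurt centre.  The velocity
#   h'(t) = c + A b s(t) (1 - s(t))
# is maximal exactly at t = tp, so the true PHV age is analytic; h' > 0
# everywhere, so the noise-free curve is strictly increasing.

#' Simulation parameters
#'
#' Defaults emulate a national school-cohort measurement programme: annual
#' April measurements of children followed from about age 7 to 18,
#' sex-specific adult-height distributions, heterogeneous pubertal timing
#' (girls' PHV mostly between ages 10 and 12, boys' between 11 and 14) and
#' stadiometer-scale measurement noise.
#'
#' @param n_per_sex Children per sex.
#' @param seed Integer seed (all randomness flows from it).
#' @param adult_height_mean,adult_height_sd Named (`male`, `female`) adult
#'   height distributions, cm.
#' @param phv_age_mean,phv_age_sd,phv_age_range PHV-age truncated-normal
#'   parameters per sex, years.
#' @param childhood_velocity_range Uniform range of the baseline (non-spurt)
#'   linear growth velocity, cm/yr; a named per-sex list or a single range
#'   shared by both sexes.  Defaults keep the 8-to-18 total height gain and
#'   the age-8 height distribution realistic for each sex.
#' @param phv_intensity_range Named list of uniform ranges for the pubertal
#'   spurt amplitude per sex, cm.
#' @param tempo_range Uniform range of the logistic tempo parameter, 1/yr.
#' @param measurement_noise_sd Gaussian measurement noise, cm (default 0.5).
#' @param missing_rate Probability that any single measurement is missing.
#' @param measurement_jitter_days Half-range of the uniform jitter around the
#'   April 15 measurement date, days.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_per_sex = 500L,
                       seed = 1L,
                       adult_height_mean = c(male = 180, female = 167),
                       adult_height_sd = c(male = 6.8, female = 6.2),
                       phv_age_mean = c(male = 12.5, female = 11),
                       phv_age_sd = c(male = 1.0, female = 1.0),
                       phv_age_range = list(male = c(9.5, 16),
                                            female = c(8.5, 14.5)),
                       childhood_velocity_range = list(male = c(3.4, 4.4),
                                                       female = c(2.3, 3.3)),
                       phv_intensity_range = list(male = c(10, 16),
                                                  female = c(8, 14)),
                       tempo_range = c(1.2, 1.8),
                       measurement_noise_sd = 0.5,
                       missing_rate = 0,
                       measurement_jitter_days = 10L) {
  stopifnot(n_per_sex >= 0, measurement_noise_sd >= 0,
            all(adult_height_sd >= 0), all(phv_age_sd >= 0),
            missing_rate >= 0, missing_rate < 1)
  structure(as.list(environment()), class = "sim_params")
}

# Truncated-normal draw by rejection (ranges are wide; acceptance is high).
rtruncnorm1 <- function(mean, sd, range, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    x <- rnorm(1, mean, sd)
    if (x >= range[1] && x <= range[2]) return(x)
  }
  stop_gc("failed to draw a parameter within physiological bounds after ",
          max_tries, " attempts", class = "gc_sim_error")
}

# Noise-free height at decimal age t for one parameter draw.
growth_curve <- function(t, par) {
  s <- plogis(par$tempo * (t - par$phv_age))
  s8 <- plogis(par$tempo * (AGE_MIN - par$phv_age))
  par$h8 + par$velocity * (t - AGE_MIN) + par$amplitude * (s - s8)
}

#' Simulate one child's measurement record
#'
#' Draws individual growth parameters (adult height, PHV age, childhood
#' velocity, spurt amplitude and tempo), constructs the smooth height
#' function above, and samples April-dated measurements from about age 7 to
#' 18 with Gaussian noise.  Consumes the current RNG state (seed it via
#' [simulate_cohort()] or `withr::with_seed()`).
#'
#' @param params A [sim_params()] list.
#' @param sex `"male"` or `"female"`.
#' @param child_id Identifier for the generated child.
#' @param birth_year Calendar year of birth.
#' @return A list with `series` (a [height_series()]) and `truth` (a one-row
#'   data.frame: `child_id`, `sex`, `true_adult_height_cm`, `true_phv_age`,
#'   and the drawn curve parameters).
#' @export
simulate_child <- function(params, sex, child_id, birth_year = 2000L) {
  sex <- normalize_sex(sex)
  for (attempt in seq_len(100L)) {
    target18 <- rnorm(1, params$adult_height_mean[[sex]],
                      params$adult_height_sd[[sex]])
    tp <- rtruncnorm1(params$phv_age_mean[[sex]], params$phv_age_sd[[sex]],
                      params$phv_age_range[[sex]])
    vrange <- if (is.list(params$childhood_velocity_range))
      params$childhood_velocity_range[[sex]] else
        params$childhood_velocity_range
    vel <- runif(1, vrange[1], vrange[2])
    amp <- runif(1, params$phv_intensity_range[[sex]][1],
                 params$phv_intensity_range[[sex]][2])
    tmp <- runif(1, params$tempo_range[1], params$tempo_range[2])
    s18 <- plogis(tmp * (AGE_MAX - tp)); s8 <- plogis(tmp * (AGE_MIN - tp))
    h8 <- target18 - vel * (AGE_MAX - AGE_MIN) - amp * (s18 - s8)
    if (h8 > 100 && h8 < 150) break
    if (attempt == 100L)
      stop_gc("no physiologically plausible parameter draw in 100 attempts",
              class = "gc_sim_error")
  }
  par <- list(h8 = h8, velocity = vel, amplitude = amp, tempo = tmp,
              phv_age = tp)
  birth <- as.Date(sprintf("%d-01-01", birth_year)) +
    floor(runif(1, 0, 365))
  jit <- params$measurement_jitter_days
  years <- (birth_year + 7L):(birth_year + 19L)
  mdates <- as.Date(sprintf("%d-04-15", years)) +
    round(runif(length(years), -jit, jit))
  ages <- age_at_date(birth, mdates)
  keep <- ages >= 7 & ages < 19
  if (params$missing_rate > 0)
    keep <- keep & (runif(length(ages)) >= params$missing_rate)
  mdates <- mdates[keep]; ages <- ages[keep]
  hts <- growth_curve(ages, par) +
    rnorm(length(ages), 0, params$measurement_noise_sd)
  series <- height_series(child_id, sex, birth, mdates, hts)
  truth <- data.frame(child_id = child_id, sex = sex,
                      true_adult_height_cm = growth_curve(AGE_MAX, par),
                      true_phv_age = tp,
                      h8 = h8, velocity = vel, amplitude = amp,
                      tempo = tmp)
  list(series = series, truth = truth)
}

#' Simulate a full two-sex cohort
#'
#' Generates `n_per_sex` children per sex under `params`, deterministically
#' from `params$seed`.  Optionally writes the cohort CSV (canonical long
#' format), the truth table and the full parameter provenance to a directory.
#'
#' @param params A [sim_params()] list.
#' @param dir Optional output directory; when given, writes `cohort.csv`,
#'   `truth.csv` and `params.yaml`.
#' @return A list with `cohort` (list of `height_series`) and `truth`
#'   (data.frame `child_id, sex, true_adult_height_cm, true_phv_age, ...`).
#' @export
simulate_cohort <- function(params, dir = NULL) {
  stopifnot(inherits(params, "sim_params"))
  gen <- function() {
    out <- vector("list", 2L * params$n_per_sex)
    k <- 0L
    for (sex in c("male", "female")) {
      for (i in seq_len(params$n_per_sex)) {
        k <- k + 1L
        id <- sprintf("%s%05d", if (sex == "male") "b" else "g", i)
        out[[k]] <- simulate_child(params, sex, id,
                                   birth_year = 2000L + (i %% 5L))
      }
    }
    out
  }
  children <- withr::with_seed(as.integer(params$seed), gen())
  cohort <- lapply(children, `[[`, "series")
  truth <- do.call(rbind, lapply(children, `[[`, "truth"))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(dir, "cohort.csv"))
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE,
                     quote = FALSE)
    yaml::write_yaml(lapply(unclass(params), function(x)
      if (is.numeric(x)) as.numeric(x) else x),
      file.path(dir, "params.yaml"))
  }
  list(cohort = cohort, truth = truth)
}
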