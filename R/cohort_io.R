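# Longitudinal height records: validation, CSV IO, and birthday alignment.
#
# The canonical exchange format is a long CSV with columns
#   child_id, sex, birth_date, measurement_date, height_cm
# (ISO-8601 dates, UTF-8, header required).  Column names can be overridden
# through a dialect list, optionally loaded from a YAML file.

#' Construct a single child's height record
#'
#' A `height_series` holds one child's sex, birth date and dated height
#' measurements — the raw input to birthday alignment.  Measurement dates must
#' be strictly increasing and lie after the birth date; heights must be
#' positive and below 250 cm.
#'
#' @param child_id Character scalar identifier.
#' @param sex `"male"` or `"female"` (abbreviations `M`/`F`/`boy`/`girl`
#'   accepted, case-insensitive).
#' @param birth_date A `Date` (or ISO-8601 string).
#' @param dates Measurement dates (`Date` or ISO-8601 strings).
#' @param heights_cm Heights in centimetres, one per date.
#' @return An object of class `height_series`.
#' @examples
#' hs <- height_series("c1", "F", "2002-03-01",
#'                     c("2010-04-15", "2011-04-15"), c(138.2, 144.0))
#' hs
#' @export
height_series <- function(child_id, sex, birth_date, dates, heights_cm) {
  child_id <- as.character(child_id)
  stopifnot(length(child_id) == 1L, nzchar(child_id))
  sex <- normalize_sex(sex)
  birth_date <- as.Date(birth_date)
  dates <- as.Date(dates)
  heights_cm <- as.numeric(heights_cm)
  if (length(dates) != length(heights_cm))
    stop("dates and heights_cm must have equal length", call. = FALSE)
  if (length(dates) < 1L)
    stop_gc("child ", child_id, ": at least one measurement required",
            class = "gc_insufficient_data")
  o <- order(dates)
  dates <- dates[o]; heights_cm <- heights_cm[o]
  if (anyDuplicated(dates))
    stop("child ", child_id, ": duplicate measurement dates", call. = FALSE)
  if (any(dates <= birth_date))
    stop("child ", child_id, ": measurement date on or before birth date",
         call. = FALSE)
  if (any(!is.finite(heights_cm)) || any(heights_cm <= 0) ||
      any(heights_cm >= 250))
    stop("child ", child_id, ": heights must be in (0, 250) cm",
         call. = FALSE)
  structure(
    list(child_id = child_id, sex = sex, birth_date = birth_date,
         measurements = data.frame(date = dates, height_cm = heights_cm)),
    class = "height_series"
  )
}

#' @export
print.height_series <- function(x, ...) {
  cat(sprintf("<height_series> %s (%s), born %s, %d measurement(s)\n",
              x$child_id, x$sex, format(x$birth_date),
              nrow(x$measurements)))
  invisible(x)
}

default_dialect <- function() {
  list(child_id = "child_id", sex = "sex", birth_date = "birth_date",
       measurement_date = "measurement_date", height_cm = "height_cm")
}

#' Read a longitudinal height cohort from CSV
#'
#' Parses a long-format CSV (one row per measurement) into a list of
#' [height_series()].  Rows are grouped by child and date-sorted.  Malformed
#' rows (unparseable dates or heights, duplicate child/date pairs) are
#' collected and reported together with their line numbers.
#'
#' @param path Path to the CSV file.
#' @param dialect Optional named list overriding the default column names
#'   (`child_id`, `sex`, `birth_date`, `measurement_date`, `height_cm`), or a
#'   path to a YAML file containing such a list.
#' @return A list of `height_series`, one per child.
#' @export
read_cohort <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(dialect) && length(dialect) == 1L)
    dialect <- yaml::read_yaml(dialect)
  dia <- utils::modifyList(default_dialect(), as.list(dialect %||% list()))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- unlist(dia, use.names = FALSE)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop_gc("missing column(s): ", paste(missing_cols, collapse = ", "),
            class = "gc_schema_error")
  n <- nrow(raw)
  line <- seq_len(n) + 1L  # header is line 1
  probs <- character(0)
  bd <- as.Date(raw[[dia$birth_date]], optional = TRUE)
  md <- as.Date(raw[[dia$measurement_date]], optional = TRUE)
  ht <- suppressWarnings(as.numeric(raw[[dia$height_cm]]))
  bad <- is.na(bd)
  if (any(bad)) probs <- c(probs, sprintf(
    "line %d: unparseable birth_date '%s'", line[bad],
    raw[[dia$birth_date]][bad]))
  bad <- is.na(md)
  if (any(bad)) probs <- c(probs, sprintf(
    "line %d: unparseable measurement_date '%s'", line[bad],
    raw[[dia$measurement_date]][bad]))
  bad <- is.na(ht)
  if (any(bad)) probs <- c(probs, sprintf(
    "line %d: unparseable height '%s'", line[bad], raw[[dia$height_cm]][bad]))
  key <- paste(raw[[dia$child_id]], raw[[dia$measurement_date]])
  dup <- duplicated(key)
  if (any(dup)) probs <- c(probs, sprintf(
    "line %d: duplicate (child_id, measurement_date) pair", line[dup]))
  if (length(probs))
    stop_gc("malformed rows in ", path, ":\n  ",
            paste(probs, collapse = "\n  "), class = "gc_row_error")
  sex <- normalize_sex(raw[[dia$sex]])
  ids <- raw[[dia$child_id]]
  out <- lapply(split(seq_len(n), ids), function(i) {
    if (length(unique(sex[i])) > 1L || length(unique(bd[i])) > 1L)
      stop("child ", ids[i[1]], ": inconsistent sex or birth_date across rows",
           call. = FALSE)
    height_series(ids[i[1]], sex[i[1]], bd[i[1]], md[i], ht[i])
  })
  out[order(names(out))]
}

#' Write a cohort back to canonical long CSV
#'
#' @param cohort A list of `height_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  rows <- do.call(rbind, lapply(cohort, function(hs) {
    data.frame(child_id = hs$child_id, sex = hs$sex,
               birth_date = format(hs$birth_date),
               measurement_date = format(hs$measurements$date),
               height_cm = hs$measurements$height_cm)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Interpolate dated measurements to heights at integer-age birthdays
#'
#' For each integer age in 8..18 whose birthday lies within the measured date
#' range, the height at the birthday is obtained by linear interpolation in
#' time between the two bracketing measurements (a birthday exactly on a
#' measurement date takes the measured height).  Birthdays outside the
#' measured range are absent — no extrapolation.  Ages outside 8..18 are
#' dropped.
#'
#' @param series A [height_series()] with at least two measurements.
#' @param decrease_tol_cm Height decreases between consecutive aligned ages
#'   larger than this (default 1 cm) trigger a warning (measurement noise is
#'   tolerated, gross errors flagged); the series is never rejected.
#' @return An `aligned_series`: list with `child_id`, `sex`, `ages` (integer)
#'   and `heights` (cm at each birthday).
#' @export
interpolate_to_birthdays <- function(series, decrease_tol_cm = 1) {
  stopifnot(inherits(series, "height_series"))
  m <- series$measurements
  if (nrow(m) < 2L)
    stop_gc("child ", series$child_id,
            ": at least two measurements are required for alignment",
            class = "gc_insufficient_data")
  bdays <- birthday_at_age(series$birth_date, ALL_AGES)
  got <- approx(x = as.numeric(m$date), y = m$height_cm,
                xout = as.numeric(bdays), method = "linear",
                rule = 1, ties = "ordered")$y
  keep <- !is.na(got)
  if (!any(keep))
    stop_gc("child ", series$child_id,
            ": no birthday at ages 8..18 falls within the measured date range",
            class = "gc_empty_output")
  aligned_series(series$child_id, series$sex,
                 ALL_AGES[keep], got[keep],
                 decrease_tol_cm = decrease_tol_cm)
}

#' Construct an age-aligned growth curve
#'
#' Usually produced by [interpolate_to_birthdays()]; exported for building
#' fixtures and for data already recorded at exact ages.
#'
#' @param child_id,sex Identifier and sex as in [height_series()].
#' @param ages Strictly increasing integer ages within 8..18.
#' @param heights_cm Heights (cm) at each age.
#' @param decrease_tol_cm Warn on decreases larger than this (cm).
#' @return An object of class `aligned_series`.
#' @export
aligned_series <- function(child_id, sex, ages, heights_cm,
                           decrease_tol_cm = 1) {
  ages <- as.integer(ages)
  heights_cm <- as.numeric(heights_cm)
  stopifnot(length(ages) == length(heights_cm), length(ages) >= 1L)
  if (is.unsorted(ages, strictly = TRUE))
    stop("ages must be strictly increasing", call. = FALSE)
  if (any(ages < AGE_MIN) || any(ages > AGE_MAX)) {
    warning("dropping ages outside 8..18 for child ", child_id)
    keep <- ages >= AGE_MIN & ages <= AGE_MAX
    ages <- ages[keep]; heights_cm <- heights_cm[keep]
  }
  decr <- diff(heights_cm)
  flag <- any(decr < -decrease_tol_cm)
  if (flag)
    warning("child ", child_id, ": height decrease exceeding ",
            decrease_tol_cm, " cm between consecutive ages", call. = FALSE)
  structure(
    list(child_id = as.character(child_id), sex = normalize_sex(sex),
         ages = ages, heights = heights_cm, decrease_flag = flag),
    class = "aligned_series"
  )
}

#' @export
print.aligned_series <- function(x, ...) {
  cat(sprintf("<aligned_series> %s (%s): ages %s\n", x$child_id, x$sex,
              paste(x$ages, collapse = ",")))
  print(setNames(round(x$heights, 2), x$ages))
  invisible(x)
}

#' Align every child of a cohort to birthdays
#'
#' Convenience wrapper applying [interpolate_to_birthdays()] to a list of
#' height series; children that cannot be aligned (fewer than two
#' measurements, or no bracketed birthday) are dropped with a message.
#'
#' @inheritParams write_cohort
#' @param decrease_tol_cm Passed to [interpolate_to_birthdays()].
#' @return A list of `aligned_series`.
#' @export
align_cohort <- function(cohort, decrease_tol_cm = 1) {
  out <- vector("list", length(cohort))
  dropped <- 0L
  for (i in seq_along(cohort)) {
    res <- tryCatch(
      interpolate_to_birthdays(cohort[[i]], decrease_tol_cm),
      growthcast_error = function(e) NULL)
    if (is.null(res)) dropped <- dropped + 1L else out[[i]] <- res
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (dropped > 0L)
    message(dropped, " series could not be aligned and were dropped")
  out
}

#' Assemble the complete-curve reference library
#'
#' Retains only children with heights at every age 8..18 (the complete-curve
#' subset all forecasting methods are fitted on) and partitions them by sex.
#' Internally each sex stratum is a children-by-ages matrix for fast
#' similarity retrieval.
#'
#' @param aligned A list of `aligned_series`.
#' @return An object of class `reference_cohort` with elements `ages` (8:18)
#'   and `heights`, a list of matrices (`male`, `female`; rownames are child
#'   ids, columns ages 8..18).
#' @export
build_reference_cohort <- function(aligned) {
  complete <- vapply(aligned, function(a) length(a$ages) == length(ALL_AGES),
                     logical(1))
  kept <- aligned[complete]
  message(sprintf("reference cohort: %d complete series retained, %d dropped",
                  length(kept), sum(!complete)))
  if (!length(kept))
    stop_gc("no complete age-8..18 series to build a reference cohort from",
            class = "gc_cohort_error")
  ids <- vapply(kept, `[[`, character(1), "child_id")
  if (anyDuplicated(ids))
    stop_gc("duplicate child_id in reference cohort: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "),
            class = "gc_cohort_error")
  sexes <- vapply(kept, `[[`, character(1), "sex")
  heights <- lapply(c(male = "male", female = "female"), function(s) {
    sel <- kept[sexes == s]
    if (!length(sel))
      return(matrix(numeric(0), nrow = 0, ncol = length(ALL_AGES),
                    dimnames = list(NULL, ALL_AGES)))
    m <- do.call(rbind, lapply(sel, `[[`, "heights"))
    dimnames(m) <- list(vapply(sel, `[[`, character(1), "child_id"), ALL_AGES)
    m[order(rownames(m)), , drop = FALSE]
  })
  structure(list(ages = ALL_AGES, heights = heights),
            class = "reference_cohort")
}

#' @export
print.reference_cohort <- function(x, ...) {
  cat(sprintf("<reference_cohort> %d boys, %d girls, ages 8-18\n",
              nrow(x$heights$male), nrow(x$heights$female)))
  invisible(x)
}

#' Extract one sex stratum of a reference cohort
#'
#' @param cohort A `reference_cohort`.
#' @param sex `"male"` or `"female"`.
#' @return The children-by-ages height matrix for that sex.
#' @export
cohort_stratum <- function(cohort, sex) {
  stopifnot(inherits(cohort, "reference_cohort"))
  sex <- normalize_sex(sex)
  m <- cohort$heights[[sex]]
  if (nrow(m) == 0L)
    stop_gc("reference cohort has no ", sex, " members",
            class = "gc_cohort_error")
  m
}

#' Write aligned series to CSV (`child_id,sex,age,height_cm`)
#'
#' @param aligned List of `aligned_series`.
#' @param path Output path.
#' @export
write_aligned_cohort <- function(aligned, path) {
  rows <- do.call(rbind, lapply(aligned, function(a) {
    data.frame(child_id = a$child_id, sex = a$sex, age = a$ages,
               height_cm = a$heights)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
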