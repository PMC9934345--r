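# Internal helpers shared across modules.

AGE_MIN <- 8L
AGE_MAX <- 18L
ALL_AGES <- 8:18

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalise a sex label to "male"/"female"
#' @noRd
normalize_sex <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- c(
    m = "male", male = "male", boy = "male", b = "male",
    f = "female", female = "female", girl = "female", g = "female"
  )[key]
  out <- unname(out)
  if (anyNA(out)) {
    bad <- unique(key[is.na(out)])
    stop("unrecognised sex value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

# Calendar birthday at integer age `a`: same month/day as birth, `a` years on.
# Feb 29 birthdays fall back to Feb 28 in non-leap years.
birthday_at_age <- function(birth_date, age) {
  stopifnot(inherits(birth_date, "Date"))
  y <- as.integer(format(birth_date, "%Y")) + as.integer(age)
  md <- format(birth_date, "%m-%d")
  out <- as.Date(paste0(y, "-", md))
  feb29 <- which(is.na(out) & md == "02-29")
  if (length(feb29)) out[feb29] <- as.Date(paste0(y[feb29], "-02-28"))
  out
}

# Decimal age at a date, in years.
age_at_date <- function(birth_date, date) {
  as.numeric(date - birth_date) / 365.2425
}

stop_gc <- function(..., class) {
  stop(structure(
    class = c(class, "growthcast_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
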