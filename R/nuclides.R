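#' Registered radiocesium nuclides
#'
#' The two gamma-emitting cesium isotopes followed by the survey, with the
#' half-lives used for every decay correction in the package.  The values are
#' standard nuclear data: 2.0652 y for Cs-134 and 30.08 y for Cs-137.  Their
#' adequacy is validated end-to-end by the bundled reference tables: forward
#' decay correction of worn-date activities reproduces the published
#' 2011-03-11 activities to the printed precision.
#'
#' @param cs134_years,cs137_years Override half-lives (years).
#' @return A tibble with columns `nuclide` and `half_life_years`.
#' @examples
#' nuclide_table()
#' @export
nuclide_table <- function(cs134_years = 2.0652, cs137_years = 30.08) {
  stopifnot(cs134_years > 0, cs137_years > 0)
  tibble(
    nuclide = c("cs134", "cs137"),
    half_life_years = c(cs134_years, cs137_years)
  )
}

#' @rdname nuclide_table
#' @param nuclide Character vector, `"cs134"` or `"cs137"`.
#' @param nuclides Nuclide registry, as from [nuclide_table()].
#' @export
half_life_years <- function(nuclide, nuclides = nuclide_table()) {
  idx <- match(nuclide, nuclides$nuclide)
  if (anyNA(idx)) {
    abort(paste0(
      "Unknown nuclide(s): ",
      paste(unique(nuclide[is.na(idx)]), collapse = ", ")
    ))
  }
  nuclides$half_life_years[idx]
}

as_survey_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  # accept ISO 8601 and the survey's YYYY/M/D dialect
  out <- as.Date(rep(NA_character_, length(x)))
  slash <- grepl("/", x, fixed = TRUE)
  out[slash] <- as.Date(x[slash], format = "%Y/%m/%d")
  out[!slash] <- as.Date(x[!slash], format = "%Y-%m-%d")
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    abort(paste0(
      "Unparseable date(s): ", paste(unique(x[bad]), collapse = ", "),
      " (expected YYYY-MM-DD or YYYY/M/D)"
    ))
  }
  out
}

#' Elapsed time between two calendar dates, in years
#'
#' Whole-day difference divided by 365.25.  The survey records dates only, so
#' no time-of-day resolution is attempted.  Signed: `to_date` earlier than
#' `from_date` gives a negative result.
#'
#' @param from_date,to_date Dates (`Date`, ISO strings, or the `YYYY/M/D`
#'   dialect used in the survey tables).
#' @return Numeric vector of years.
#' @examples
#' elapsed_years("2011-03-11", "2016-09-29")
#' @export
elapsed_years <- function(from_date, to_date) {
  from <- as_survey_date(from_date)
  to <- as_survey_date(to_date)
  as.numeric(to - from) / 365.25
}

#' Exponential decay factor between two dates
#'
#' `exp(-ln(2) * elapsed / half_life)`.  Equal dates give exactly 1; the
#' factor for the reverse interval is the exact reciprocal, so decay
#' corrections round-trip.  The half-life itself is treated as exact: its
#' relative uncertainty is negligible against counting uncertainty.
#'
#' @inheritParams elapsed_years
#' @inheritParams half_life_years
#' @return Positive numeric vector.
#' @examples
#' decay_factor("cs137", "2011-03-11", "2016-09-29")
#' @export
decay_factor <- function(nuclide, from_date, to_date, nuclides = nuclide_table()) {
  hl <- half_life_years(nuclide, nuclides)
  exp(-log(2) * elapsed_years(from_date, to_date) / hl)
}

#' Construct a table of activity measurements
#'
#' The package's canonical long form for date-referenced activities: one row
#' per measurement with a value, its 1-sigma counting uncertainty, the
#' nuclide, the reference date, and censoring state.  A censored row carries
#' the detection limit in `detection_limit` (and as `value`, so downstream
#' code treating it as an upper bound needs no special case); its `sigma` is
#' `NA`.
#'
#' @param value Activity in Bq (ignored for censored rows; may be `NA`).
#' @param sigma 1-sigma uncertainty in Bq.
#' @param nuclide `"cs134"` or `"cs137"`.
#' @param ref_date Reference date of each value.
#' @param censored Logical; below the detection limit?
#' @param detection_limit Bq; required where `censored` is `TRUE`.
#' @return A tibble with columns `value`, `sigma`, `nuclide`, `ref_date`,
#'   `censored`, `detection_limit`.
#' @examples
#' activity(1.01, 0.01, "cs137", "2016-09-29")
#' @export
activity <- function(value, sigma = 0, nuclide = "cs137", ref_date,
                     censored = FALSE, detection_limit = NA_real_) {
  half_life_years(nuclide) # validates the nuclide names
  out <- tibble(
    value = as.numeric(value),
    sigma = as.numeric(sigma),
    nuclide = nuclide,
    ref_date = as_survey_date(ref_date),
    censored = censored,
    detection_limit = as.numeric(detection_limit)
  )
  if (any(out$censored & is.na(out$detection_limit))) {
    abort("Censored activities must carry a detection limit.")
  }
  out$value[out$censored] <- out$detection_limit[out$censored]
  out$sigma[out$censored] <- NA_real_
  ok <- !out$censored
  if (any(out$value[ok] < 0, na.rm = TRUE) || any(out$sigma[ok] < 0, na.rm = TRUE)) {
    abort("Activity values and sigmas must be nonnegative.")
  }
  out
}

#' Decay-correct activities to a target date
#'
#' Scales `value`, `sigma` and `detection_limit` by the decay factor from
#' each row's `ref_date` to `target_date` and replaces `ref_date`.  Censored
#' rows keep their flag; their limit is scaled by the same factor.  The
#' operation is exactly invertible: correcting back to the original date
#' recovers the input to floating-point precision.
#'
#' @param x An activity table from [activity()].
#' @param target_date Date to correct to.
#' @inheritParams half_life_years
#' @return The corrected activity table.
#' @examples
#' a <- activity(1.01, 0.01, "cs137", "2016-09-29")
#' decay_correct(a, "2011-03-11")
#' @export
decay_correct <- function(x, target_date, nuclides = nuclide_table()) {
  target <- as_survey_date(target_date)
  f <- decay_factor(x$nuclide, x$ref_date, rep(target, length.out = nrow(x)),
                    nuclides = nuclides)
  x$value <- x$value * f
  x$sigma <- x$sigma * f
  x$detection_limit <- x$detection_limit * f
  x$ref_date <- rep(target, length.out = nrow(x))
  x
}

#' Cs-134/Cs-137 activity ratio at a common reference date
#'
#' Both activities are decay-corrected to `at_date` before the ratio is
#' formed; its uncertainty follows first-order quadrature,
#' `(sigma_R/R)^2 = (sigma_134/A134)^2 + (sigma_137/A137)^2`.  At a common
#' origin date the ratio attributes material to a reactor unit (roughly
#' 0.94, 1.08 and 1.05 for Units 1-3 at 2011-03-11).
#'
#' @param a134,a137 Activity tables ([activity()]) of equal length, for
#'   Cs-134 and Cs-137 respectively.
#' @param at_date Common reference date (default the accident date,
#'   2011-03-11).
#' @inheritParams half_life_years
#' @return A tibble with columns `value` and `sigma`.
#' @examples
#' r <- isotope_ratio(
#'   activity(0.193, 0.012, "cs134", "2016-09-29"),
#'   activity(1.01, 0.01, "cs137", "2016-09-29")
#' )
#' @export
isotope_ratio <- function(a134, a137, at_date = "2011-03-11",
                          nuclides = nuclide_table()) {
  if (any(a134$censored) || any(a137$censored)) {
    abort("Cannot form an isotope ratio from censored activities.")
  }
  if (!all(a134$nuclide == "cs134") || !all(a137$nuclide == "cs137")) {
    abort("isotope_ratio() expects a cs134 table and a cs137 table, in that order.")
  }
  a134 <- decay_correct(a134, at_date, nuclides)
  a137 <- decay_correct(a137, at_date, nuclides)
  if (any(a137$value == 0)) {
    abort("Undefined ratio: Cs-137 activity is zero.")
  }
  r <- a134$value / a137$value
  rel <- sqrt((a134$sigma / a134$value)^2 + (a137$sigma / a137$value)^2)
  tibble(value = r, sigma = r * rel)
}

#' Isotope ratios for a particle table
#'
#' Data-frame-first convenience over [isotope_ratio()]: takes a particle (or
#' mask) table in the package's wide schema and appends `ratio` and
#' `ratio_sigma` columns at a common reference date.  Rows with a censored
#' Cs-134 value get `NA` ratios rather than an error, since published tables
#' legitimately contain below-limit Cs-134 entries.
#'
#' @param data Tibble with columns `a134_bq`, `a134_sigma`, `a137_bq`,
#'   `a137_sigma`, a reference date column, and optionally `a134_censored`.
#' @param ref_date Name of the reference date column (default `"ref_date"`).
#' @inheritParams isotope_ratio
#' @return `data` with `ratio` and `ratio_sigma` appended.
#' @export
isotope_ratio_table <- function(data, at_date = "2011-03-11",
                                ref_date = "ref_date",
                                nuclides = nuclide_table()) {
  stopifnot(ref_date %in% names(data))
  cens <- if ("a134_censored" %in% names(data)) data$a134_censored else
    is.na(data$a134_bq)
  cens <- cens | is.na(data$a134_bq) | is.na(data$a137_bq)
  data$ratio <- NA_real_
  data$ratio_sigma <- NA_real_
  if (any(!cens)) {
    ok <- which(!cens)
    r <- isotope_ratio(
      activity(data$a134_bq[ok], data$a134_sigma[ok], "cs134", data[[ref_date]][ok]),
      activity(data$a137_bq[ok], data$a137_sigma[ok], "cs137", data[[ref_date]][ok]),
      at_date = at_date, nuclides = nuclides
    )
    data$ratio[ok] <- r$value
    data$ratio_sigma[ok] <- r$sigma
  }
  data
}
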