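# parse a (value, sigma) column pair where below-limit entries appear as
# "LDL" in the value cell and a dash in the sigma cell
parse_censored_pair <- function(value_chr, sigma_chr) {
  value_chr <- trimws(value_chr %||% character(0))
  sigma_chr <- trimws(sigma_chr %||% character(0))
  censored <- toupper(value_chr) == "LDL" |
    value_chr %in% c("–", "—", "-", "")
  censored[is.na(value_chr)] <- TRUE
  value <- suppressWarnings(as.numeric(value_chr))
  sigma <- suppressWarnings(as.numeric(sigma_chr))
  bad <- (!censored & is.na(value) & !is.na(value_chr)) |
    (!censored & is.na(sigma) & !is.na(sigma_chr) &
       !sigma_chr %in% c("–", "—", "-", ""))
  value[censored] <- NA_real_
  sigma[censored] <- NA_real_
  list(value = value, sigma = sigma, censored = censored, bad = bad)
}

read_raw_table <- function(path, required) {
  out <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE)
  missing <- setdiff(required, names(out))
  if (length(missing)) {
    abort(paste0("File ", path, " is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out
}

# carry through columns outside the canonical schema, type-guessed, so that
# write/read round-trips preserve whole tables
append_extra_cols <- function(out, raw) {
  extra <- setdiff(names(raw), names(out))
  extra <- setdiff(extra, grep("_censored$", names(raw), value = TRUE))
  if (length(extra)) {
    guessed <- suppressMessages(readr::type_convert(raw[extra]))
    for (nm in extra) out[[nm]] <- guessed[[nm]]
  }
  out
}

finish_rows <- function(data, bad, path, skip_bad_rows) {
  if (any(bad)) {
    msg <- paste0("Malformed row(s) ", paste(which(bad), collapse = ", "),
                  " in ", path)
    if (!skip_bad_rows) abort(paste0(msg, " (use skip_bad_rows = TRUE to drop them)"))
    warn(paste0(msg, "; dropped"))
    data <- data[!bad, ]
  }
  data
}

apply_nuclide_pair <- function(out, raw, prefix, bad) {
  p <- parse_censored_pair(raw[[paste0(prefix, "_bq")]],
                           raw[[paste0(prefix, "_sigma")]])
  cens_col <- paste0(prefix, "_censored")
  if (cens_col %in% names(raw)) {
    # explicit flag column (round-tripped files): the value cell then holds
    # the detection limit, not "LDL"
    flagged <- toupper(raw[[cens_col]]) %in% c("TRUE", "T", "1", "YES")
    p$censored <- p$censored | flagged
  }
  out[[paste0(prefix, "_bq")]] <- p$value
  out[[paste0(prefix, "_sigma")]] <- p$sigma
  out[[cens_col]] <- p$censored
  list(out = out, bad = bad | p$bad)
}

#' Read survey tables
#'
#' CSV readers for the package's tabular interchange schemas (UTF-8, header
#' row, `#` comment lines, `.` decimal, scientific notation accepted).
#' Below-detection-limit entries written as `LDL` with a dash sigma are
#' parsed into `NA` values with a `*_censored` flag; dates are accepted in
#' ISO-8601 or the survey's `YYYY/M/D` dialect and normalised to `Date`.
#' Malformed rows are collected and abort the read with their row numbers
#' unless `skip_bad_rows` is set, in which case they are dropped with a
#' warning.
#'
#' @param path CSV file path.
#' @param skip_bad_rows Drop malformed rows instead of aborting?
#' @return A validated tibble.
#' @name read_tables
NULL

#' @rdname read_tables
#' @export
read_particles <- function(path, skip_bad_rows = FALSE) {
  raw <- read_raw_table(path, c("particle_id", "a134_bq", "a134_sigma",
                                "a137_bq", "a137_sigma"))
  if (anyDuplicated(raw$particle_id)) {
    abort(paste0("Duplicate particle_id in ", path, ": ",
                 paste(unique(raw$particle_id[duplicated(raw$particle_id)]),
                       collapse = ", ")))
  }
  bad <- rep(FALSE, nrow(raw))
  out <- tibble(particle_id = raw$particle_id)
  for (opt in c("residence_id", "mask_id")) {
    if (opt %in% names(raw)) out[[opt]] <- raw[[opt]]
  }
  for (dcol in intersect(c("measurement_date", "worn_date"), names(raw))) {
    out[[dcol]] <- as_survey_date(raw[[dcol]])
  }
  if ("live_time_s" %in% names(raw)) {
    out$live_time_s <- suppressWarnings(as.numeric(gsub(",", "", raw$live_time_s)))
    bad <- bad | (is.na(out$live_time_s) & !is.na(raw$live_time_s))
  }
  r <- apply_nuclide_pair(out, raw, "a134", bad)
  r <- apply_nuclide_pair(r$out, raw, "a137", r$bad)
  out <- r$out
  if ("previously_reported" %in% names(raw)) {
    out$previously_reported <- toupper(raw$previously_reported) %in%
      c("TRUE", "T", "1", "YES")
  }
  out <- append_extra_cols(out, raw)
  out <- out[, c(intersect(names(raw), names(out)),
                 setdiff(names(out), names(raw)))]
  finish_rows(out, r$bad, path, skip_bad_rows)
}

#' @rdname read_tables
#' @export
read_masks <- function(path, skip_bad_rows = FALSE) {
  raw <- read_raw_table(path, c("mask_id", "a137_bq", "a137_sigma"))
  if (anyDuplicated(raw$mask_id)) {
    abort(paste0("Duplicate mask_id in ", path))
  }
  bad <- rep(FALSE, nrow(raw))
  out <- tibble(mask_id = raw$mask_id)
  for (opt in c("residence_id", "person_id", "mask_type")) {
    if (opt %in% names(raw)) out[[opt]] <- raw[[opt]]
  }
  if ("mask_type" %in% names(out)) {
    known <- c("single", "inner", "outer", "n95")
    bad <- bad | (!is.na(out$mask_type) & !tolower(out$mask_type) %in% known)
    out$mask_type <- tolower(out$mask_type)
  }
  if ("worn_date" %in% names(raw)) out$worn_date <- as_survey_date(raw$worn_date)
  if ("a134_bq" %in% names(raw)) {
    r <- apply_nuclide_pair(out, raw, "a134", bad)
    out <- r$out
    bad <- r$bad
  }
  r <- apply_nuclide_pair(out, raw, "a137", bad)
  out <- append_extra_cols(r$out, raw)
  out <- out[, c(intersect(names(raw), names(out)),
                 setdiff(names(out), names(raw)))]
  finish_rows(out, r$bad, path, skip_bad_rows)
}

#' @rdname read_tables
#' @export
read_pairs <- function(path, skip_bad_rows = FALSE) {
  raw <- read_raw_table(path, c("outer_mask_id", "inner_mask_id"))
  bad <- is.na(raw$outer_mask_id) | is.na(raw$inner_mask_id) |
    raw$outer_mask_id == raw$inner_mask_id
  finish_rows(tibble(outer_mask_id = raw$outer_mask_id,
                     inner_mask_id = raw$inner_mask_id),
              bad, path, skip_bad_rows)
}

#' @rdname read_tables
#' @export
read_residences <- function(path, skip_bad_rows = FALSE) {
  raw <- read_raw_table(path, c("residence_id", "distance_km"))
  out <- tibble(
    residence_id = raw$residence_id,
    distance_km = suppressWarnings(as.numeric(raw$distance_km))
  )
  if ("construction" %in% names(raw)) out$construction <- raw$construction
  bad <- is.na(out$distance_km) | out$distance_km <= 0
  finish_rows(out, bad, path, skip_bad_rows)
}

#' Read or write a survey directory
#'
#' A survey lives as four CSVs (`masks.csv`, `particles.csv`, `pairs.csv`,
#' `residences.csv`) plus, for synthetic surveys, the generator truth as
#' `truth.json`.  Every written file starts with comment lines embedding the
#' package version, the generating seed (where known) and a content hash, so
#' outputs are traceable; readers skip them.  Writing then reading a survey
#' reproduces the observable tables exactly.
#'
#' @param survey A `csmp_survey` (or any list with those tibbles).
#' @param dir Directory to write to / read from.
#' @return `write_survey()` returns `dir` invisibly; `read_survey()` returns
#'   a `csmp_survey` list.
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- tryCatch(survey$config$seed, error = function(e) NULL)
  for (nm in c("masks", "particles", "pairs", "residences")) {
    if (!is.null(survey[[nm]])) {
      write_stamped_csv(survey[[nm]], file.path(dir, paste0(nm, ".csv")), seed)
    }
  }
  if (!is.null(survey$truth)) {
    jsonlite::write_json(survey$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         Date = "ISO8601")
  }
  invisible(dir)
}

write_stamped_csv <- function(data, path, seed = NULL) {
  ver <- as.character(utils::packageVersion("csmpsurvey"))
  header <- c(
    paste0("# csmpsurvey v", ver),
    if (!is.null(seed)) paste0("# seed: ", seed),
    paste0("# content_hash: ", rlang::hash(data))
  )
  writeLines(header, path)
  readr::write_csv(data, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(dir) {
  pth <- function(f) file.path(dir, f)
  out <- list(
    masks = if (file.exists(pth("masks.csv"))) read_masks(pth("masks.csv")),
    particles = if (file.exists(pth("particles.csv"))) read_particles(pth("particles.csv")),
    pairs = if (file.exists(pth("pairs.csv"))) read_pairs(pth("pairs.csv")),
    residences = if (file.exists(pth("residences.csv"))) read_residences(pth("residences.csv")),
    truth = if (file.exists(pth("truth.json"))) jsonlite::read_json(pth("truth.json"), simplifyVector = TRUE)
  )
  structure(out, class = "csmp_survey")
}
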