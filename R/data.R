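#' Bundled reference survey tables
#'
#' Transcriptions of the published tables from the 2016-2020 mask-wearing
#' campaign at residences near the FDNPP, shipped as plain CSV under
#' `inst/extdata/` and parsed through the package's censoring-aware readers.
#'
#' * `reference_particles_worn()` — the 48 isolated CsMPs with Cs-134 and
#'   Cs-137 activities decay-corrected to the date each host mask was worn,
#'   plus residence, measurement date, live time and a flag for the four
#'   particles already known from the earlier pilot survey.  Three Cs-134
#'   entries are below the detection limit and come back censored.
#' * `reference_particles_2011()` — the 45 spherical particles with
#'   activities corrected to 2011-03-11 and the published volume and
#'   diameter estimates (the three amorphous particles of the most
#'   contaminated mask are excluded from sizing).
#' * `reference_pair_efficiencies()` — the 51 stacked-pair cases with
#'   significant collection efficiency: outer-mask Cs-137 activity and the
#'   published efficiency.
#' * `reference_particle_fractions()` — per particle, the worn date, the
#'   particle and host-mask activities at the worn date, and the published
#'   CsMP/mask Cs-137 percentage.
#'
#' @return A tibble (see above for the columns of each table).
#' @examples
#' reference_particles_worn()
#' @name reference_tables
NULL

ref_path <- function(file) {
  system.file("extdata", file, package = "csmpsurvey", mustWork = TRUE)
}

#' @rdname reference_tables
#' @export
reference_particles_worn <- function() {
  read_particles(ref_path("survey_particles_worn.csv"))
}

#' @rdname reference_tables
#' @export
reference_particles_2011 <- function() {
  read_particles(ref_path("survey_particles_2011.csv")) |>
    dplyr::mutate(ref_date = as.Date("2011-03-11"))
}

#' @rdname reference_tables
#' @export
reference_pair_efficiencies <- function() {
  readr::read_csv(ref_path("pair_efficiencies.csv"),
                  col_types = "cccidd", progress = FALSE)
}

#' @rdname reference_tables
#' @export
reference_particle_fractions <- function() {
  raw <- readr::read_csv(ref_path("particle_mask_fractions.csv"),
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  p <- parse_censored_pair(raw$p134_bq, raw$p134_sigma)
  tibble(
    particle_id = raw$particle_id,
    worn_date = as_survey_date(raw$worn_date),
    p134_bq = p$value,
    p134_sigma = p$sigma,
    p134_censored = p$censored,
    p137_bq = as.numeric(raw$p137_bq),
    p137_sigma = as.numeric(raw$p137_sigma),
    m134_bq = as.numeric(raw$m134_bq),
    m134_sigma = as.numeric(raw$m134_sigma),
    m137_bq = as.numeric(raw$m137_bq),
    m137_sigma = as.numeric(raw$m137_sigma),
    fraction_pct = as.numeric(raw$fraction_pct)
  )
}

#' Reconcile particle IDs between survey tables
#'
#' The published per-particle tables disagree on a handful of IDs (one
#' particle appears under two different host-mask numbers, and two blocks of
#' lettered IDs are swapped between tables).  This helper joins a worn-date
#' particle table to a target table by exact ID first, then pairs the
#' leftover rows by nearest worn-date Cs-137 activity — the same physical
#' quantity appears in both tables, so value matching resolves the typos —
#' and reports every non-identity assignment via a warning.
#'
#' @param worn Tibble with `particle_id` and `a137_bq` (worn-date basis),
#'   e.g. [reference_particles_worn()].
#' @param target Tibble with `particle_id` and a worn-date Cs-137 column
#'   (`p137_bq` or `a137_bq`), e.g. [reference_particle_fractions()].
#' @return `worn` with a `canonical_id` column holding the target table's ID
#'   for every row (`NA` where the target has no counterpart).
#' @export
match_particle_ids <- function(worn, target) {
  t137 <- target$p137_bq %||% target$a137_bq
  if (is.null(t137)) abort("target needs a p137_bq or a137_bq column.")
  worn$canonical_id <- ifelse(worn$particle_id %in% target$particle_id,
                              worn$particle_id, NA_character_)
  open_w <- which(is.na(worn$canonical_id))
  open_t <- which(!target$particle_id %in% worn$canonical_id &
                    !target$particle_id %in% worn$particle_id)
  if (length(open_w)) {
    for (i in open_w) {
      if (!length(open_t)) break
      j <- open_t[which.min(abs(t137[open_t] - worn$a137_bq[i]))]
      worn$canonical_id[i] <- target$particle_id[j]
      open_t <- setdiff(open_t, j)
    }
    moved <- worn$particle_id != worn$canonical_id & !is.na(worn$canonical_id)
    if (any(moved)) {
      warn(paste0(
        "ID conflicts resolved by activity matching: ",
        paste(worn$particle_id[moved], "->", worn$canonical_id[moved],
              collapse = ", ")
      ))
    }
  }
  worn
}
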