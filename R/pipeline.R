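run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the end-to-end survey analysis
#'
#' Ties the stages together on one survey (read from disk with
#' [read_survey()], generated by [generate_survey()], or assembled by hand):
#' particle sizing at 2011-03-11 with isotope ratios, CsMP/mask activity
#' fractions, particle accounting, pair collection efficiencies with their
#' summary, occurrence frequency by mask activity class, and — when
#' residence distances are available — the log-log distance regression.
#' The pipeline is deterministic: rerunning on the same survey reproduces
#' the same report.
#'
#' @param survey List with tibbles `particles` (canonical activity schema,
#'   worn-date basis) and optionally `masks`, `pairs`, `residences`.
#' @param model [size_model()] used for sizing.
#' @param at_date Reference date for sizing and isotope ratios.
#' @param class_edges Activity class edges for the frequency table.
#' @param output_dir Optional directory; when given, every result table is
#'   written as a stamped CSV plus a machine-readable `summary.json`.
#' @return A `csmp_report` list of result tibbles.
#' @export
run_pipeline <- function(survey, model = size_model(), at_date = "2011-03-11",
                         class_edges = c(0, 0.1, 1, 10, 100, 1000, Inf),
                         output_dir = NULL) {
  particles <- survey$particles
  if (is.null(particles)) abort("run_pipeline() needs a particles table.")
  date_col <- intersect(c("worn_date", "ref_date"), names(particles))[1]
  if (is.na(date_col)) abort("particles need a worn_date or ref_date column.")

  sized <- run_stage("sizing", {
    ok <- !isTRUE_vec(particles[["a137_censored"]] %||% FALSE)
    size_particles(particles[ok, ], model = model, at_date = at_date,
                   ref_date = date_col) |>
      isotope_ratio_table(at_date = at_date, ref_date = date_col)
  })

  counts <- run_stage("particle accounting", {
    pr <- particles
    if (is.null(pr$previously_reported)) pr$previously_reported <- FALSE
    count_particles(pr)
  })

  fractions <- NULL
  frequency <- NULL
  efficiency <- NULL
  efficiency_summary_tbl <- NULL
  regression <- NULL

  if (!is.null(survey$masks)) {
    fractions <- run_stage("csmp fractions", {
      particles |>
        dplyr::rename(p137_bq = "a137_bq") |>
        csmp_fraction(masks = survey$masks)
    })
    frequency <- run_stage("frequency by class", {
      frequency_by_activity_class(survey$masks, particles, class_edges)
    })
    if (!is.null(survey$pairs) && nrow(survey$pairs) > 0) {
      efficiency <- run_stage("collection efficiency", {
        act <- survey$masks[, c("mask_id", "a137_bq")]
        survey$pairs |>
          dplyr::left_join(dplyr::rename(act, outer_a137_bq = "a137_bq"),
                           by = c(outer_mask_id = "mask_id")) |>
          dplyr::left_join(dplyr::rename(act, inner_a137_bq = "a137_bq"),
                           by = c(inner_mask_id = "mask_id")) |>
          collection_efficiency()
      })
      efficiency_summary_tbl <- efficiency_summary(efficiency)
    }
    if (!is.null(survey$residences)) {
      regression <- run_stage("distance regression", {
        # censored masks enter at their detection-limit value (dropping them
        # would bias the slope toward zero via distance-dependent selection)
        d <- dplyr::inner_join(survey$masks, survey$residences,
                               by = "residence_id")
        distance_regression(d)
      })
    }
  }

  report <- structure(
    list(
      particles_sized = sized,
      counts = counts,
      fractions = fractions,
      frequency = frequency,
      efficiency = efficiency,
      efficiency_summary = efficiency_summary_tbl,
      regression = regression,
      model = model,
      at_date = as_survey_date(at_date)
    ),
    class = "csmp_report"
  )

  if (!is.null(output_dir)) write_report(report, output_dir, survey)
  report
}

#' @export
print.csmp_report <- function(x, ...) {
  cat("<csmp_report>\n")
  cat(sprintf("  particles: %d sized (%d total, %d new)\n",
              nrow(x$particles_sized), x$counts$n_total, x$counts$n_new))
  if (!is.null(x$efficiency_summary)) {
    cat(sprintf("  efficiency: %d/%d significant, mean %.1f%%, max %.1f%%\n",
                x$efficiency_summary$n_significant, x$efficiency_summary$n,
                x$efficiency_summary$mean_pct, x$efficiency_summary$max_pct))
  }
  if (!is.null(x$regression)) print(x$regression)
  invisible(x)
}

write_report <- function(report, dir, survey) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- tryCatch(survey$config$seed, error = function(e) NULL)
  for (nm in c("particles_sized", "counts", "fractions", "frequency",
               "efficiency", "efficiency_summary")) {
    if (!is.null(report[[nm]])) {
      write_stamped_csv(report[[nm]], file.path(dir, paste0(nm, ".csv")), seed)
    }
  }
  summary <- list(
    package_version = as.character(utils::packageVersion("csmpsurvey")),
    seed = seed,
    reference_date = format(report$at_date),
    size_model = report$model[c("prefactor", "exponent", "diameter_variant")],
    counts = as.list(report$counts),
    efficiency = if (!is.null(report$efficiency_summary))
      as.list(report$efficiency_summary),
    regression = if (!is.null(report$regression))
      as.list(glance(report$regression))
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
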