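#' Collection efficiency of stacked mask pairs
#'
#' For masks worn stacked in pairs, the outer mask filters the airstream
#' before the inner one, so the radiocesium it retains relative to the inner
#' mask measures its collection efficiency:
#' `efficiency [%] = (1 - inner Cs-137 / outer Cs-137) * 100`.
#' An efficiency above zero is counted as significant, matching how the
#' survey tallied "51 of 76" informative pairs.  Because the outer mask
#' pre-cleans the air reaching the inner mask, the formula tends to
#' overestimate the true single-mask efficiency; the value is reported
#' verbatim and no correction is attempted.
#'
#' @param pairs Tibble with columns `outer_a137_bq` and `inner_a137_bq`
#'   (plus optional `outer_a137_censored` / `inner_a137_censored` flags).
#' @return `pairs` with `efficiency_pct` and `significant` appended.
#' @examples
#' collection_efficiency(
#'   tibble::tibble(outer_a137_bq = 0.785, inner_a137_bq = 0.341)
#' )
#' @export
collection_efficiency <- function(pairs) {
  stopifnot(all(c("outer_a137_bq", "inner_a137_bq") %in% names(pairs)))
  cens <- rep(FALSE, nrow(pairs))
  for (cl in c("outer_a137_censored", "inner_a137_censored")) {
    if (cl %in% names(pairs)) cens <- cens | isTRUE_vec(pairs[[cl]])
  }
  if (any(cens)) {
    abort("Undefined efficiency: censored activities in a mask pair.")
  }
  if (any(pairs$outer_a137_bq <= 0)) {
    abort("Undefined efficiency: outer mask Cs-137 activity must be positive.")
  }
  pairs$efficiency_pct <- (1 - pairs$inner_a137_bq / pairs$outer_a137_bq) * 100
  pairs$significant <- pairs$efficiency_pct > 0
  pairs
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Summarise collection efficiencies
#'
#' Counts significant results (efficiency above zero) and reports the
#' minimum, maximum and mean over the significant entries only, mirroring
#' how the survey summarised its pair table.
#'
#' @param efficiencies Numeric vector of efficiencies in percent, or a
#'   tibble from [collection_efficiency()].
#' @return One-row tibble: `n`, `n_significant`, `min_pct`, `max_pct`,
#'   `mean_pct`.  If nothing is significant the three statistics are `NA`.
#' @examples
#' efficiency_summary(c(-5, 50))
#' @export
efficiency_summary <- function(efficiencies) {
  if (is.data.frame(efficiencies)) efficiencies <- efficiencies$efficiency_pct
  if (length(efficiencies) == 0) abort("No efficiencies supplied.")
  sig <- efficiencies[efficiencies > 0]
  tibble(
    n = length(efficiencies),
    n_significant = length(sig),
    min_pct = if (length(sig)) min(sig) else NA_real_,
    max_pct = if (length(sig)) max(sig) else NA_real_,
    mean_pct = if (length(sig)) mean(sig) else NA_real_
  )
}

#' CsMP share of a mask's Cs-137 activity
#'
#' `100 * particle Cs-137 / mask Cs-137`, both referenced to the worn date.
#' If `masks` is supplied the mask activity is joined in by `mask_id`;
#' otherwise `particles` must already carry `m137_bq`.  A censored particle
#' numerator is computed at its detection limit and flagged as an upper
#' bound.
#'
#' @param particles Tibble with `p137_bq` (particle Cs-137, worn date) and
#'   either `m137_bq` or a `mask_id` to join on; optional `p137_censored`.
#' @param masks Optional tibble with `mask_id` and `a137_bq`.
#' @return `particles` with `fraction_pct` (and `fraction_upper_bound`)
#'   appended.
#' @examples
#' csmp_fraction(tibble::tibble(p137_bq = 1.01, m137_bq = 39.0))
#' @export
csmp_fraction <- function(particles, masks = NULL) {
  if (!is.null(masks)) {
    stopifnot(all(c("mask_id", "a137_bq") %in% names(masks)))
    particles <- dplyr::left_join(
      particles,
      dplyr::select(masks, "mask_id", m137_bq = "a137_bq"),
      by = "mask_id"
    )
  }
  stopifnot(all(c("p137_bq", "m137_bq") %in% names(particles)))
  if (any(!is.na(particles$m137_bq) & particles$m137_bq <= 0)) {
    abort("Mask Cs-137 activity must be positive.")
  }
  particles$fraction_pct <- 100 * particles$p137_bq / particles$m137_bq
  particles$fraction_upper_bound <-
    if ("p137_censored" %in% names(particles)) {
      isTRUE_vec(particles$p137_censored)
    } else {
      FALSE
    }
  particles
}

# host mask of a particle: strip the trailing single-letter suffix
particle_host_mask <- function(particle_id) {
  sub("-[A-Z]$", "", particle_id)
}

#' Particle accounting
#'
#' Totals for a particle table: how many particles in all, how many are new
#' to this campaign (not flagged `previously_reported`), and how many
#' distinct host masks carry a new particle.  If no `mask_id` column is
#' present the host mask is derived from the particle ID by stripping its
#' trailing letter suffix.
#'
#' @param particles Tibble with `particle_id`, `previously_reported`, and
#'   optionally `mask_id`.
#' @return One-row tibble: `n_total`, `n_new`, `n_masks_with_new`.
#' @examples
#' count_particles(tibble::tibble(
#'   particle_id = c("Mask-001-A", "Mask-001-B"),
#'   previously_reported = c(TRUE, FALSE)
#' ))
#' @export
count_particles <- function(particles) {
  if (nrow(particles) == 0) {
    return(tibble(n_total = 0L, n_new = 0L, n_masks_with_new = 0L))
  }
  mask_id <- particles[["mask_id"]] %||% particle_host_mask(particles$particle_id)
  new <- !particles$previously_reported
  tibble(
    n_total = nrow(particles),
    n_new = sum(new),
    n_masks_with_new = dplyr::n_distinct(mask_id[new])
  )
}

#' CsMP occurrence by mask activity class
#'
#' Bins masks into half-open Cs-137 activity classes `[lo, hi)` and tallies
#' in each class how many masks carry at least one detected CsMP.  In the
#' survey, particles were only found on masks above about 10 Bq and the
#' occurrence frequency rose with mask activity; that monotonicity is a
#' property of the data, not enforced here.
#'
#' @param masks Tibble with `mask_id` and `a137_bq`.
#' @param particles Tibble with `mask_id` (or `particle_id` to derive it).
#' @param class_edges Strictly increasing bin edges in Bq.
#' @return Tibble with one row per class: `class`, `lower_bq`, `upper_bq`,
#'   `n_masks`, `n_masks_with_csmp`, `percent`.
#' @export
frequency_by_activity_class <- function(masks, particles,
                                        class_edges = c(0, 0.1, 1, 10, 100, 1000, Inf)) {
  if (is.unsorted(class_edges, strictly = TRUE)) {
    abort("class_edges must be strictly increasing.")
  }
  pmask <- if (nrow(particles) == 0) {
    character(0)
  } else {
    unique(particles[["mask_id"]] %||% particle_host_mask(particles$particle_id))
  }
  lo <- head(class_edges, -1)
  hi <- class_edges[-1]
  cls <- cut(masks$a137_bq, class_edges, right = FALSE,
             labels = sprintf("[%g, %g)", lo, hi))
  tibble(
    class = factor(levels(cls), levels = levels(cls)),
    lower_bq = lo,
    upper_bq = hi
  ) |>
    dplyr::left_join(
      tibble(class = cls, with_csmp = masks$mask_id %in% pmask) |>
        dplyr::group_by(.data$class) |>
        dplyr::summarise(
          n_masks = dplyr::n(),
          n_masks_with_csmp = sum(.data$with_csmp)
        ),
      by = "class"
    ) |>
    tidyr::replace_na(list(n_masks = 0L, n_masks_with_csmp = 0L)) |>
    dplyr::mutate(percent = ifelse(.data$n_masks > 0,
                                   100 * .data$n_masks_with_csmp / .data$n_masks,
                                   0))
}

#' Log-log regression of mask activity on distance from the source
#'
#' Ordinary least squares of `log10(activity)` on `log10(distance)`.  An
#' inverse-square dilution law corresponds to slope -2; noiseless power-law
#' data recover their exponent exactly.  With `fixed_slope` given (typically
#' -2), only the intercept is fitted and the reported R-squared is that of
#' the constrained model, `1 - RSS/TSS` about the mean of `log10(activity)`.
#'
#' @param data Tibble of observations.
#' @param distance,activity Column names (character) holding distance in km
#'   and Cs-137 activity in Bq; both must be positive.
#' @param fixed_slope Optional fixed slope.
#' @return A `distance_fit` object with [tidy()], [glance()], [autoplot()]
#'   and `print()` methods.
#' @examples
#' d <- tibble::tibble(distance_km = c(2, 4, 8), a137_bq = 300 / c(2, 4, 8)^2)
#' distance_regression(d)
#' @export
distance_regression <- function(data, distance = "distance_km",
                                activity = "a137_bq", fixed_slope = NULL) {
  x <- data[[distance]]
  y <- data[[activity]]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) abort("Need at least 3 observations.")
  if (any(x <= 0) || any(y <= 0)) {
    abort("Distances and activities must be positive for the log-log fit.")
  }
  lx <- log10(x)
  ly <- log10(y)
  df <- tibble(log_distance = lx, log_activity = ly)
  if (is.null(fixed_slope)) {
    fit <- lm(log_activity ~ log_distance, data = df)
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    r2 <- suppressWarnings(summary(fit)$r.squared)
  } else {
    fit <- lm(log_activity ~ 1, data = df, offset = fixed_slope * lx)
    slope <- fixed_slope
    intercept <- unname(coef(fit)[1])
    rss <- sum((ly - (intercept + slope * lx))^2)
    tss <- sum((ly - mean(ly))^2)
    r2 <- 1 - rss / tss
  }
  structure(
    list(
      slope = slope, intercept = intercept, r_squared = r2,
      fixed_slope = fixed_slope, n = length(x), model = fit,
      data = tibble(distance_km = x, a137_bq = y)
    ),
    class = "distance_fit"
  )
}

#' @export
print.distance_fit <- function(x, ...) {
  cat(sprintf(
    "<distance_fit> log10(A) = %.3f %+.3f * log10(d)%s, R^2 = %.3f, n = %d\n",
    x$intercept, x$slope,
    if (!is.null(x$fixed_slope)) " (slope fixed)" else "",
    x$r_squared, x$n
  ))
  invisible(x)
}

#' @rdname distance_regression
#' @param x A `distance_fit`.
#' @param ... Unused.
#' @export
tidy.distance_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$model)$coefficients)
  out <- tibble(
    term = c("(Intercept)", "log10(distance_km)"),
    estimate = c(x$intercept, x$slope),
    std.error = NA_real_,
    statistic = NA_real_,
    p.value = NA_real_,
    conf.low = NA_real_,
    conf.high = NA_real_
  )
  ci <- suppressMessages(confint(x$model))
  fitted_terms <- seq_len(nrow(s))
  out$std.error[fitted_terms] <- s[, "Std. Error"]
  out$statistic[fitted_terms] <- s[, "t value"]
  out$p.value[fitted_terms] <- s[, "Pr(>|t|)"]
  out$conf.low[fitted_terms] <- ci[, 1]
  out$conf.high[fitted_terms] <- ci[, 2]
  out
}

#' @rdname distance_regression
#' @export
glance.distance_fit <- function(x, ...) {
  tibble(
    r.squared = x$r_squared,
    sigma = suppressWarnings(summary(x$model)$sigma),
    nobs = x$n,
    slope = x$slope,
    intercept = x$intercept,
    slope.fixed = !is.null(x$fixed_slope)
  )
}
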