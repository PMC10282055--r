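#' Configuration for the synthetic survey generator
#'
#' Defaults emulate the study conditions of the mask campaign: residences
#' 1.6-16.1 km from the source whose ambient loading falls off as
#' distance^-2 with wide lognormal scatter, about 284 masks worn by six
#' persons at 59 residences, a soluble-cesium background on every mask plus
#' occasional discrete CsMPs (none above 25 Bq Cs-137), a Cs-134/Cs-137
#' ratio of 1.08 at 2011-03-11, Poisson counting at the stated live times,
#' and roughly half the masks worn stacked in pairs with a true collection
#' efficiency drawn from 0-85%.
#'
#' @param n_residences Number of residences.
#' @param n_persons Number of persons wearing masks.
#' @param masks_per_residence Mean masks per residence (Poisson).
#' @param distance_range_km Residence distance interval from the source.
#' @param distance_law_coefficient `C` in `soluble Bq = C / d^2` (Bq km^2).
#' @param distance_scatter_sd Lognormal scatter on `log10(activity)`, in
#'   dex, drawn independently per mask.
#' @param soluble_fraction Scales the distance-law draw into the soluble
#'   (non-particle) component of each mask.
#' @param particle_rate_coefficient,particle_rate_threshold_bq Expected CsMP
#'   count per mask is `r * max(0, log10(soluble / threshold))` — zero below
#'   the threshold, rising with mask activity.
#' @param particle_meanlog,particle_sdlog,particle_max_bq Lognormal
#'   parameters of particle Cs-137 activity at 2011-03-11, truncated at
#'   `particle_max_bq`.
#' @param ratio_134_137_2011 Cs-134/Cs-137 activity ratio at 2011-03-11.
#' @param pair_fraction Fraction of a residence's masks worn stacked.
#' @param true_efficiency_range Interval for a pair's drawn collection
#'   efficiency (fraction, not percent).
#' @param n95_fraction Fraction of unpaired masks that are N95 respirators.
#' @param mask_counting,particle_counting [counting_setup()]s for the two
#'   geometries; backgrounds default to Currie-calibrated values matching
#'   the stated detection limits (0.070 Bq at 50,000 s on masks; 0.00537 Bq
#'   Cs-137 at 600,000 s on particles).
#' @param mask_detection_limit_bq,particle_detection_limit_134_bq,particle_detection_limit_137_bq
#'   Censoring limits applied to observed activities.
#' @param mask_standard_bq,particle_standard_bq Activities of the
#'   quantification standards.
#' @param start_date,end_date Interval in which worn dates fall.
#' @param counting_noise Set `FALSE` for a noiseless survey (observed =
#'   true); used by recovery tests to establish a zero-bias baseline.
#' @param seed Integer seed governing all draws.
#' @return A `survey_config` list.
#' @export
survey_config <- function(n_residences = 59,
                          n_persons = 6,
                          masks_per_residence = 4.8,
                          distance_range_km = c(1.6, 16.1),
                          distance_law_coefficient = 300,
                          distance_scatter_sd = 1.0,
                          soluble_fraction = 1.0,
                          particle_rate_coefficient = 0.35,
                          particle_rate_threshold_bq = 10,
                          particle_meanlog = log(0.35),
                          particle_sdlog = 1.0,
                          particle_max_bq = 25,
                          ratio_134_137_2011 = 1.08,
                          pair_fraction = 0.54,
                          true_efficiency_range = c(0, 0.85),
                          n95_fraction = 0.05,
                          mask_counting = NULL,
                          particle_counting = NULL,
                          mask_detection_limit_bq = 0.070,
                          particle_detection_limit_134_bq = 0.00577,
                          particle_detection_limit_137_bq = 0.00537,
                          mask_standard_bq = 236,
                          particle_standard_bq = 25.3,
                          start_date = "2016-04-01",
                          end_date = "2019-01-31",
                          counting_noise = TRUE,
                          seed = 1L) {
  if (is.null(mask_counting)) {
    s <- counting_setup(50000, 0.02, 1) # placeholder background, calibrated next
    mask_counting <- counting_setup(
      50000, 0.02, background_for_limit(mask_detection_limit_bq, s)
    )
  }
  if (is.null(particle_counting)) {
    s <- counting_setup(600000, 0.05, 1)
    particle_counting <- counting_setup(
      600000, 0.05, background_for_limit(particle_detection_limit_137_bq, s)
    )
  }
  cfg <- list(
    n_residences = n_residences, n_persons = n_persons,
    masks_per_residence = masks_per_residence,
    distance_range_km = distance_range_km,
    distance_law_coefficient = distance_law_coefficient,
    distance_scatter_sd = distance_scatter_sd,
    soluble_fraction = soluble_fraction,
    particle_rate_coefficient = particle_rate_coefficient,
    particle_rate_threshold_bq = particle_rate_threshold_bq,
    particle_meanlog = particle_meanlog, particle_sdlog = particle_sdlog,
    particle_max_bq = particle_max_bq,
    ratio_134_137_2011 = ratio_134_137_2011,
    pair_fraction = pair_fraction,
    true_efficiency_range = true_efficiency_range,
    n95_fraction = n95_fraction,
    mask_counting = mask_counting, particle_counting = particle_counting,
    mask_detection_limit_bq = mask_detection_limit_bq,
    particle_detection_limit_134_bq = particle_detection_limit_134_bq,
    particle_detection_limit_137_bq = particle_detection_limit_137_bq,
    mask_standard_bq = mask_standard_bq,
    particle_standard_bq = particle_standard_bq,
    start_date = as_survey_date(start_date),
    end_date = as_survey_date(end_date),
    counting_noise = counting_noise,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_residences >= 1, cfg$n_persons >= 1,
    diff(cfg$distance_range_km) > 0, all(cfg$distance_range_km > 0),
    cfg$distance_law_coefficient > 0, cfg$distance_scatter_sd >= 0,
    cfg$soluble_fraction >= 0, cfg$soluble_fraction <= 1,
    cfg$particle_rate_coefficient >= 0, cfg$particle_rate_threshold_bq > 0,
    cfg$particle_max_bq > 0, cfg$ratio_134_137_2011 > 0,
    cfg$pair_fraction >= 0, cfg$pair_fraction <= 1,
    all(cfg$true_efficiency_range >= 0), all(cfg$true_efficiency_range <= 1),
    cfg$n95_fraction >= 0, cfg$n95_fraction <= 1,
    cfg$end_date >= cfg$start_date
  )
  structure(cfg, class = "survey_config")
}

rtrunc_lnorm <- function(n, meanlog, sdlog, max_value) {
  out <- rlnorm(n, meanlog, sdlog)
  while (any(bad <- out > max_value)) {
    out[bad] <- rlnorm(sum(bad), meanlog, sdlog)
  }
  out
}

# observe a vector of true activities through the counting model
observe_activities <- function(true_bq, nuclide, ref_date, setup, standard_bq,
                               limit_bq, noise = TRUE) {
  n <- length(true_bq)
  if (n == 0) {
    return(activity(numeric(0), numeric(0), character(0), as.Date(character(0))))
  }
  if (!noise) {
    return(activity(true_bq, 0, rep(nuclide, n), ref_date))
  }
  std <- simulate_counts(standard_bq, setup)
  cnt <- simulate_counts(true_bq, setup)
  obs <- quantify_comparative(cnt, std[rep(1, n), ], standard_bq,
                              nuclide = rep(nuclide, n), ref_date = ref_date)
  censor_activity(obs, limit_bq)
}

#' Generate a complete synthetic mask survey
#'
#' Produces residences, masks (single, N95, and stacked outer/inner pairs),
#' discrete CsMPs, and Poisson counting noise with the statistical structure
#' the analysis pipeline assumes, and keeps the generating ground truth so
#' every downstream estimate can be scored against it.
#'
#' Construction, per mask: a soluble cesium background is drawn from the
#' inverse-square distance law with per-mask lognormal scatter; an inner
#' mask's background is its outer partner's times `1 - efficiency` with the
#' pair's efficiency drawn from `true_efficiency_range`.  CsMP counts are
#' Poisson with expectation rising in the soluble background above the
#' occurrence threshold; particle activities are drawn at 2011-03-11 (so
#' sizing has an exact internal truth through the power law) and decayed to
#' the worn date.  The mask's true total is soluble background plus its
#' particles, so particle activity can never exceed the mask total.  Cs-134
#' follows from the 2011 ratio and the two half-lives.  Observed values
#' come from the comparative counting model and are censored at the
#' configured detection limits.  Deterministic for a fixed config seed.
#'
#' @param config A [survey_config()].
#' @return A `csmp_survey` list: tibbles `masks`, `particles`, `pairs`,
#'   `residences`, plus `truth` (per-mask, per-particle and per-pair true
#'   values and the distance-law parameters) and `config`.
#' @examples
#' sv <- generate_survey(survey_config(n_residences = 5, seed = 42))
#' @export
generate_survey <- function(config = survey_config()) {
  stopifnot(inherits(config, "survey_config"))
  withr::with_seed(config$seed, generate_survey_impl(config))
}

generate_survey_impl <- function(cfg) {
  res <- tibble(
    residence_id = sprintf("RES_%02d", seq_len(cfg$n_residences)),
    distance_km = runif(cfg$n_residences, cfg$distance_range_km[1],
                        cfg$distance_range_km[2]),
    construction = sample(c("wood", "light_steel", "reinforced_concrete"),
                          cfg$n_residences, replace = TRUE,
                          prob = c(51, 10, 4)),
    worn_date = cfg$start_date +
      sample.int(as.integer(cfg$end_date - cfg$start_date) + 1L,
                 cfg$n_residences, replace = TRUE) - 1L
  )

  masks <- list()
  pairs <- list()
  mask_no <- 0L
  for (i in seq_len(cfg$n_residences)) {
    n_m <- max(1L, rpois(1, cfg$masks_per_residence))
    n_paired <- 2L * floor(n_m * cfg$pair_fraction / 2)
    roles <- c(rep(c("outer", "inner"), n_paired / 2),
               rep("single", n_m - n_paired))
    is_n95 <- roles == "single" & runif(n_m) < cfg$n95_fraction
    roles[is_n95] <- "n95"
    pair_id <- c(rep(seq_len(n_paired / 2), each = 2),
                 rep(NA_integer_, n_m - n_paired))
    masks[[i]] <- tibble(
      mask_id = sprintf("SYN-M%04d", mask_no + seq_len(n_m)),
      residence_id = res$residence_id[i],
      person_id = sprintf("P%d", sample.int(cfg$n_persons, n_m, replace = TRUE)),
      worn_date = res$worn_date[i],
      mask_type = roles,
      pair_local = pair_id,
      distance_km = res$distance_km[i]
    )
    mask_no <- mask_no + n_m
  }
  masks <- dplyr::bind_rows(masks)

  # soluble background from the distance law, per-mask scatter
  masks$soluble_bq <- cfg$soluble_fraction *
    cfg$distance_law_coefficient / masks$distance_km^2 *
    10^rnorm(nrow(masks), 0, cfg$distance_scatter_sd)

  # stacked pairs: inner background is the filtered outer background
  pair_key <- paste(masks$residence_id, masks$pair_local)
  pairs_idx <- which(masks$mask_type == "outer")
  drawn_eff <- runif(length(pairs_idx), cfg$true_efficiency_range[1],
                     cfg$true_efficiency_range[2])
  inner_idx <- match(paste(masks$residence_id[pairs_idx],
                           masks$pair_local[pairs_idx]),
                     ifelse(masks$mask_type == "inner", pair_key, NA))
  masks$soluble_bq[inner_idx] <- masks$soluble_bq[pairs_idx] * (1 - drawn_eff)

  # discrete CsMPs: occurrence rises with the mask's soluble loading
  lam <- cfg$particle_rate_coefficient *
    pmax(0, log10(masks$soluble_bq / cfg$particle_rate_threshold_bq))
  n_par <- rpois(nrow(masks), lam)
  host <- rep(seq_len(nrow(masks)), n_par)
  particles <- tibble(
    mask_id = masks$mask_id[host],
    particle_id = paste0(masks$mask_id[host], "-",
                         unlist(lapply(n_par[n_par > 0], function(k) LETTERS[seq_len(k)]))),
    worn_date = masks$worn_date[host],
    true_a137_2011_bq = rtrunc_lnorm(length(host), cfg$particle_meanlog,
                                     cfg$particle_sdlog, cfg$particle_max_bq)
  )
  f137 <- decay_factor("cs137", rep(as.Date("2011-03-11"), nrow(particles)),
                       particles$worn_date)
  f134 <- decay_factor("cs134", rep(as.Date("2011-03-11"), nrow(particles)),
                       particles$worn_date)
  particles$true_a137_worn_bq <- particles$true_a137_2011_bq * f137
  particles$true_a134_worn_bq <- particles$true_a137_2011_bq *
    cfg$ratio_134_137_2011 * f134
  particles$true_volume_cm3 <- volume_from_activity(particles$true_a137_2011_bq)
  particles$true_diameter_um <- diameter_from_volume(particles$true_volume_cm3)

  # mask true totals = soluble background + its particles (worn-date basis)
  psum <- tapply(particles$true_a137_worn_bq, particles$mask_id, sum)
  masks$true_a137_worn_bq <- masks$soluble_bq +
    as.numeric(ifelse(is.na(psum[masks$mask_id]), 0, psum[masks$mask_id]))
  mf137 <- decay_factor("cs137", rep(as.Date("2011-03-11"), nrow(masks)),
                        masks$worn_date)
  mf134 <- decay_factor("cs134", rep(as.Date("2011-03-11"), nrow(masks)),
                        masks$worn_date)
  masks$true_a134_worn_bq <- masks$true_a137_worn_bq *
    cfg$ratio_134_137_2011 * mf134 / mf137

  pairs <- tibble(
    outer_mask_id = masks$mask_id[pairs_idx],
    inner_mask_id = masks$mask_id[inner_idx],
    drawn_efficiency_pct = 100 * drawn_eff,
    true_efficiency_pct = 100 *
      (1 - masks$true_a137_worn_bq[inner_idx] / masks$true_a137_worn_bq[pairs_idx])
  )

  # observation layer: comparative counting + censoring
  m137 <- observe_activities(masks$true_a137_worn_bq, "cs137", masks$worn_date,
                             cfg$mask_counting, cfg$mask_standard_bq,
                             cfg$mask_detection_limit_bq, cfg$counting_noise)
  m134 <- observe_activities(masks$true_a134_worn_bq, "cs134", masks$worn_date,
                             cfg$mask_counting, cfg$mask_standard_bq,
                             cfg$mask_detection_limit_bq, cfg$counting_noise)
  p137 <- observe_activities(particles$true_a137_worn_bq, "cs137",
                             particles$worn_date, cfg$particle_counting,
                             cfg$particle_standard_bq,
                             cfg$particle_detection_limit_137_bq,
                             cfg$counting_noise)
  p134 <- observe_activities(particles$true_a134_worn_bq, "cs134",
                             particles$worn_date, cfg$particle_counting,
                             cfg$particle_standard_bq,
                             cfg$particle_detection_limit_134_bq,
                             cfg$counting_noise)

  masks_obs <- tibble(
    mask_id = masks$mask_id,
    residence_id = masks$residence_id,
    person_id = masks$person_id,
    worn_date = masks$worn_date,
    mask_type = masks$mask_type,
    a134_bq = m134$value, a134_sigma = m134$sigma,
    a134_censored = m134$censored,
    a137_bq = m137$value, a137_sigma = m137$sigma,
    a137_censored = m137$censored,
    detection_limit_bq = cfg$mask_detection_limit_bq
  )
  particles_obs <- tibble(
    particle_id = particles$particle_id,
    mask_id = particles$mask_id,
    worn_date = particles$worn_date,
    a134_bq = p134$value, a134_sigma = p134$sigma,
    a134_censored = p134$censored,
    a137_bq = p137$value, a137_sigma = p137$sigma,
    a137_censored = p137$censored,
    previously_reported = FALSE
  )

  truth <- list(
    masks = dplyr::select(masks, "mask_id", "soluble_bq",
                          "true_a137_worn_bq", "true_a134_worn_bq"),
    particles = dplyr::select(particles, "particle_id", "mask_id",
                              "true_a137_2011_bq", "true_a137_worn_bq",
                              "true_a134_worn_bq", "true_volume_cm3",
                              "true_diameter_um"),
    pairs = pairs,
    distance_law = list(
      coefficient = cfg$distance_law_coefficient,
      exponent = -2,
      scatter_sd = cfg$distance_scatter_sd
    )
  )

  structure(
    list(
      masks = masks_obs,
      particles = particles_obs,
      pairs = dplyr::select(pairs, "outer_mask_id", "inner_mask_id"),
      residences = dplyr::select(res, "residence_id", "distance_km",
                                 "construction"),
      truth = truth,
      config = cfg
    ),
    class = "csmp_survey"
  )
}

#' @export
print.csmp_survey <- function(x, ...) {
  cat(sprintf(
    "<csmp_survey> %d masks, %d particles, %d pairs, %d residences (seed %d)\n",
    nrow(x$masks), nrow(x$particles), nrow(x$pairs), nrow(x$residences),
    x$config$seed
  ))
  invisible(x)
}

#' Run the full pipeline on a synthetic survey and score it against truth
#'
#' Executes the downstream analysis (counting observation already applied by
#' the generator; here: sizing, pair efficiency, particle accounting,
#' distance regression) on the observed tables and compares each estimate
#' with the generator's ground truth.
#'
#' @param survey A `csmp_survey` from [generate_survey()].
#' @return A tibble of recovery metrics: mean relative bias of observed
#'   particle Cs-137 activity, mean absolute relative error of recovered
#'   particle diameters, mean absolute pair-efficiency error in percentage
#'   points, the fitted distance-law slope with its 95% CI and whether the
#'   CI covers the true exponent, and the particle/mask tallies.
#' @export
recover_and_score <- function(survey) {
  if (!inherits(survey, "csmp_survey")) {
    abort("recover_and_score() expects a survey from generate_survey().")
  }
  p <- dplyr::inner_join(survey$particles, survey$truth$particles,
                         by = c("particle_id", "mask_id"))
  p_ok <- dplyr::filter(p, !.data$a137_censored)
  act_bias <- mean((p_ok$a137_bq - p_ok$true_a137_worn_bq) /
                     p_ok$true_a137_worn_bq)
  sized <- size_particles(p_ok, ref_date = "worn_date")
  dia_err <- mean(abs(sized$diameter_um - sized$true_diameter_um) /
                    sized$true_diameter_um)

  eff_mae <- NA_real_
  if (nrow(survey$pairs) > 0) {
    act <- survey$masks[, c("mask_id", "a137_bq", "a137_censored")]
    pr <- survey$pairs |>
      dplyr::left_join(
        dplyr::rename(act, outer_a137_bq = "a137_bq",
                      outer_cens = "a137_censored"),
        by = c(outer_mask_id = "mask_id")
      ) |>
      dplyr::left_join(
        dplyr::rename(act, inner_a137_bq = "a137_bq",
                      inner_cens = "a137_censored"),
        by = c(inner_mask_id = "mask_id")
      ) |>
      dplyr::filter(!.data$outer_cens, !.data$inner_cens) |>
      collection_efficiency() |>
      dplyr::left_join(survey$truth$pairs[, c("outer_mask_id", "true_efficiency_pct")],
                       by = "outer_mask_id")
    eff_mae <- mean(abs(pr$efficiency_pct - pr$true_efficiency_pct))
  }

  # censored masks stay in at their detection-limit value: dropping them
  # preferentially removes far, low-activity residences and flattens the slope
  reg_data <- dplyr::inner_join(survey$masks, survey$residences,
                                by = "residence_id")
  fit <- distance_regression(reg_data)
  ci <- confint(fit$model)["log_distance", ]
  true_slope <- survey$truth$distance_law$exponent

  counts <- count_particles(survey$particles)
  tibble(
    metric = c("particle_activity_rel_bias", "particle_diameter_mean_abs_rel_error",
               "efficiency_mean_abs_error_pp", "slope", "slope_conf_low",
               "slope_conf_high", "slope_covers_true", "r_squared",
               "n_masks", "n_particles", "n_pairs"),
    value = c(act_bias, dia_err, eff_mae, fit$slope, ci[1], ci[2],
              as.numeric(ci[1] <= true_slope && true_slope <= ci[2]),
              fit$r_squared,
              nrow(survey$masks), counts$n_total, nrow(survey$pairs))
  )
}
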