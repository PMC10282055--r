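test_that("survey generation is deterministic in the seed", {
  a <- generate_survey(survey_config(n_residences = 10, seed = 21))
  b <- generate_survey(survey_config(n_residences = 10, seed = 21))
  expect_identical(a$masks, b$masks)
  expect_identical(a$particles, b$particles)
  expect_identical(a$pairs, b$pairs)
  expect_identical(a$truth, b$truth)
  c_ <- generate_survey(survey_config(n_residences = 10, seed = 22))
  expect_false(identical(a$masks, c_$masks))
})

test_that("a zero particle rate yields a particle-free survey", {
  sv <- generate_survey(survey_config(n_residences = 8,
                                      particle_rate_coefficient = 0,
                                      seed = 23))
  expect_equal(nrow(sv$particles), 0L)
  expect_equal(count_particles(sv$particles)$n_total, 0L)
})

test_that("mask totals conserve their particle inventory", {
  sv <- generate_survey(survey_config(seed = 24))
  psum <- tapply(sv$truth$particles$true_a137_worn_bq,
                 sv$truth$particles$mask_id, sum)
  tr <- sv$truth$masks
  got <- as.numeric(ifelse(is.na(psum[tr$mask_id]), 0, psum[tr$mask_id]))
  # total = soluble + particles, so the particle sum never exceeds the total
  expect_true(all(got <= tr$true_a137_worn_bq + 1e-12))
  expect_equal(unname(got) + tr$soluble_bq, tr$true_a137_worn_bq)
})

test_that("generated isotope ratios carry the configured 2011 ratio", {
  sv <- generate_survey(survey_config(seed = 25))
  p <- dplyr::filter(sv$particles, !.data$a134_censored, !.data$a137_censored)
  p$ref_date <- p$worn_date
  r <- isotope_ratio_table(p)
  expect_equal(median(r$ratio, na.rm = TRUE), 1.08, tolerance = 0.15)
})

test_that("true sub-limit masks are censored with high probability", {
  # push the distance law down so much of the survey sits below 0.070 Bq
  sv <- generate_survey(survey_config(distance_law_coefficient = 0.5,
                                      seed = 26))
  joined <- dplyr::inner_join(sv$masks, sv$truth$masks, by = "mask_id")
  deep <- dplyr::filter(joined, .data$true_a137_worn_bq < 0.070 / 3)
  expect_gt(nrow(deep), 10)
  expect_gte(mean(deep$a137_censored), 0.9)
  # and censored observations carry the limit as their value
  expect_true(all(joined$a137_bq[joined$a137_censored] == 0.070))
})

test_that("occurrence frequency rises with mask activity class in a large survey", {
  sv <- generate_survey(survey_config(n_residences = 300, seed = 27))
  f <- frequency_by_activity_class(sv$masks, sv$particles,
                                   class_edges = c(0.1, 10, 100, 1000, Inf))
  expect_true(all(diff(f$percent) >= 0))
  # no particles below the 10 Bq occurrence threshold by construction
  expect_equal(f$n_masks_with_csmp[1], 0L)
})

test_that("a noiseless survey is recovered with zero bias everywhere", {
  sv <- generate_survey(survey_config(counting_noise = FALSE, seed = 28))
  r <- recover_and_score(sv)
  v <- setNames(r$value, r$metric)
  expect_equal(v[["particle_activity_rel_bias"]], 0, tolerance = 1e-12)
  expect_equal(v[["particle_diameter_mean_abs_rel_error"]], 0, tolerance = 1e-10)
  expect_equal(v[["efficiency_mean_abs_error_pp"]], 0, tolerance = 1e-10)
  expect_equal(v[["slope_covers_true"]], 1)
})

test_that("recover_and_score validates its input", {
  expect_error(recover_and_score(list(masks = tibble::tibble())),
               "generate_survey")
})
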