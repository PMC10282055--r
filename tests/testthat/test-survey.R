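test_that("collection efficiency matches the pair formula and its edge cases", {
  p <- tibble::tibble(
    outer_a137_bq = c(1, 1, 0.785),
    inner_a137_bq = c(1, 0, 0.341)
  )
  out <- collection_efficiency(p)
  expect_equal(out$efficiency_pct, c(0, 100, (1 - 0.341 / 0.785) * 100))
  expect_identical(out$significant, c(FALSE, TRUE, TRUE))
  expect_true(agrees_last_digit(out$efficiency_pct[3], 56.6))
  # scale invariance in the pair activities
  out10 <- collection_efficiency(dplyr::mutate(
    p, outer_a137_bq = outer_a137_bq * 10, inner_a137_bq = inner_a137_bq * 10
  ))
  expect_equal(out10$efficiency_pct, out$efficiency_pct)
  expect_error(
    collection_efficiency(tibble::tibble(outer_a137_bq = 0, inner_a137_bq = 1)),
    "positive"
  )
  expect_error(
    collection_efficiency(tibble::tibble(
      outer_a137_bq = 1, inner_a137_bq = 0.1, inner_a137_censored = TRUE
    )),
    "censored"
  )
})

test_that("efficiency summary averages significant cases only", {
  expect_equal(
    efficiency_summary(50),
    tibble::tibble(n = 1L, n_significant = 1L, min_pct = 50, max_pct = 50,
                   mean_pct = 50)
  )
  s <- efficiency_summary(c(-5, 50))
  expect_equal(s$n_significant, 1L)
  expect_equal(s$mean_pct, 50)
  none <- efficiency_summary(c(-5, -10))
  expect_equal(none$n_significant, 0L)
  expect_true(is.na(none$mean_pct))
  expect_error(efficiency_summary(numeric(0)), "No efficiencies")
})

test_that("published pair efficiencies summarise to the reported statistics", {
  s <- efficiency_summary(reference_pair_efficiencies()$efficiency_pct)
  expect_equal(s$n_significant, 51L)
  expect_equal(signif(s$mean_pct, 3), 34.7)
  expect_equal(s$max_pct, 81.7)
})

test_that("CsMP fractions divide particle by host-mask activity", {
  out <- csmp_fraction(tibble::tibble(
    p137_bq = c(1.01, 58.8, 5), m137_bq = c(39.0, 1420, 5)
  ))
  expect_true(agrees_last_digit(out$fraction_pct[1], 2.59))
  expect_true(agrees_last_digit(out$fraction_pct[2], 4.14))
  expect_equal(out$fraction_pct[3], 100)
  # join path through a mask table
  out2 <- csmp_fraction(
    tibble::tibble(mask_id = "M1", p137_bq = 1, p137_censored = TRUE),
    masks = tibble::tibble(mask_id = "M1", a137_bq = 10)
  )
  expect_equal(out2$fraction_pct, 10)
  expect_true(out2$fraction_upper_bound)
  expect_error(
    csmp_fraction(tibble::tibble(p137_bq = 1, m137_bq = 0)), "positive"
  )
})

test_that("particle accounting tallies totals, new finds and host masks", {
  expect_equal(
    count_particles(tibble::tibble(particle_id = character(0),
                                   previously_reported = logical(0))),
    tibble::tibble(n_total = 0L, n_new = 0L, n_masks_with_new = 0L)
  )
  one <- count_particles(tibble::tibble(particle_id = "Mask-101",
                                        previously_reported = FALSE))
  expect_equal(unlist(one), c(n_total = 1L, n_new = 1L, n_masks_with_new = 1L))
  # lettered suffixes share a host mask
  multi <- count_particles(tibble::tibble(
    particle_id = c("Mask-087-A", "Mask-087-B", "Mask-090", "Mask-012-A"),
    previously_reported = c(FALSE, FALSE, FALSE, TRUE)
  ))
  expect_equal(unlist(multi), c(n_total = 4L, n_new = 3L, n_masks_with_new = 2L))
})

test_that("occurrence frequency by activity class bins half-open and tallies", {
  masks <- tibble::tibble(mask_id = sprintf("M%d", 1:6),
                          a137_bq = c(0.5, 5, 10, 40, 400, 4000))
  particles <- tibble::tibble(particle_id = c("P1", "P2", "P3"),
                              mask_id = c("M4", "M5", "M6"))
  f <- frequency_by_activity_class(masks, particles,
                                   class_edges = c(0.1, 1, 10, 100, 1000, Inf))
  expect_equal(f$n_masks, c(1L, 1L, 2L, 1L, 1L))
  expect_equal(f$percent, c(0, 0, 50, 100, 100))
  # lower edge is inclusive (10 Bq lands in [10, 100))
  expect_equal(f$n_masks[3], 2L)
  expect_error(
    frequency_by_activity_class(masks, particles, class_edges = c(1, 1, 2)),
    "strictly increasing"
  )
  empty <- frequency_by_activity_class(masks, particles[0, ],
                                       class_edges = c(0.1, Inf))
  expect_equal(empty$percent, 0)
  expect_equal(empty$n_masks, 6L)
})

test_that("log-log regression recovers exact power laws to 1e-10", {
  d <- tibble::tibble(distance_km = c(1.6, 3, 7, 12, 16.1),
                      a137_bq = 300 / c(1.6, 3, 7, 12, 16.1)^2)
  fit <- distance_regression(d)
  expect_equal(fit$slope, -2, tolerance = 1e-10)
  expect_equal(fit$intercept, log10(300), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  flat <- distance_regression(tibble::tibble(distance_km = c(1, 2, 4, 8),
                                             a137_bq = rep(7, 4)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
})

test_that("fixed-slope regression fits the intercept and reports constrained R^2", {
  withr::with_seed(9, {
    d <- tibble::tibble(distance_km = runif(40, 1.6, 16.1))
    d$a137_bq <- 300 / d$distance_km^2 * 10^rnorm(40, 0, 0.3)
  })
  fit <- distance_regression(d, fixed_slope = -2)
  expect_equal(fit$slope, -2)
  # intercept is the mean offset of log activity against the fixed law
  expect_equal(fit$intercept,
               mean(log10(d$a137_bq) + 2 * log10(d$distance_km)))
  expect_lt(fit$r_squared, 1)
  free <- distance_regression(d)
  expect_gte(free$r_squared, fit$r_squared)
})

test_that("regression input contracts are enforced", {
  expect_error(distance_regression(tibble::tibble(distance_km = c(1, 2),
                                                  a137_bq = c(1, 2))),
               "at least 3")
  expect_error(distance_regression(tibble::tibble(distance_km = c(1, 2, -3),
                                                  a137_bq = c(1, 2, 3))),
               "positive")
})

test_that("distance fits expose tidy, glance and autoplot views", {
  withr::with_seed(10, {
    d <- tibble::tibble(distance_km = runif(30, 1.6, 16.1))
    d$a137_bq <- 300 / d$distance_km^2 * 10^rnorm(30, 0, 0.5)
  })
  fit <- distance_regression(d)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "log10(distance_km)"))
  expect_equal(td$estimate[2], fit$slope)
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$nobs, 30L)
  expect_equal(gl$r.squared, fit$r_squared)
  expect_s3_class(autoplot(fit), "ggplot")
})
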