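test_that("elapsed time between dates is day-counted, year-scaled and antisymmetric", {
  expect_identical(elapsed_years("2011-03-11", "2011-03-11"), 0)
  expect_equal(elapsed_years("2011-03-11", "2016-09-29"), 2029 / 365.25)
  expect_equal(
    elapsed_years("2016-09-29", "2011-03-11"),
    -elapsed_years("2011-03-11", "2016-09-29")
  )
  # the survey's slashed date dialect parses to the same result
  expect_equal(elapsed_years("2011/3/11", "2016/9/29"), 2029 / 365.25)
  expect_error(elapsed_years("2011-03-11", "not-a-date"), "Unparseable")
})

test_that("decay factors follow the exponential law and invert exactly", {
  expect_identical(decay_factor("cs137", "2019-05-16", "2019-05-16"), 1)
  expect_equal(decay_factor("cs137", "2011-03-11", "2016-09-29"),
               exp(-log(2) * (2029 / 365.25) / 30.08))
  expect_equal(signif(decay_factor("cs137", "2011-03-11", "2016-09-29"), 3), 0.880)
  expect_equal(signif(decay_factor("cs134", "2016-09-29", "2011-03-11"), 3), 6.45)
  expect_equal(
    decay_factor("cs134", "2012-01-05", "2019-08-17") *
      decay_factor("cs134", "2019-08-17", "2012-01-05"),
    1
  )
  expect_error(half_life_years("cs136"), "Unknown nuclide")
})

test_that("decay factor is strictly decreasing in forward time", {
  dates <- as.Date("2011-03-11") + seq(0, 3000, by = 300)
  f <- decay_factor(rep("cs137", length(dates)), as.Date("2011-03-11"), dates)
  expect_true(all(diff(f) < 0))
  expect_true(all(f[-1] < 1))
})

test_that("decay correction reproduces the published worn-date to 2011 chain", {
  a <- activity(c(1.01, 0.193), c(0.01, 0.012), c("cs137", "cs134"), "2016-09-29")
  b <- decay_correct(a, "2011-03-11")
  expect_true(agrees_last_digit(b$value[1], 1.15))
  expect_true(agrees_last_digit(b$value[2], 1.25))
  expect_identical(b$ref_date, rep(as.Date("2011-03-11"), 2))
  # target equal to reference leaves the activity untouched
  expect_equal(decay_correct(a, "2016-09-29"), a)
})

test_that("decay correction round-trips to 1e-12 relative over random date pairs", {
  withr::with_seed(11, {
    for (i in 1:25) {
      d1 <- as.Date("2011-03-11") + sample.int(5000, 1)
      d2 <- as.Date("2011-03-11") + sample.int(5000, 1)
      nuc <- sample(c("cs134", "cs137"), 1)
      a <- activity(runif(1, 0.01, 100), runif(1, 0.001, 1), nuc, d1)
      back <- decay_correct(decay_correct(a, d2), d1)
      expect_equal(back$value, a$value, tolerance = 1e-12)
      expect_equal(back$sigma, a$sigma, tolerance = 1e-12)
    }
  })
})

test_that("censored activities decay-correct their detection limit and keep the flag", {
  a <- activity(NA, NA, "cs137", "2020-07-07", censored = TRUE,
                detection_limit = 0.00537)
  b <- decay_correct(a, "2011-03-11")
  expect_true(b$censored)
  expect_equal(b$detection_limit,
               0.00537 * decay_factor("cs137", "2020-07-07", "2011-03-11"))
  expect_identical(b$value, b$detection_limit)
})

test_that("isotope ratio and its uncertainty follow first-order quadrature", {
  r <- isotope_ratio(activity(1.25, 0.08, "cs134", "2011-03-11"),
                     activity(1.15, 0.01, "cs137", "2011-03-11"))
  expect_equal(signif(r$value, 4), 1.087)
  expect_equal(r$sigma,
               r$value * sqrt((0.08 / 1.25)^2 + (0.01 / 1.15)^2))
  # zero numerator sigma leaves only the denominator's relative error
  r2 <- isotope_ratio(activity(2, 0, "cs134", "2011-03-11"),
                      activity(4, 0.2, "cs137", "2011-03-11"))
  expect_equal(r2$sigma / r2$value, 0.2 / 4)
  # equal activities, zero sigmas
  r3 <- isotope_ratio(activity(1, 0, "cs134", "2011-03-11"),
                      activity(1, 0, "cs137", "2011-03-11"))
  expect_equal(r3, tibble::tibble(value = 1, sigma = 0))
})

test_that("isotope ratio rejects censored input and wrong nuclide order", {
  cens <- activity(NA, NA, "cs134", "2011-03-11", censored = TRUE,
                   detection_limit = 0.006)
  a137 <- activity(1, 0.1, "cs137", "2011-03-11")
  expect_error(isotope_ratio(cens, a137), "censored")
  expect_error(isotope_ratio(a137, a137), "cs134")
})

test_that("ratios computed at a common date undo the differential decay", {
  # same physical particle measured late: ratio at 2011 must recover 1.08
  a137_2011 <- 2.5
  worn <- as.Date("2018-06-01")
  a137 <- a137_2011 * decay_factor("cs137", "2011-03-11", worn)
  a134 <- 1.08 * a137_2011 * decay_factor("cs134", "2011-03-11", worn)
  r <- isotope_ratio(activity(a134, 0, "cs134", worn),
                     activity(a137, 0, "cs137", worn))
  expect_equal(r$value, 1.08, tolerance = 1e-12)
})

test_that("isotope_ratio_table skips censored rows instead of failing", {
  p <- reference_particles_worn()
  # worn-date table is its own reference basis here; use measurement basis
  p$ref_date <- p$measurement_date
  out <- isotope_ratio_table(p)
  expect_identical(is.na(out$ratio), p$a134_censored)
})
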