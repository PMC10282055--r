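test_that("the exposure forward model is background-correct, linear and order-free", {
  bg_only <- simulate_exposure(dim = c(48, 48), background_rate = 1,
                               exposure_min = 30, seed = 1)
  expect_equal(mean(bg_only), 30, tolerance = 0.05)
  src <- ip_sources(c(10, 30), c(30, 12), c(2, 1))
  img <- simulate_exposure(src, seed = 2)
  img2x <- simulate_exposure(src, exposure_min = 60, seed = 2)
  # expected-count field is exactly linear in exposure
  expect_equal(attr(img2x, "expected_counts"), 2 * attr(img, "expected_counts"))
  # source order does not change the field (hence not the seeded draw)
  perm <- simulate_exposure(src[2:1, ], seed = 2)
  expect_identical(unclass(img), unclass(perm))
  expect_equal(sum(attr(img, "expected_counts")), sum(attr(perm, "expected_counts")))
  expect_error(simulate_exposure(ip_sources(999, 1, 1)), "outside")
})

test_that("an insoluble source dominates its own pixel and is detected once", {
  img <- simulate_exposure(ip_sources(32, 32, 5), seed = 3)
  expect_equal(which(img == max(img), arr.ind = TRUE)[1, ],
               c(row = 32, col = 32), tolerance = 2)
  spots <- detect_hotspots(img)
  expect_equal(nrow(spots), 1L)
  expect_lt(abs(spots$centroid_row - 32), 1)
  expect_lt(abs(spots$centroid_col - 32), 1)
  expect_gte(spots$integrated_counts, spots$peak_counts)
  expect_gt(spots$symmetry, 0.5)
})

test_that("well-separated sources yield one hotspot each, strongest first", {
  img <- simulate_exposure(ip_sources(c(12, 50), c(12, 50), c(2, 6)), seed = 4)
  spots <- detect_hotspots(img)
  expect_equal(nrow(spots), 2L)
  expect_true(all(diff(spots$integrated_counts) <= 0))
  expect_lt(abs(spots$centroid_row[1] - 50), 1.5)
  expect_lt(abs(spots$centroid_row[2] - 12), 1.5)
})

test_that("background-only images rarely produce false hotspots at 5 sigma", {
  fp <- vapply(1:40, function(s) {
    nrow(detect_hotspots(simulate_exposure(dim = c(64, 64), seed = 100 + s)))
  }, integer(1))
  expect_lt(mean(fp > 0), 0.05)
})

test_that("spot symmetry separates circular particles from smeared patches", {
  sym_point <- vapply(1:15, function(s) {
    img <- simulate_exposure(ip_sources(32, 32, 5), seed = 200 + s)
    detect_hotspots(img)$symmetry[1]
  }, numeric(1))
  expect_gte(median(sym_point), 0.8)
  expect_true(all(sym_point > 0.5))
  sym_patch <- vapply(1:15, function(s) {
    img <- simulate_exposure(
      ip_sources(32, 32, 60, kind = "soluble_patch", patch_scale_px = 6,
                 patch_aspect = 3),
      seed = 300 + s
    )
    detect_hotspots(img)$symmetry[1]
  }, numeric(1))
  expect_true(all(sym_patch <= 0.5))
})

test_that("symmetry is 1 for a single pixel and invariant under 90-degree rotation", {
  m <- matrix(0, 21, 21)
  m[11, 11] <- 100
  img <- ip_image(m)
  spots <- detect_hotspots(img)
  expect_equal(spots$symmetry, 1)
  expect_equal(spots$n_pixels, 1L)
  patch <- simulate_exposure(
    ip_sources(16, 16, 60, kind = "soluble_patch", patch_aspect = 3),
    dim = c(31, 31), seed = 7
  )
  rotated <- ip_image(t(patch)[ncol(patch):1, ],
                      attr(patch, "pixel_size_mm"), attr(patch, "exposure_min"))
  s1 <- detect_hotspots(patch)$symmetry[1]
  s2 <- detect_hotspots(rotated)$symmetry[1]
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("spot_symmetry recomputes the component around a detected centroid", {
  img <- simulate_exposure(ip_sources(20, 44, 5), seed = 8)
  spots <- detect_hotspots(img)
  expect_equal(spot_symmetry(img, spots[1, ]), spots$symmetry[1])
  expect_error(spot_symmetry(img, tibble::tibble(centroid_row = 500,
                                                 centroid_col = 1)),
               "outside")
})

test_that("the isolation trace separates insoluble particles from soluble material", {
  insol <- simulate_isolation(ip_sources(16, 16, 5, solubility = 0),
                              n_sonications = 3, seed = 11)
  expect_true(all(insol$expected_net == insol$expected_net[1]))
  noise_sd <- sqrt(insol$expected_net[1] + 30 * 1024)
  expect_true(all(abs(insol$net_counts - insol$expected_net) < 5 * noise_sd))
  sol <- simulate_isolation(
    ip_sources(16, 16, 5, kind = "soluble_patch", solubility = 1),
    n_sonications = 2, seed = 12
  )
  # one sonication removes everything: nothing but background remains
  expect_lt(abs(sol$net_counts[2]), 5 * sqrt(30 * 1024))
  half <- simulate_isolation(
    ip_sources(16, 16, 5, kind = "soluble_patch", solubility = 0.5),
    n_sonications = 3, seed = 13
  )
  expect_equal(half$expected_net / half$expected_net[1], (1 / 2)^(0:3))
  expect_true(all(abs(half$net_counts - half$expected_net) <
                    5 * sqrt(half$expected_net + 30 * 1024)))
})
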