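#' Imaging-plate image container
#'
#' A 2-D grid of photo-stimulated luminescence (PSL) counts with the pixel
#' pitch and exposure time attached.  The simulated forward model also
#' attaches the noiseless expected-count field as attribute
#' `expected_counts`.
#'
#' @param counts Numeric matrix of nonnegative counts.
#' @param pixel_size_mm Pixel pitch in mm.
#' @param exposure_min Exposure time in minutes.
#' @return An `ip_image` (matrix subclass).
#' @export
ip_image <- function(counts, pixel_size_mm = 0.2, exposure_min = 30) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("PSL counts must be nonnegative.")
  stopifnot(pixel_size_mm > 0, exposure_min > 0)
  structure(counts,
            pixel_size_mm = pixel_size_mm,
            exposure_min = exposure_min,
            class = c("ip_image", class(counts)))
}

#' @export
print.ip_image <- function(x, ...) {
  cat(sprintf(
    "<ip_image> %d x %d px, %g mm/px, %g min exposure, total %g counts\n",
    nrow(x), ncol(x), attr(x, "pixel_size_mm"), attr(x, "exposure_min"),
    sum(x)
  ))
  invisible(x)
}

#' Source specifications for the imaging-plate forward model
#'
#' One row per radioactive source on the plate.  An `insoluble_particle`
#' deposits a tight isotropic (circular) point-spread; a `soluble_patch`
#' deposits a broader anisotropic profile, emulating dissolved radiocesium
#' smeared over the fabric.  `solubility` is the activity fraction removed
#' by one sonication round: ~0 for a glassy CsMP, ~1 for fully soluble
#' material.
#'
#' @param row,col Source centre in pixel coordinates.
#' @param activity_bq Source activity.
#' @param kind `"insoluble_particle"` or `"soluble_patch"`.
#' @param patch_scale_px Major-axis Gaussian scale of a soluble patch.
#' @param patch_aspect Major/minor axis ratio of a soluble patch.
#' @param solubility Fraction of activity removed per sonication.
#' @return Tibble of source specs.
#' @export
ip_sources <- function(row, col, activity_bq,
                       kind = "insoluble_particle",
                       patch_scale_px = 6, patch_aspect = 3,
                       solubility = ifelse(kind == "soluble_patch", 1, 0)) {
  stopifnot(all(activity_bq >= 0),
            all(kind %in% c("insoluble_particle", "soluble_patch")),
            all(solubility >= 0 & solubility <= 1))
  tibble(
    row = row, col = col, activity_bq = activity_bq, kind = kind,
    patch_scale_px = patch_scale_px, patch_aspect = patch_aspect,
    solubility = solubility
  )
}

# expected PSL field for one source on an nr x nc grid
source_kernel <- function(src, nr, nc, psf_sigma_px, total_counts) {
  r <- matrix(seq_len(nr), nr, nc)
  c_ <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  if (src$kind == "insoluble_particle") {
    s1 <- s2 <- psf_sigma_px
  } else {
    s1 <- src$patch_scale_px
    s2 <- src$patch_scale_px / src$patch_aspect
  }
  k <- exp(-((r - src$row)^2 / (2 * s1^2) + (c_ - src$col)^2 / (2 * s2^2)))
  total_counts * k / (2 * pi * s1 * s2)
}

#' Simulate an imaging-plate exposure
#'
#' Forward model for plate autoradiography: each source deposits its
#' expected PSL kernel (total counts `activity * psl_per_bq_min *
#' exposure`), a uniform background rate is added, and the observed image is
#' a per-pixel Poisson draw.  The noiseless expected field is kept as
#' attribute `expected_counts`, so linearity properties can be checked
#' without simulation.  Deterministic for a fixed `seed`; the expected field
#' (hence the draw) does not depend on source order.
#'
#' @param sources Tibble from [ip_sources()] (may be empty).
#' @param dim Grid size, `c(rows, cols)`.
#' @param exposure_min Exposure in minutes.
#' @param background_rate Background PSL counts per pixel per minute.
#' @param psl_per_bq_min PSL counts recorded per Bq per minute (single
#'   effective calibration scalar; no plate-fading model).
#' @param psf_sigma_px Isotropic point-spread sigma for insoluble particles.
#' @param pixel_size_mm Pixel pitch.
#' @param seed Optional integer for a reproducible draw.
#' @return An [ip_image()].
#' @examples
#' img <- simulate_exposure(ip_sources(32, 32, 2), seed = 1)
#' @export
simulate_exposure <- function(sources = ip_sources(numeric(0), numeric(0), numeric(0)),
                              dim = c(64, 64), exposure_min = 30,
                              background_rate = 1, psl_per_bq_min = 20,
                              psf_sigma_px = 1.5, pixel_size_mm = 0.2,
                              seed = NULL) {
  nr <- dim[1]
  nc <- dim[2]
  stopifnot(nr > 0, nc > 0)
  if (nrow(sources) > 0 &&
      (any(sources$row < 1 | sources$row > nr) ||
       any(sources$col < 1 | sources$col > nc))) {
    abort("Source position outside the image grid.")
  }
  expected <- matrix(background_rate * exposure_min, nr, nc)
  for (i in seq_len(nrow(sources))) {
    src <- sources[i, ]
    expected <- expected +
      source_kernel(src, nr, nc, psf_sigma_px,
                    src$activity_bq * psl_per_bq_min * exposure_min)
  }
  draw <- function() matrix(rpois(nr * nc, expected), nr, nc)
  counts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- ip_image(counts, pixel_size_mm, exposure_min)
  attr(out, "expected_counts") <- expected
  out
}

# 8-connectivity labelling of a logical matrix (iterative flood fill)
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    labels[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (p - 1L) %% nr + 1L
      c_ <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr
        cc <- c_ + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          q <- (cc - 1L) * nr + rr
          if (mask[q] && labels[q] == 0L) {
            labels[q] <- cur
            stack <- c(stack, q)
          }
        }
      }
    }
  }
  labels
}

# minor/major principal second-moment ratio of a weighted pixel set
component_symmetry <- function(rows, cols, weights) {
  if (length(rows) < 2) return(1) # single pixel: circular by convention
  w <- weights / sum(weights)
  mr <- sum(w * rows)
  mc <- sum(w * cols)
  srr <- sum(w * (rows - mr)^2)
  scc <- sum(w * (cols - mc)^2)
  src <- sum(w * (rows - mr) * (cols - mc))
  ev <- eigen(matrix(c(srr, src, src, scc), 2, 2), symmetric = TRUE)$values
  if (ev[1] <= 0) return(1)
  max(0, ev[2]) / ev[1]
}

# robust background statistics: median and MAD-based sd
background_stats <- function(image) {
  list(mean = median(image), sd = max(mad(image), sqrt(max(median(image), 1e-12))))
}

#' Detect hotspots on an imaging-plate image
#'
#' Pixels above `background mean + k_sigma * background sd` are grouped by
#' 8-neighbour connectivity; each connected component becomes one hotspot
#' with an intensity-weighted centroid, its integrated and peak counts, and
#' a circularity score (see [spot_symmetry()]).  Background statistics are
#' estimated robustly (median and MAD) so that the sources themselves do not
#' inflate the threshold.  Spots are returned sorted by integrated counts,
#' descending.
#'
#' @param image An [ip_image()].
#' @param k_sigma Threshold multiplier (default 5).
#' @return Tibble: `spot_id`, `centroid_row`, `centroid_col`, `n_pixels`,
#'   `integrated_counts`, `peak_counts`, `symmetry`.  Empty when nothing
#'   exceeds the threshold.
#' @examples
#' img <- simulate_exposure(ip_sources(20, 40, 2), seed = 1)
#' detect_hotspots(img)
#' @export
detect_hotspots <- function(image, k_sigma = 5) {
  bg <- background_stats(image)
  thresh <- bg$mean + k_sigma * bg$sd
  mask <- image > thresh
  if (!any(mask)) {
    return(tibble(
      spot_id = integer(0), centroid_row = numeric(0),
      centroid_col = numeric(0), n_pixels = integer(0),
      integrated_counts = numeric(0), peak_counts = numeric(0),
      symmetry = numeric(0)
    ))
  }
  labels <- label_components(mask)
  nr <- nrow(image)
  spots <- purrr::map_dfr(seq_len(max(labels)), function(lab) {
    px <- which(labels == lab)
    rows <- (px - 1L) %% nr + 1L
    cols <- (px - 1L) %/% nr + 1L
    w <- as.numeric(image[px])
    wex <- pmax(w - bg$mean, 0) # background-subtracted weights for moments
    if (sum(wex) == 0) wex <- w
    tibble(
      centroid_row = sum(wex * rows) / sum(wex),
      centroid_col = sum(wex * cols) / sum(wex),
      n_pixels = length(px),
      integrated_counts = sum(w),
      peak_counts = max(w),
      symmetry = component_symmetry(rows, cols, wex)
    )
  })
  spots <- dplyr::arrange(spots, dplyr::desc(.data$integrated_counts))
  spots$spot_id <- seq_len(nrow(spots))
  dplyr::relocate(spots, "spot_id")
}

#' Circularity of a detected spot
#'
#' Ratio of the minor to the major principal second moment of the
#' above-threshold component containing the spot, in `[0, 1]`: 1 is a
#' circular count distribution (the signature of a spherical glassy CsMP),
#' small values indicate the broad asymmetric smears left by soluble
#' radiocesium.  A degenerate single-pixel spot scores 1 by convention.
#' The metric is invariant under image rotation by 90 degrees.
#'
#' @param image An [ip_image()].
#' @param spot One row of the [detect_hotspots()] table (or anything with
#'   `centroid_row` / `centroid_col`).
#' @param k_sigma Threshold multiplier used to re-form the component.
#' @return Symmetry score in `[0, 1]`.
#' @export
spot_symmetry <- function(image, spot, k_sigma = 5) {
  r0 <- round(spot$centroid_row[1])
  c0 <- round(spot$centroid_col[1])
  if (r0 < 1 || r0 > nrow(image) || c0 < 1 || c0 > ncol(image)) {
    abort("Spot centroid lies outside the image.")
  }
  bg <- background_stats(image)
  mask <- image > bg$mean + k_sigma * bg$sd
  if (!mask[r0, c0]) {
    # centroid pixel itself below threshold (can happen between two lobes);
    # fall back to the nearest above-threshold pixel
    px <- which(mask)
    if (length(px) == 0) return(1)
    rows <- (px - 1L) %% nrow(image) + 1L
    cols <- (px - 1L) %/% nrow(image) + 1L
    j <- which.min((rows - r0)^2 + (cols - c0)^2)
    r0 <- rows[j]
    c0 <- cols[j]
  }
  labels <- label_components(mask)
  px <- which(labels == labels[r0, c0])
  rows <- (px - 1L) %% nrow(image) + 1L
  cols <- (px - 1L) %/% nrow(image) + 1L
  wex <- pmax(as.numeric(image[px]) - bg$mean, 0)
  if (sum(wex) == 0) wex <- as.numeric(image[px])
  component_symmetry(rows, cols, wex)
}

#' Simulate the cut-sonicate-re-image isolation workflow
#'
#' A suspected CsMP is cut from the fabric, sonicated, redeposited and
#' re-imaged; the cycle repeats.  Each sonication removes the soluble
#' fraction of the source activity, so after round `k` the expected activity
#' is `activity * (1 - solubility)^k`.  An insoluble glassy particle yields
#' a flat count trace within counting noise; fully soluble material drops to
#' background after one round.  The observation itself cannot distinguish a
#' truly soluble deposit from a brittle particle destroyed by handling or
#' self-irradiation; `solubility` is a phenomenological removal fraction,
#' not a mechanistic claim.
#'
#' @param source One-row tibble from [ip_sources()].
#' @param n_sonications Number of sonication rounds (>= 1).
#' @param exposure_min Re-imaging exposure per round.
#' @param dim,background_rate,psl_per_bq_min,psf_sigma_px Forward-model
#'   parameters, as in [simulate_exposure()].
#' @param seed Optional integer; round `k` uses `seed + k`.
#' @return Tibble with one row per round (round 0 = before sonication):
#'   `round`, `net_counts` (background-subtracted image total) and
#'   `expected_net` (noiseless expectation).
#' @export
simulate_isolation <- function(source, n_sonications = 3, exposure_min = 30,
                               dim = c(32, 32), background_rate = 1,
                               psl_per_bq_min = 20, psf_sigma_px = 1.5,
                               seed = NULL) {
  stopifnot(n_sonications >= 1, nrow(source) == 1)
  purrr::map_dfr(0:n_sonications, function(k) {
    src <- source
    src$activity_bq <- src$activity_bq * (1 - src$solubility)^k
    img <- simulate_exposure(
      src, dim = dim, exposure_min = exposure_min,
      background_rate = background_rate, psl_per_bq_min = psl_per_bq_min,
      psf_sigma_px = psf_sigma_px,
      seed = if (is.null(seed)) NULL else seed + k
    )
    bg_total <- background_rate * exposure_min * prod(dim)
    tibble(
      round = k,
      net_counts = sum(img) - bg_total,
      expected_net = sum(attr(img, "expected_counts")) - bg_total
    )
  })
}
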