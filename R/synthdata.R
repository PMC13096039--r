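# Seeded synthetic brightfield scenes of pigmented epidermis-on-a-chip wells.
#
# A scene is a bright background field (transmission imaging: the specimen
# absorbs, so melanin is dark) with elliptical melanin deposits rasterised
# into an exact ground-truth mask. "good" scenes carry many fine discrete
# micro-spots; "poor" scenes carry fewer, larger, frequently fused islands
# plus a radial ring inhomogeneity. Imaging artifacts (illumination gradient,
# defocus blur, sensor noise) act on the image only, never on the mask.

#' Specify a synthetic brightfield scene
#'
#' @param quality_label `"good"` or `"poor"`.
#' @param image_size `c(height, width)` in pixels.
#' @param pixels_per_mm Spatial calibration (> 0).
#' @param spot_count_range Integer range `c(lo, hi)` of melanin spots.
#' @param spot_radius_range_px Radius range in pixels.
#' @param fusion_probability Probability that a spot is seeded next to an
#'   existing one so the two overlap and fuse (poor phenotype only).
#' @param ring_artifact_amplitude Amplitude of the radial ring darkening.
#' @param illumination_gradient_amplitude Amplitude of the linear
#'   illumination gradient across the field.
#' @param defocus_sigma_px Gaussian defocus blur sigma (pixels).
#' @param melanin_min_intensity_drop Minimal fractional absorption of a spot,
#'   in (0, 1]. Per-spot absorption is drawn from
#'   `[drop, min(1, drop + 0.25)]`.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Integer seed; identical specs yield bit-identical samples.
#' @return A `melachip_scene_spec` list.
#' @export
scene_spec <- function(quality_label = c("good", "poor"),
                       image_size = c(256L, 256L),
                       pixels_per_mm = 100,
                       spot_count_range = c(40L, 60L),
                       spot_radius_range_px = c(2, 4),
                       fusion_probability = 0,
                       ring_artifact_amplitude = 0,
                       illumination_gradient_amplitude = 0.05,
                       defocus_sigma_px = 0.8,
                       melanin_min_intensity_drop = 0.35,
                       noise_sd = 0.01,
                       seed = 1L) {
  quality_label <- match.arg(quality_label)
  abort_if(any(image_size <= 0), "image size must be positive")
  abort_if(pixels_per_mm <= 0, "pixels_per_mm must be positive")
  abort_if(max(spot_radius_range_px) > min(image_size) / 2,
           "radius range exceeds image half-extent")
  abort_if(fusion_probability < 0 || fusion_probability > 1,
           "fusion_probability must be in [0,1]")
  abort_if(melanin_min_intensity_drop <= 0 || melanin_min_intensity_drop > 1,
           "melanin_min_intensity_drop must be in (0,1]")
  structure(list(
    quality_label = quality_label,
    image_size = as.integer(image_size),
    pixels_per_mm = pixels_per_mm,
    spot_count_range = as.integer(spot_count_range),
    spot_radius_range_px = as.numeric(spot_radius_range_px),
    fusion_probability = fusion_probability,
    ring_artifact_amplitude = ring_artifact_amplitude,
    illumination_gradient_amplitude = illumination_gradient_amplitude,
    defocus_sigma_px = defocus_sigma_px,
    melanin_min_intensity_drop = melanin_min_intensity_drop,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "melachip_scene_spec")
}

#' Preset scene specifications for the two phenotypes
#'
#' The good phenotype uses many fine discrete micro-spots (no fusion, no ring
#' artifact); the poor phenotype uses fewer but much larger islands with a
#' high fusion probability and a radial ring inhomogeneity. Spot counts scale
#' with image area so the foreground fraction is size-independent.
#'
#' @param quality `"good"` or `"poor"`.
#' @param image_size `c(height, width)` in pixels.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [scene_spec()].
#' @return A `melachip_scene_spec`.
#' @export
synth_preset <- function(quality = c("good", "poor"),
                         image_size = c(256L, 256L), seed = 1L, ...) {
  quality <- match.arg(quality)
  area_scale <- prod(image_size) / (256 * 256)
  base <- if (quality == "good") {
    list(
      quality_label = "good",
      spot_count_range = pmax(1L, as.integer(round(c(40, 60) * area_scale))),
      spot_radius_range_px = c(2, 4),
      fusion_probability = 0,
      ring_artifact_amplitude = 0,
      illumination_gradient_amplitude = 0.05,
      defocus_sigma_px = 0.8,
      melanin_min_intensity_drop = 0.35,
      noise_sd = 0.01
    )
  } else {
    list(
      quality_label = "poor",
      spot_count_range = pmax(1L, as.integer(round(c(10, 18) * area_scale))),
      spot_radius_range_px = c(7, 16),
      fusion_probability = 0.6,
      ring_artifact_amplitude = 0.08,
      illumination_gradient_amplitude = 0.08,
      defocus_sigma_px = 1.0,
      melanin_min_intensity_drop = 0.45,
      noise_sd = 0.01
    )
  }
  args <- modifyList(c(base, list(image_size = image_size, seed = seed)),
                     list(...))
  do.call(scene_spec, args)
}

# Rasterise one ellipse with the pixel-centre-inside rule; returns logical
# matrix restricted work to the bounding box for speed.
rasterize_ellipse <- function(h, w, cy, cx, ry, rx, theta) {
  mask <- matrix(FALSE, h, w)
  rmax <- max(ry, rx)
  y0 <- max(1L, floor(cy - rmax)); y1 <- min(h, ceiling(cy + rmax))
  x0 <- max(1L, floor(cx - rmax)); x1 <- min(w, ceiling(cx + rmax))
  if (y0 > y1 || x0 > x1) return(mask)
  ys <- seq(y0, y1); xs <- seq(x0, x1)
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  ct <- cos(theta); st <- sin(theta)
  u <- dy * ct + dx * st
  v <- -dy * st + dx * ct
  mask[y0:y1, x0:x1] <- (u / ry)^2 + (v / rx)^2 <= 1
  mask
}

#' Generate one synthetic brightfield sample
#'
#' Artifact order: (1) background + illumination gradient, (2) multiplicative
#' melanin absorption, (3) radial ring modulation, (4) Gaussian defocus blur,
#' (5) additive Gaussian noise, (6) clip to \[0,1\]. Absorption belongs to the
#' specimen, blur and noise to the optics/sensor, so the mask reflects only
#' step (2).
#'
#' @param spec A [scene_spec()].
#' @return A `melachip_sample`: list with `image` (matrix in \[0,1\]), `mask`
#'   (0/1 matrix), `label`, `spec`, and `spots` (tibble of the sampled
#'   ellipse parameters, usable as an independent rasterisation oracle).
#' @export
generate_sample <- function(spec) {
  abort_if(!inherits(spec, "melachip_scene_spec"), "`spec` must be a scene_spec")
  h <- spec$image_size[1]; w <- spec$image_size[2]
  withr::with_seed(spec$seed, {
    # (1) background field
    bg0 <- 0.82
    dir <- runif(1, 0, 2 * pi)
    gy <- (seq_len(h) / h - 0.5); gx <- (seq_len(w) / w - 0.5)
    grad <- outer(gy, rep(1, w)) * cos(dir) + outer(rep(1, h), gx) * sin(dir)
    bg <- bg0 * (1 + spec$illumination_gradient_amplitude * grad)

    # (2) melanin spots
    n_spots <- if (diff(spec$spot_count_range) == 0) spec$spot_count_range[1] else
      sample(seq(spec$spot_count_range[1], spec$spot_count_range[2]), 1)
    spots <- list()
    mask <- matrix(0L, h, w)
    absorb <- matrix(0, h, w)
    for (i in seq_len(n_spots)) {
      r <- runif(1, spec$spot_radius_range_px[1], spec$spot_radius_range_px[2])
      fuse_draw <- runif(1)
      if (length(spots) > 0 && fuse_draw < spec$fusion_probability) {
        anchor <- spots[[sample(length(spots), 1)]]
        ang <- runif(1, 0, 2 * pi)
        d <- runif(1, 0.3, 0.9) * (anchor$r + r)
        cy <- anchor$cy + d * cos(ang)
        cx <- anchor$cx + d * sin(ang)
      } else {
        cy <- runif(1, 1 + r, h - r)
        cx <- runif(1, 1 + r, w - r)
      }
      cy <- min(max(cy, 1), h); cx <- min(max(cx, 1), w)
      ecc <- runif(1, 0.8, 1.25)
      theta <- runif(1, 0, pi)
      drop <- runif(1, spec$melanin_min_intensity_drop,
                    min(1, spec$melanin_min_intensity_drop + 0.25))
      ell <- rasterize_ellipse(h, w, cy, cx, r * ecc, r / ecc, theta)
      mask[ell] <- 1L
      absorb[ell] <- pmax(absorb[ell], drop)
      spots[[length(spots) + 1]] <- list(cy = cy, cx = cx, r = r, ecc = ecc,
                                         theta = theta, drop = drop)
    }
    img <- bg * (1 - absorb)

    # (3) radial ring modulation (poor phenotype inhomogeneity)
    if (spec$ring_artifact_amplitude > 0) {
      ry <- (seq_len(h) - (h + 1) / 2) / (h / 2)
      rx <- (seq_len(w) - (w + 1) / 2) / (w / 2)
      rad <- sqrt(outer(ry^2, rep(1, w)) + outer(rep(1, h), rx^2))
      img <- img * (1 - spec$ring_artifact_amplitude * pmin(rad, 1)^3)
    }

    # (4) defocus, (5) noise, (6) clip
    img <- gaussian_blur(img, spec$defocus_sigma_px)
    if (spec$noise_sd > 0) img <- img + rnorm(length(img), 0, spec$noise_sd)
    img <- clamp01(img)

    spots_tbl <- if (length(spots) == 0) {
      tibble::tibble(cy = numeric(), cx = numeric(), r = numeric(),
                     ecc = numeric(), theta = numeric(), drop = numeric())
    } else {
      dplyr::bind_rows(lapply(spots, tibble::as_tibble))
    }
    structure(list(image = img, mask = mask, label = spec$quality_label,
                   spec = spec, spots = spots_tbl),
              class = "melachip_sample")
  })
}

#' Generate a labelled cohort of synthetic samples
#'
#' Sample `k` (1-based over the whole cohort, good samples first) uses seed
#' `base_seed + k`, so cohorts are reproducible and order-deterministic.
#'
#' @param n_good,n_poor Non-negative counts per class.
#' @param base_seed Integer root seed.
#' @param image_size Passed to [synth_preset()].
#' @param good_args,poor_args Named lists of preset overrides.
#' @return List of `melachip_sample` objects, good samples first.
#' @export
generate_cohort <- function(n_good, n_poor, base_seed = 1L,
                            image_size = c(256L, 256L),
                            good_args = list(), poor_args = list()) {
  abort_if(n_good < 0 || n_poor < 0, "counts must be non-negative")
  labels <- c(rep("good", n_good), rep("poor", n_poor))
  purrr::imap(labels, function(lab, k) {
    args <- if (lab == "good") good_args else poor_args
    spec <- do.call(synth_preset,
                    c(list(quality = lab, image_size = image_size,
                           seed = base_seed + k), args))
    generate_sample(spec)
  })
}

#' Write a cohort to disk (16-bit TIFF images, 0/255 PNG masks, manifest CSV)
#'
#' @param samples List of `melachip_sample`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest tibble.
#' @export
write_cohort <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::imap(samples, function(s, k) {
    id <- sprintf("sample_%03d", k)
    write_image(s$image, file.path(dir, paste0(id, ".tiff")))
    write_mask(s$mask, file.path(dir, paste0(id, "_mask.png")))
    tibble::tibble(sample_id = id, label = s$label, seed = s$spec$seed,
                   height = nrow(s$image), width = ncol(s$image),
                   pixels_per_mm = s$spec$pixels_per_mm,
                   n_spots = nrow(s$spots))
  })
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @export
print.melachip_sample <- function(x, ...) {
  cat(sprintf("<melachip_sample> %dx%d, label: %s, foreground: %.2f%%\n",
              nrow(x$image), ncol(x$image), x$label, 100 * mean(x$mask)))
  invisible(x)
}
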