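# Melanin patch morphometry: connected components, areas, transmittance and
# optical density. Intensities are read from the loaded [0,1] image on its
# original scale (not the network's normalised scale).

#' Extract melanin patches from a binary mask
#'
#' Connected components under 4- or 8-connectivity; components smaller than
#' `min_patch_size` pixels are discarded (single-pixel noise suppression).
#' Patches are ordered by the top-left corner of their bounding box.
#'
#' @param mask 0/1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @param min_patch_size Minimum component area in pixels (default 5).
#' @param image Optional aligned intensity matrix; adds `mean_intensity`.
#' @param pixels_per_mm Optional calibration; adds `area_mm2`.
#' @return Tibble with one row per patch: `patch_id`, `area_px`,
#'   (`area_mm2`), (`mean_intensity`), `centroid_row`, `centroid_col`,
#'   `bbox_r0`, `bbox_c0`, `bbox_r1`, `bbox_c1`. The filtered, relabelled
#'   component matrix is attached as attribute `"label_matrix"`.
#' @export
extract_patches <- function(mask, connectivity = 8L, min_patch_size = 5L,
                            image = NULL, pixels_per_mm = NULL) {
  check_mask(mask)
  abort_if(!connectivity %in% c(4L, 8L), "connectivity must be 4 or 8")
  if (!is.null(image)) check_same_dim(mask, image, "image and mask")
  lab <- cpp_label_components(matrix(as.integer(mask), nrow(mask), ncol(mask)),
                              as.integer(connectivity))
  empty <- tibble::tibble(
    patch_id = integer(), area_px = integer(), centroid_row = numeric(),
    centroid_col = numeric(), bbox_r0 = integer(), bbox_c0 = integer(),
    bbox_r1 = integer(), bbox_c1 = integer()
  )
  if (max(lab) == 0L) {
    attr(empty, "label_matrix") <- lab
    return(empty)
  }
  fg <- which(lab > 0L)
  comp <- lab[fg]
  rows <- ((fg - 1L) %% nrow(mask)) + 1L
  cols <- ((fg - 1L) %/% nrow(mask)) + 1L
  stats <- tibble::tibble(comp = comp, row = rows, col = cols)
  stats <- dplyr::summarise(dplyr::group_by(stats, .data$comp),
    area_px = dplyr::n(),
    centroid_row = mean(.data$row), centroid_col = mean(.data$col),
    bbox_r0 = min(.data$row), bbox_c0 = min(.data$col),
    bbox_r1 = max(.data$row), bbox_c1 = max(.data$col),
    .groups = "drop")
  if (!is.null(image)) {
    means <- tapply(image[fg], comp, mean)
    stats$mean_intensity <- as.numeric(means[as.character(stats$comp)])
  }
  stats <- dplyr::filter(stats, .data$area_px >= min_patch_size)
  stats <- dplyr::arrange(stats, .data$bbox_r0, .data$bbox_c0)
  keep <- stats$comp
  relab <- matrix(0L, nrow(mask), ncol(mask))
  new_id <- match(comp, keep)
  ok <- !is.na(new_id)
  relab[fg[ok]] <- new_id[ok]
  stats$patch_id <- seq_len(nrow(stats))
  stats$comp <- NULL
  if (!is.null(pixels_per_mm)) {
    stats$area_mm2 <- stats$area_px / pixels_per_mm^2
  }
  stats <- dplyr::relocate(stats, "patch_id")
  attr(stats, "label_matrix") <- relab
  stats
}

#' Total and mean melanin patch area
#'
#' `A_total = sum(A_i)`; `A_mean = A_total / N`. An empty patch list returns
#' 0 for both with a warning (division-by-zero guard).
#'
#' @param patches Tibble from [extract_patches()] (or any tibble with
#'   `area_px`).
#' @param unit `"px"` or `"mm2"` (requires `area_mm2` column).
#' @return Numeric scalar.
#' @export
total_area <- function(patches, unit = c("px", "mm2")) {
  unit <- match.arg(unit)
  areas <- patch_areas(patches, unit)
  if (length(areas) == 0) {
    rlang::warn("no patches; total area is 0")
    return(0)
  }
  sum(areas)
}

#' @rdname total_area
#' @export
mean_area <- function(patches, unit = c("px", "mm2")) {
  unit <- match.arg(unit)
  areas <- patch_areas(patches, unit)
  if (length(areas) == 0) {
    rlang::warn("no patches; mean area is 0")
    return(0)
  }
  mean(areas)
}

patch_areas <- function(patches, unit) {
  col <- if (unit == "px") "area_px" else "area_mm2"
  abort_if(!col %in% names(patches), paste0("missing column ", col))
  patches[[col]]
}

#' Estimate the background (reference) light intensity I0
#'
#' Strategy `"complement"` averages intensity over mask-background pixels
#' after excluding a border margin (the well periphery can be cell-free blank
#' plate, which would bias the reference). Strategy `"region"` averages over
#' a caller-supplied control-region mask.
#'
#' @param image Intensity matrix in \[0,1\].
#' @param mask 0/1 melanin mask.
#' @param strategy `"complement"` or `"region"`.
#' @param border_margin Fraction of each dimension to exclude (default 0.02).
#' @param region 0/1 matrix marking the control region (for `"region"`).
#' @return Scalar I0.
#' @export
estimate_background <- function(image, mask,
                                strategy = c("complement", "region"),
                                border_margin = 0.02, region = NULL) {
  check_image(image); check_mask(mask)
  check_same_dim(image, mask, "image and mask")
  strategy <- match.arg(strategy)
  if (strategy == "region") {
    abort_if(is.null(region), "strategy 'region' needs a control region mask")
    check_same_dim(image, region, "image and region")
    abort_if(sum(region) == 0, "empty control region")
    return(mean(image[region == 1]))
  }
  h <- nrow(image); w <- ncol(image)
  my <- floor(border_margin * h); mx <- floor(border_margin * w)
  inner <- matrix(FALSE, h, w)
  inner[(my + 1L):(h - my), (mx + 1L):(w - mx)] <- TRUE
  bg <- inner & mask == 0
  abort_if(sum(bg) == 0, "empty background")
  mean(image[bg])
}

patch_pixel_values <- function(image, patches) {
  lab <- attr(patches, "label_matrix")
  if (is.null(lab)) {
    rlang::abort("patches must come from extract_patches() (label matrix missing)")
  }
  check_same_dim(image, lab, "image and patch labels")
  image[lab > 0L]
}

#' Transmittance of the melanin patch region
#'
#' `T = I / I0 * 100` where I is the mean intensity over the pooled union of
#' patch pixels. With no patches the value is undefined and `NA` is returned
#' with a warning.
#'
#' @param image Intensity matrix.
#' @param patches Tibble from [extract_patches()].
#' @param i0 Background intensity (> 0), e.g. [estimate_background()].
#' @return Transmittance in percent.
#' @export
transmittance <- function(image, patches, i0) {
  abort_if(i0 <= 0, "I0 must be positive")
  if (nrow(patches) == 0) {
    rlang::warn("no patches; transmittance undefined")
    return(NA_real_)
  }
  mean(patch_pixel_values(image, patches)) / i0 * 100
}

#' Optical density of the melanin patch region
#'
#' `OD = -log10(I / I0)`; I is clamped at a small epsilon so fully black
#' patches stay finite. Higher OD means heavier pigment.
#'
#' @inheritParams transmittance
#' @param eps Lower clamp for I (default 1e-6).
#' @return Optical density (unitless).
#' @export
optical_density <- function(image, patches, i0, eps = 1e-6) {
  abort_if(i0 <= 0, "I0 must be positive")
  if (nrow(patches) == 0) {
    rlang::warn("no patches; optical density undefined")
    return(NA_real_)
  }
  i <- max(mean(patch_pixel_values(image, patches)), eps)
  -log10(i / i0)
}

#' Quantify one sample: the four melanin deposition indicators
#'
#' Composes patch extraction, area statistics, background estimation,
#' transmittance and optical density into one record.
#'
#' @param image Intensity matrix in \[0,1\].
#' @param mask 0/1 melanin mask.
#' @param sample_id Identifier for the output row.
#' @param connectivity,min_patch_size Passed to [extract_patches()].
#' @param pixels_per_mm Optional calibration for mm^2 areas.
#' @param border_margin Passed to [estimate_background()].
#' @return One-row tibble: `sample_id`, `n_patches`, `a_total_px`,
#'   (`a_total_mm2`), `a_mean_px`, `transmittance_pct`, `optical_density`,
#'   `i0`.
#' @export
quantify_sample <- function(image, mask, sample_id = "sample",
                            connectivity = 8L, min_patch_size = 5L,
                            pixels_per_mm = NULL, border_margin = 0.02) {
  patches <- extract_patches(mask, connectivity, min_patch_size,
                             image = image, pixels_per_mm = pixels_per_mm)
  i0 <- estimate_background(image, mask, border_margin = border_margin)
  n <- nrow(patches)
  a_tot <- suppressWarnings(total_area(patches))
  a_mean <- suppressWarnings(mean_area(patches))
  t_pct <- suppressWarnings(transmittance(image, patches, i0))
  od <- suppressWarnings(optical_density(image, patches, i0))
  out <- tibble::tibble(
    sample_id = sample_id, n_patches = n,
    a_total_px = a_tot, a_mean_px = a_mean,
    transmittance_pct = t_pct, optical_density = od, i0 = i0
  )
  if (!is.null(pixels_per_mm)) {
    out$a_total_mm2 <- a_tot / pixels_per_mm^2
  }
  out
}

#' Quantify a cohort of samples
#'
#' @param samples List of `melachip_sample` (or lists with `image`, `mask`,
#'   optionally `label`).
#' @param ... Passed to [quantify_sample()].
#' @return Tibble with one row per sample (plus `label` when available).
#' @export
quantify_cohort <- function(samples, ...) {
  rows <- purrr::imap(samples, function(s, k) {
    row <- quantify_sample(s$image, s$mask,
                           sample_id = sprintf("sample_%03d", k), ...)
    if (!is.null(s$label)) row$label <- s$label
    row
  })
  dplyr::bind_rows(rows)
}
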