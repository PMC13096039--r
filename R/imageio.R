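# Image and annotation I/O, dataset splitting, annotation QC, focus stacking.
#
# Mask file dialect: single-channel PNG, 0 = background, 255 = foreground;
# the loader maps 255 -> 1. Coordinates are row-major, origin top-left,
# 1-based inside R (exported JSON/CSV uses the annotation tools' 0-based
# pixel coordinates).

LUMA_WEIGHTS <- c(0.299, 0.587, 0.114) # ITU-R BT.601 luminance

#' Load a brightfield image as a grayscale matrix in \[0,1\]
#'
#' PNG and TIFF are read natively, JPG when the `jpeg` package is present;
#' RGB inputs are collapsed by BT.601 luminance weighting
#' (0.299 R + 0.587 G + 0.114 B).
#'
#' @param path File path (.png, .tif/.tiff, .jpg/.jpeg).
#' @return Numeric matrix in \[0,1\].
#' @export
load_image <- function(path) {
  abort_if(!file.exists(path), paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      abort_if(!requireNamespace("jpeg", quietly = TRUE),
               "reading JPG requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    rlang::abort(paste0("unsupported image format: .", ext))
  )
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3]
    img <- if (nch >= 3) {
      img[, , 1] * LUMA_WEIGHTS[1] + img[, , 2] * LUMA_WEIGHTS[2] +
        img[, , 3] * LUMA_WEIGHTS[3]
    } else {
      img[, , 1]
    }
  }
  clamp01(img)
}

#' Write an intensity image (16-bit TIFF or PNG by extension)
#' @param img Matrix in \[0,1\]. @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path) {
  check_image(img)
  ext <- tolower(tools::file_ext(path))
  img <- clamp01(img)
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
    rlang::abort(paste0("unsupported image format: .", ext))
  )
  invisible(path)
}

#' Load / write binary masks (PNG, 0 = background, 255 = foreground)
#' @param path PNG path.
#' @return 0/1 integer matrix.
#' @export
load_mask <- function(path) {
  m <- load_image(path)
  out <- matrix(as.integer(m >= 0.5), nrow(m), ncol(m))
  out
}

#' @rdname load_mask
#' @param mask 0/1 matrix.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

# Even-odd point-in-polygon (crossing number) for pixel centres.
# px/py are 0-based pixel-centre coordinates matching LabelMe exports.
points_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((poly_y[i] > py) != (poly_y[j] > py))
    if (any(crosses)) {
      xint <- poly_x[i] + (py - poly_y[i]) *
        (poly_x[j] - poly_x[i]) / (poly_y[j] - poly_y[i])
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

#' Rasterise LabelMe polygon annotations to a binary mask
#'
#' All polygons become class 1 (overlaps union); everything else class 0.
#' A pixel is foreground when its centre lies inside the polygon (even-odd
#' rule). Out-of-bounds vertices are clipped with a warning; polygons with
#' fewer than 3 points are an error.
#'
#' @param path LabelMe JSON file.
#' @param image_size `c(height, width)` of the target mask.
#' @return 0/1 integer matrix.
#' @export
import_labelme <- function(path, image_size) {
  abort_if(!file.exists(path), paste0("file not found: ", path))
  h <- as.integer(image_size[1]); w <- as.integer(image_size[2])
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mask <- matrix(0L, h, w)
  shapes <- doc$shapes %||% list()
  for (shape in shapes) {
    pts <- do.call(rbind, lapply(shape$points, unlist))
    abort_if(is.null(pts) || nrow(pts) < 3,
             "polygon must have at least 3 points")
    xs <- pts[, 1]; ys <- pts[, 2]
    if (any(xs < 0 | xs > w | ys < 0 | ys > h)) {
      rlang::warn("polygon coordinates outside image bounds; clipping")
      xs <- pmin(pmax(xs, 0), w)
      ys <- pmin(pmax(ys, 0), h)
    }
    x0 <- max(1L, floor(min(xs) + 0.5) + 1L)
    x1 <- min(w, ceiling(max(xs) + 0.5))
    y0 <- max(1L, floor(min(ys) + 0.5) + 1L)
    y1 <- min(h, ceiling(max(ys) + 0.5))
    if (x0 > x1 || y0 > y1) next
    # pixel (r, c) 1-based has centre (c - 0.5, r - 0.5) in LabelMe coords
    grid <- expand.grid(r = y0:y1, c = x0:x1)
    inside <- points_in_polygon(grid$c - 0.5, grid$r - 0.5, xs, ys)
    mask[cbind(grid$r, grid$c)[inside, , drop = FALSE]] <- 1L
  }
  mask
}

#' Inter-annotator agreement quality control
#'
#' Pixel-wise IoU between two annotators' masks; agreement passes when
#' IoU >= 0.80 (an image below 80% goes back for senior re-evaluation).
#'
#' @param mask_a,mask_b 0/1 matrices of equal dimensions.
#' @return List with `iou` and `pass`.
#' @export
interannotator_qc <- function(mask_a, mask_b) {
  check_mask(mask_a, "mask_a"); check_mask(mask_b, "mask_b")
  check_same_dim(mask_a, mask_b, "masks")
  inter <- sum(mask_a == 1 & mask_b == 1)
  union <- sum(mask_a == 1 | mask_b == 1)
  iou <- if (union == 0) 1.0 else inter / union
  list(iou = iou, pass = iou >= 0.80)
}

#' Per-sample train/validation/test split (50/20/30)
#'
#' Sample ids are shuffled with `seed` and partitioned at `floor(0.5 n)` and
#' `floor(0.7 n)`; the remainder goes to test. All images of one sample id
#' land in exactly one subset.
#'
#' @param sample_ids Character or integer vector of unique ids (>= 3).
#' @param seed Integer seed.
#' @return A `melachip_split`: list of `train_ids`, `val_ids`, `test_ids`,
#'   `fractions`, `seed`.
#' @export
split_dataset <- function(sample_ids, seed = 1L) {
  ids <- unique(sample_ids)
  abort_if(length(ids) < 3, "need at least 3 unique sample ids")
  shuffled <- withr::with_seed(seed, sample(ids))
  n <- length(ids)
  n_train <- floor(0.5 * n)
  n_trval <- floor(0.7 * n)
  structure(list(
    train_ids = shuffled[seq_len(n_train)],
    val_ids = shuffled[seq(n_train + 1L, n_trval)],
    test_ids = shuffled[seq(n_trval + 1L, n)],
    fractions = c(train = 0.5, val = 0.2, test = 0.3),
    seed = as.integer(seed)
  ), class = "melachip_split")
}

#' @export
print.melachip_split <- function(x, ...) {
  cat(sprintf("<melachip_split> train %d / val %d / test %d (seed %d)\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids),
              x$seed))
  invisible(x)
}

#' Write / read a dataset split as JSON
#' @param split A `melachip_split`. @param path JSON path.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(list(train_ids = x$train_ids, val_ids = x$val_ids,
                 test_ids = x$test_ids,
                 fractions = unlist(x$fractions), seed = as.integer(x$seed)),
            class = "melachip_split")
}

#' Focus stacking by per-pixel sharpness selection
#'
#' For each pixel the plane with the highest local Laplacian energy (mean of
#' squared 4-neighbour Laplacian over a `window` x `window` box) is selected.
#' Ties go to the lowest plane index; a single plane is returned unchanged.
#'
#' @param planes List of equally sized intensity matrices (>= 1).
#' @param window Odd window size for the local energy (default 9).
#' @return Composite matrix.
#' @export
focus_stack <- function(planes, window = 9L) {
  abort_if(length(planes) == 0, "need at least one plane")
  purrr::walk(planes, check_image)
  d <- dim(planes[[1]])
  purrr::walk(planes, function(p) check_same_dim(planes[[1]], p, "planes"))
  if (length(planes) == 1L) return(planes[[1]])
  energies <- lapply(planes, function(p) box_mean(laplacian(p)^2, window))
  best <- matrix(1L, d[1], d[2])
  best_e <- energies[[1]]
  for (i in seq_along(planes)[-1]) {
    better <- energies[[i]] > best_e # strict: ties keep lowest index
    best[better] <- i
    best_e[better] <- energies[[i]][better]
  }
  out <- planes[[1]]
  for (i in seq_along(planes)[-1]) {
    sel <- best == i
    out[sel] <- planes[[i]][sel]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
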