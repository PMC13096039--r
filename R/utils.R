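# Shared helpers: argument checks, image resizing, Gaussian blur.
# Images are plain numeric matrices (rows = y, cols = x), intensities in [0,1].
# Masks are 0/1 matrices of the same shape.

abort_if <- function(cond, msg) {
  if (cond) rlang::abort(msg)
}

check_image <- function(img, arg = "image") {
  abort_if(!is.matrix(img) || !is.numeric(img), paste0("`", arg, "` must be a numeric matrix"))
  abort_if(length(img) == 0L, paste0("`", arg, "` is empty"))
  invisible(img)
}

check_mask <- function(mask, arg = "mask") {
  check_image(mask, arg)
  vals <- unique(as.vector(mask))
  abort_if(!all(vals %in% c(0, 1)), paste0("`", arg, "` must be binary (0/1)"))
  invisible(mask)
}

check_same_dim <- function(a, b, what = "inputs") {
  abort_if(!identical(dim(a), dim(b)), paste0(what, " must have identical dimensions"))
  invisible(NULL)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Resize a 2D intensity grid
#'
#' Bilinear interpolation for continuous images, nearest-neighbour for masks.
#' Coordinates follow the pixel-centre convention: output pixel centres are
#' mapped linearly onto the input grid.
#'
#' @param img Numeric matrix.
#' @param size Target `c(height, width)`.
#' @param method `"bilinear"` or `"nearest"`.
#' @return A numeric matrix of dimension `size`.
#' @export
resize_image <- function(img, size, method = c("bilinear", "nearest")) {
  check_image(img)
  method <- match.arg(method)
  h0 <- nrow(img); w0 <- ncol(img)
  h1 <- as.integer(size[1]); w1 <- as.integer(size[2])
  abort_if(h1 <= 0L || w1 <= 0L, "target size must be positive")
  if (h0 == h1 && w0 == w1) return(img)
  # map output pixel centres to input coordinates
  ys <- (seq_len(h1) - 0.5) * h0 / h1 + 0.5
  xs <- (seq_len(w1) - 0.5) * w0 / w1 + 0.5
  if (method == "nearest") {
    yi <- pmin(pmax(round(ys), 1L), h0)
    xi <- pmin(pmax(round(xs), 1L), w0)
    return(img[yi, xi, drop = FALSE])
  }
  y0 <- pmin(pmax(floor(ys), 1L), h0); y1 <- pmin(y0 + 1L, h0)
  x0 <- pmin(pmax(floor(xs), 1L), w0); x1 <- pmin(x0 + 1L, w0)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  a <- img[y0, x0, drop = FALSE] * (1 - fy) + img[y1, x0, drop = FALSE] * fy
  b <- img[y0, x1, drop = FALSE] * (1 - fy) + img[y1, x1, drop = FALSE] * fy
  a * rep(1 - fx, each = h1) + b * rep(fx, each = h1)
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  g / sum(g)
}

#' Gaussian blur of a 2D image (separable, edge-replicated)
#'
#' @param img Numeric matrix.
#' @param sigma Standard deviation in pixels; `sigma <= 0` returns the input.
#' @return Blurred matrix of the same dimensions.
#' @export
gaussian_blur <- function(img, sigma) {
  check_image(img)
  if (sigma <= 0) return(img)
  g <- gaussian_kernel_1d(sigma)
  r <- (length(g) - 1L) / 2L
  pad_idx <- function(n) pmin(pmax(seq(1 - r, n + r), 1L), n)
  # rows pass
  tmp <- img[pad_idx(nrow(img)), , drop = FALSE]
  tmp <- apply_1d_conv(tmp, g, nrow(img))
  # cols pass (transpose trick)
  tmp <- t(tmp)[pad_idx(ncol(img)), , drop = FALSE]
  t(apply_1d_conv(tmp, g, ncol(img)))
}

apply_1d_conv <- function(padded, g, n_out) {
  k <- length(g)
  out <- matrix(0, n_out, ncol(padded))
  for (i in seq_len(k)) {
    out <- out + g[i] * padded[seq_len(n_out) + (i - 1L), , drop = FALSE]
  }
  out
}

# Local box mean via cumulative sums (used by focus stacking).
box_mean <- function(img, window) {
  r <- (window - 1L) %/% 2L
  n <- nrow(img); m <- ncol(img)
  idx <- function(len) pmin(pmax(seq(1 - r, len + r), 1L), len)
  p <- img[idx(n), idx(m), drop = FALSE]
  cs <- apply(apply(p, 2, cumsum), 1, cumsum) # transposed cumsum matrix
  cs <- t(cs)
  # padded integral image lookup
  np <- nrow(p); mp <- ncol(p)
  S <- matrix(0, np + 1L, mp + 1L)
  S[-1, -1] <- cs
  w <- 2L * r + 1L
  r1 <- seq_len(n); c1 <- seq_len(m)
  (S[r1 + w, c1 + w, drop = FALSE] - S[r1, c1 + w, drop = FALSE] -
     S[r1 + w, c1, drop = FALSE] + S[r1, c1, drop = FALSE]) / (w * w)
}

# 4-neighbour Laplacian with replicated edges.
laplacian <- function(img) {
  n <- nrow(img); m <- ncol(img)
  up <- img[c(1L, seq_len(n - 1L)), , drop = FALSE]
  dn <- img[c(seq_len(n - 1L) + 1L, n), , drop = FALSE]
  lf <- img[, c(1L, seq_len(m - 1L)), drop = FALSE]
  rt <- img[, c(seq_len(m - 1L) + 1L, m), drop = FALSE]
  up + dn + lf + rt - 4 * img
}
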