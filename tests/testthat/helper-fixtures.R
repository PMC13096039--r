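# Shared in-code fixtures: tiny images, masks and model configs.

# a flat image with a dark rectangular patch
fixture_patch_image <- function(h = 32, w = 32, bg = 0.8, fg = 0.4,
                                rows = 10:15, cols = 8:14) {
  img <- matrix(bg, h, w)
  mask <- matrix(0L, h, w)
  img[rows, cols] <- fg
  mask[rows, cols] <- 1L
  list(image = img, mask = mask)
}

# micro network config for fast exact tests (16x16 input, 4 tokens)
fixture_micro_config <- function(dropout = 0) {
  memvit_config(image_size = c(16L, 16L), patch_size = 8L, embed_dim = 8L,
                depth = 4L, num_heads = 2L, mlp_ratio = 2,
                skip_layers = 1:4, skip_channels = 4L, raw_channels = 3L,
                decoder_channels = c(6L, 5L, 4L, 3L), dropout_rate = dropout)
}

# brute-force point-in-polygon oracle (even-odd rule over pixel centres)
oracle_polygon_mask <- function(h, w, xs, ys) {
  mask <- matrix(0L, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      px <- c - 0.5; py <- r - 0.5
      crossings <- 0
      n <- length(xs)
      j <- n
      for (i in seq_len(n)) {
        if ((ys[i] > py) != (ys[j] > py)) {
          xint <- xs[i] + (py - ys[i]) * (xs[j] - xs[i]) / (ys[j] - ys[i])
          if (px < xint) crossings <- crossings + 1
        }
        j <- i
      }
      if (crossings %% 2 == 1) mask[r, c] <- 1L
    }
  }
  mask
}

write_labelme_json <- function(path, shapes, h, w) {
  doc <- list(
    version = "5.0.1",
    imageHeight = h, imageWidth = w,
    shapes = lapply(shapes, function(pts) {
      list(label = "melanin", shape_type = "polygon",
           points = lapply(seq_len(nrow(pts)), function(i) {
             list(pts[i, 1], pts[i, 2])
           }))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  path
}
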