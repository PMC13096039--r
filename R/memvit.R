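# MEM-ViT: a ViT encoder with global self-attention feeding a U-shaped
# multi-branch decoder with five skip connections - four from intermediate
# transformer layers (tokens reshaped to spatial grids, each refined by two
# 3x3 conv + BN + ReLU blocks) and one from the raw input image (two 3x3
# conv + BN + ReLU at full resolution). Transposed convolutions double the
# spatial resolution at every decoder stage until the patch scale is undone,
# and the head emits a per-pixel sigmoid probability.

#' MEM-ViT network configuration
#'
#' The decoder needs `log2(patch_size)` doubling stages to return from the
#' token grid to pixel resolution; config construction enforces that
#' `patch_size` is a power of two and that `image_size` is divisible by it.
#' The four transformer skip taps default to evenly spaced quarters of the
#' encoder depth. `binarize_threshold` is the probability cutoff (strictly
#' greater-than) used when producing binary masks.
#'
#' @param image_size `c(H, W)`, both divisible by `patch_size`.
#' @param patch_size Patch edge in pixels (power of two).
#' @param embed_dim Token embedding width (divisible by `num_heads`).
#' @param depth Number of transformer layers.
#' @param num_heads Attention heads.
#' @param mlp_ratio Hidden width of the token MLP as a multiple of
#'   `embed_dim`.
#' @param skip_layers Four strictly increasing transformer layer indices
#'   feeding the decoder skips.
#' @param skip_channels Channels of each processed transformer skip branch.
#' @param raw_channels Channels of the raw-image skip branch.
#' @param decoder_channels Length `log2(patch_size) + 1` vector: channels at
#'   the token-resolution fusion and after each doubling stage.
#' @param dropout_rate Dropout at the end of the encoder and the beginning
#'   of the decoder (training mode only).
#' @param binarize_threshold Probability threshold for mask binarisation.
#' @return A `memvit_config`.
#' @export
memvit_config <- function(image_size = c(256L, 256L), patch_size = 16L,
                          embed_dim = 768L, depth = 12L, num_heads = 12L,
                          mlp_ratio = 4, skip_layers = NULL,
                          skip_channels = 64L, raw_channels = 16L,
                          decoder_channels = c(256L, 128L, 64L, 32L, 16L),
                          dropout_rate = 0.5, binarize_threshold = 0.45) {
  k <- as.integer(round(log2(patch_size)))
  abort_if(2^k != patch_size, "patch_size must be a power of two")
  abort_if(any(image_size %% patch_size != 0),
           "image_size must be divisible by patch_size")
  abort_if(embed_dim %% num_heads != 0,
           "embed_dim must be divisible by num_heads")
  if (is.null(skip_layers)) {
    skip_layers <- unique(pmax(1L, as.integer(round(depth * (1:4) / 4))))
  }
  abort_if(length(skip_layers) != 4 || any(diff(skip_layers) <= 0) ||
             max(skip_layers) > depth,
           "skip_layers must be 4 strictly increasing layer indices <= depth")
  abort_if(length(decoder_channels) != k + 1L,
           sprintf("decoder_channels must have length %d (log2(patch)+1)", k + 1L))
  abort_if(dropout_rate < 0 || dropout_rate >= 1, "dropout_rate must be in [0,1)")
  structure(list(
    image_size = as.integer(image_size), patch_size = as.integer(patch_size),
    embed_dim = as.integer(embed_dim), depth = as.integer(depth),
    num_heads = as.integer(num_heads), mlp_ratio = mlp_ratio,
    skip_layers = as.integer(skip_layers),
    skip_channels = as.integer(skip_channels),
    raw_channels = as.integer(raw_channels),
    decoder_channels = as.integer(decoder_channels),
    dropout_rate = dropout_rate, binarize_threshold = binarize_threshold,
    n_stages = k
  ), class = "memvit_config")
}

#' Small MEM-ViT preset for CPU-scale experiments
#'
#' Patch 8, depth 4, embedding 64, 4 heads, narrow decoder, dropout 0.1
#' (the full-scale dropout of 0.5 is sized for ~1000-image datasets; on
#' small synthetic cohorts a lighter rate keeps optimisation stable).
#'
#' @param image_size `c(H, W)` divisible by 8.
#' @param ... Overrides passed to [memvit_config()].
#' @return A `memvit_config`.
#' @export
memvit_tiny <- function(image_size = c(128L, 128L), ...) {
  args <- modifyList(list(
    image_size = image_size, patch_size = 8L, embed_dim = 64L, depth = 4L,
    num_heads = 4L, mlp_ratio = 2, skip_layers = 1:4, skip_channels = 16L,
    raw_channels = 4L, decoder_channels = c(32L, 32L, 16L, 8L),
    dropout_rate = 0.1
  ), list(...))
  do.call(memvit_config, args)
}

# Which transformer skip branches (1..4, in encoder order) fuse at each
# decoder point. Point 0 is the token-resolution fusion with the final
# tokens; points 1..k-1 sit after each doubling stage; point k is the
# raw-image branch. Deeper taps fuse at coarser resolution; when there are
# fewer points than taps the deepest taps share point 0.
skip_assignment <- function(cfg) {
  k <- cfg$n_stages
  deepest_first <- rev(seq_len(4))
  pts <- vector("list", k)
  if (k >= 4) {
    for (j in 1:4) pts[[j]] <- deepest_first[j]
  } else {
    n0 <- 4L - (k - 1L)
    pts[[1]] <- deepest_first[seq_len(n0)]
    for (j in seq_len(k - 1L)) pts[[j + 1L]] <- deepest_first[n0 + j]
  }
  pts
}

rand_mat <- function(n, m, sd) matrix(rnorm(n * m, 0, sd), n, m)

conv_init <- function(c_in, c_out, k = 3L) {
  rand_mat(c_in * k * k, c_out, sqrt(2 / (c_in * k * k)))
}

#' Initialise a MEM-ViT model state
#'
#' Transformer weights use a 0.02-sd normal initialisation, convolutions a
#' He initialisation; batch-norm buffers start at (0, 1).
#'
#' @param config A [memvit_config()].
#' @param seed Integer seed.
#' @return A `melachip_model` (config, params, batch-norm buffers, counters).
#' @export
memvit_init <- function(config, seed = 1L) {
  abort_if(!inherits(config, "memvit_config"), "`config` must be a memvit_config")
  cfg <- config
  D <- cfg$embed_dim; p <- cfg$patch_size
  nh <- cfg$image_size[1] %/% p; nw <- cfg$image_size[2] %/% p
  np <- nh * nw
  Dm <- as.integer(round(D * cfg$mlp_ratio))
  Cs <- cfg$skip_channels; Cr <- cfg$raw_channels
  dc <- cfg$decoder_channels; k <- cfg$n_stages
  withr::with_seed(seed, {
    P <- list(
      pe_W = rand_mat(p * p, D, 0.02), pe_b = numeric(D),
      pos = rand_mat(np, D, 0.02),
      encf_g = rep(1, D), encf_b = numeric(D)
    )
    for (l in seq_len(cfg$depth)) {
      pre <- paste0("L", l, "_")
      P[[paste0(pre, "ln1_g")]] <- rep(1, D)
      P[[paste0(pre, "ln1_b")]] <- numeric(D)
      for (nm in c("Wq", "Wk", "Wv", "Wo")) P[[paste0(pre, nm)]] <- rand_mat(D, D, 0.02)
      for (nm in c("bq", "bk", "bv", "bo")) P[[paste0(pre, nm)]] <- numeric(D)
      P[[paste0(pre, "ln2_g")]] <- rep(1, D)
      P[[paste0(pre, "ln2_b")]] <- numeric(D)
      P[[paste0(pre, "m_W1")]] <- rand_mat(D, Dm, 0.02)
      P[[paste0(pre, "m_b1")]] <- numeric(Dm)
      P[[paste0(pre, "m_W2")]] <- rand_mat(Dm, D, 0.02)
      P[[paste0(pre, "m_b2")]] <- numeric(D)
    }
    bufs <- list()
    add_bn <- function(P, bufs, name, c_out) {
      P[[paste0(name, "_bng")]] <- rep(1, c_out)
      P[[paste0(name, "_bnb")]] <- numeric(c_out)
      bufs[[name]] <- list(mean = numeric(c_out), var = rep(1, c_out))
      list(P = P, bufs = bufs)
    }
    for (j in 1:4) {
      P[[sprintf("S%d_c1_W", j)]] <- conv_init(D, Cs)
      P[[sprintf("S%d_c1_b", j)]] <- numeric(Cs)
      r <- add_bn(P, bufs, sprintf("S%d_c1", j), Cs); P <- r$P; bufs <- r$bufs
      P[[sprintf("S%d_c2_W", j)]] <- conv_init(Cs, Cs)
      P[[sprintf("S%d_c2_b", j)]] <- numeric(Cs)
      r <- add_bn(P, bufs, sprintf("S%d_c2", j), Cs); P <- r$P; bufs <- r$bufs
    }
    P[["R_c1_W"]] <- conv_init(1L, Cr); P[["R_c1_b"]] <- numeric(Cr)
    r <- add_bn(P, bufs, "R_c1", Cr); P <- r$P; bufs <- r$bufs
    P[["R_c2_W"]] <- conv_init(Cr, Cr); P[["R_c2_b"]] <- numeric(Cr)
    r <- add_bn(P, bufs, "R_c2", Cr); P <- r$P; bufs <- r$bufs

    assign0 <- skip_assignment(cfg)
    c_in0 <- D + length(assign0[[1]]) * Cs
    P[["D0_W"]] <- conv_init(c_in0, dc[1]); P[["D0_b"]] <- numeric(dc[1])
    r <- add_bn(P, bufs, "D0", dc[1]); P <- r$P; bufs <- r$bufs
    for (j in seq_len(k)) {
      c_prev <- dc[j]
      P[[sprintf("U%d_W", j)]] <- rand_mat(c_prev, 4L * dc[j + 1],
                                           sqrt(2 / c_prev))
      P[[sprintf("U%d_b", j)]] <- numeric(dc[j + 1])
      extra <- if (j == k) Cr else length(assign0[[j + 1]] %||% integer()) * Cs
      P[[sprintf("F%d_W", j)]] <- conv_init(dc[j + 1] + extra, dc[j + 1])
      P[[sprintf("F%d_b", j)]] <- numeric(dc[j + 1])
      r <- add_bn(P, bufs, sprintf("F%d", j), dc[j + 1]); P <- r$P; bufs <- r$bufs
    }
    P[["head_W"]] <- rand_mat(dc[k + 1], 1L, sqrt(2 / dc[k + 1]))
    # start the head at the logit of a ~10% melanin prevalence prior, so
    # early training is not spent unlearning a 50% foreground guess
    P[["head_b"]] <- stats::qlogis(0.1)
    structure(list(config = cfg, params = P, buffers = bufs,
                   epochs_completed = 0L, seed = as.integer(seed)),
              class = "melachip_model")
  })
}

#' @export
print.melachip_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<melachip_model> MEM-ViT %dx%d patch %d depth %d embed %d (%s params), %d epochs trained\n",
    x$config$image_size[1], x$config$image_size[2], x$config$patch_size,
    x$config$depth, x$config$embed_dim, format(n_par, big.mark = ","),
    x$epochs_completed))
  invisible(x)
}

# Gather index turning a batch pixel vector (HWB) into the (np*B) x p^2
# token-content matrix.
patch_idx <- function(cfg, B) {
  h <- cfg$image_size[1]; w <- cfg$image_size[2]; p <- cfg$patch_size
  idx_memo(sprintf("patch_%d_%d_%d_%d", h, w, p, B), function() {
    nh <- h %/% p; nw <- w %/% p; np <- nh * nw
    gy <- rep.int(seq_len(nh), nw * B)
    gx <- rep.int(rep(seq_len(nw), each = nh), B)
    b <- rep(seq_len(B), each = np)
    idx <- matrix(0L, np * B, p * p)
    for (ox in seq_len(p)) {
      for (oy in seq_len(p)) {
        y <- (gy - 1L) * p + oy
        x <- (gx - 1L) * p + ox
        idx[, oy + (ox - 1L) * p] <- y + (x - 1L) * h + (b - 1L) * h * w
      }
    }
    idx
  })
}

# ---- forward pass -------------------------------------------------------

# imgs: (H*W*B) x 1 matrix of normalised intensities.
encoder_fwd <- function(imgs, state, B, training) {
  cfg <- state$config; P <- state$params
  np <- prod(cfg$image_size %/% cfg$patch_size)
  pidx <- patch_idx(cfg, B)
  Xp <- matrix(imgs[pidx], nrow(pidx), ncol(pidx))
  emb <- nn_linear(Xp, P$pe_W, P$pe_b)
  X <- emb$out + P$pos[rep(seq_len(np), B), , drop = FALSE]
  caches <- list(emb = emb, pidx = pidx, np = np)
  layer_caches <- vector("list", cfg$depth)
  skips <- list()
  for (l in seq_len(cfg$depth)) {
    pre <- paste0("L", l, "_")
    ln1 <- nn_layernorm(X, P[[paste0(pre, "ln1_g")]], P[[paste0(pre, "ln1_b")]])
    att_caches <- vector("list", B)
    att_out <- matrix(0, nrow(X), ncol(X))
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * np + 1L):(b * np)
      a <- mhsa_fwd(ln1$out[rows, , drop = FALSE],
                    P[[paste0(pre, "Wq")]], P[[paste0(pre, "bq")]],
                    P[[paste0(pre, "Wk")]], P[[paste0(pre, "bk")]],
                    P[[paste0(pre, "Wv")]], P[[paste0(pre, "bv")]],
                    P[[paste0(pre, "Wo")]], P[[paste0(pre, "bo")]],
                    cfg$num_heads)
      att_out[rows, ] <- a$out
      att_caches[[b]] <- a$cache
    }
    X <- X + att_out
    ln2 <- nn_layernorm(X, P[[paste0(pre, "ln2_g")]], P[[paste0(pre, "ln2_b")]])
    m1 <- nn_linear(ln2$out, P[[paste0(pre, "m_W1")]], P[[paste0(pre, "m_b1")]])
    ge <- nn_gelu(m1$out)
    m2 <- nn_linear(ge$out, P[[paste0(pre, "m_W2")]], P[[paste0(pre, "m_b2")]])
    X <- X + m2$out
    layer_caches[[l]] <- list(ln1 = ln1$cache, att = att_caches,
                              ln2 = ln2$cache, m1 = m1$cache, ge = ge$cache,
                              m2 = m2$cache)
    if (l %in% cfg$skip_layers) {
      skips[[match(l, cfg$skip_layers)]] <- X
    }
  }
  lnf <- nn_layernorm(X, P$encf_g, P$encf_b)
  drp <- nn_dropout(lnf$out, cfg$dropout_rate, training)
  caches$layers <- layer_caches
  caches$lnf <- lnf$cache
  caches$drop <- drp$cache
  list(tokens = drp$out, skips = skips, caches = caches)
}

conv_bn_relu <- function(X, state, name, h, w, B, training, ctx) {
  P <- state$params
  cv <- nn_conv(X, P[[paste0(name, "_W")]], P[[paste0(name, "_b")]], h, w, B)
  bn <- nn_batchnorm(cv$out, P[[paste0(name, "_bng")]],
                     P[[paste0(name, "_bnb")]], state$buffers[[name]],
                     training)
  rl <- nn_relu(bn$out)
  ctx$bufs[[name]] <- bn$bufs
  ctx$caches[[name]] <- list(conv = cv$cache, bn = bn$cache, relu = rl$cache)
  rl$out
}

conv_bn_relu_bw <- function(dout, grads, state, name, ctx) {
  ch <- ctx$caches[[name]]
  d1 <- nn_relu_bw(dout, ch$relu)
  d2 <- nn_batchnorm_bw(d1, ch$bn)
  grads[[paste0(name, "_bng")]] <- d2$dg
  grads[[paste0(name, "_bnb")]] <- d2$db
  d3 <- nn_conv_bw(d2$dx, ch$conv)
  grads[[paste0(name, "_W")]] <- d3$dW
  grads[[paste0(name, "_b")]] <- d3$db
  list(dx = d3$dx, grads = grads)
}

decoder_fwd <- function(tokens, skips, imgs, state, B, training) {
  cfg <- state$config; P <- state$params
  p <- cfg$patch_size; k <- cfg$n_stages
  nh <- cfg$image_size[1] %/% p; nw <- cfg$image_size[2] %/% p
  assign0 <- skip_assignment(cfg)
  ctx <- new.env(parent = emptyenv())
  ctx$bufs <- state$buffers
  ctx$caches <- list()

  # transformer skip branches, refined at token resolution
  skip_feats <- vector("list", 4)
  for (j in 1:4) {
    s1 <- conv_bn_relu(skips[[j]], state, sprintf("S%d_c1", j), nh, nw, B,
                       training, ctx)
    skip_feats[[j]] <- conv_bn_relu(s1, state, sprintf("S%d_c2", j), nh, nw,
                                    B, training, ctx)
  }
  # raw-image branch at full resolution
  r1 <- conv_bn_relu(imgs, state, "R_c1", cfg$image_size[1],
                     cfg$image_size[2], B, training, ctx)
  raw_feat <- conv_bn_relu(r1, state, "R_c2", cfg$image_size[1],
                           cfg$image_size[2], B, training, ctx)

  # token-resolution fusion
  x <- do.call(cbind, c(list(tokens), skip_feats[assign0[[1]]]))
  ctx$d0_in_channels <- c(ncol(tokens),
                          vapply(skip_feats[assign0[[1]]], ncol, integer(1)))
  x <- conv_bn_relu(x, state, "D0", nh, nw, B, training, ctx)
  dd <- nn_dropout(x, cfg$dropout_rate, training)
  ctx$caches$d0_drop <- dd$cache
  x <- dd$out

  h <- nh; w <- nw
  for (j in seq_len(k)) {
    tc <- nn_tconv2(x, P[[sprintf("U%d_W", j)]], P[[sprintf("U%d_b", j)]],
                    h, w, B)
    ctx$caches[[sprintf("U%d", j)]] <- tc$cache
    h <- 2L * h; w <- 2L * w
    u <- tc$out
    if (j == k) {
      fuse_in <- cbind(u, raw_feat)
      ctx[[sprintf("fuse%d_channels", j)]] <- c(ncol(u), ncol(raw_feat))
    } else {
      taps <- assign0[[j + 1]] %||% integer()
      ups <- lapply(taps, function(t) {
        up <- nn_upnearest(skip_feats[[t]], 2L^j, nh, nw, B)
        ctx$caches[[sprintf("up_s%d_j%d", t, j)]] <- up$cache
        up$out
      })
      fuse_in <- do.call(cbind, c(list(u), ups))
      ctx[[sprintf("fuse%d_channels", j)]] <-
        c(ncol(u), vapply(ups, ncol, integer(1)))
    }
    x <- conv_bn_relu(fuse_in, state, sprintf("F%d", j), h, w, B, training, ctx)
  }
  hd <- nn_linear(x, P$head_W, P$head_b)
  sg <- nn_sigmoid(hd$out)
  ctx$caches$head <- hd$cache
  ctx$caches$sig <- sg$cache
  list(prob = sg$out, ctx = ctx)
}

# Full forward. Returns per-pixel probabilities in pixel-row form plus the
# context needed for the backward pass.
memvit_fwd <- function(imgs, state, B, training = FALSE) {
  enc <- encoder_fwd(imgs, state, B, training)
  dec <- decoder_fwd(enc$tokens, enc$skips, imgs, state, B, training)
  list(prob = dec$prob, enc = enc, dec = dec)
}

# ---- public operations --------------------------------------------------

#' Normalise an image for the network
#'
#' Per-image min-max to \[0,1\] followed by a fixed standardisation
#' (`(x - 0.5) / 0.25`), so inputs are comparable across acquisitions.
#'
#' @param img Intensity matrix.
#' @return Normalised matrix.
#' @export
normalize_image <- function(img) {
  check_image(img)
  r <- range(img)
  if (diff(r) > 0) img <- (img - r[1]) / (r[2] - r[1])
  (img - 0.5) / 0.25
}

tokens_to_grid <- function(tok, nh, nw) {
  array(tok, dim = c(nh, nw, ncol(tok)))
}

#' Encode an image into transformer tokens and skip features
#'
#' Runs the ViT encoder on one image (which must match the configured input
#' size) and returns the final token grid plus the four intermediate-layer
#' token grids that feed the decoder skips, each reshaped to the spatial
#' token resolution.
#'
#' @param image Intensity matrix of the configured size.
#' @param state A `melachip_model`.
#' @return List with `tokens` (nh x nw x embed array) and `skips` (list of
#'   four such arrays).
#' @export
encode <- function(image, state) {
  cfg <- state$config
  abort_if(!identical(dim(image), as.integer(cfg$image_size)),
           "image dimensions must equal config$image_size (resize first)")
  imgs <- matrix(as.vector(normalize_image(image)), ncol = 1)
  enc <- encoder_fwd(imgs, state, 1L, training = FALSE)
  nh <- cfg$image_size[1] %/% cfg$patch_size
  nw <- cfg$image_size[2] %/% cfg$patch_size
  list(tokens = tokens_to_grid(enc$tokens, nh, nw),
       skips = lapply(enc$skips, tokens_to_grid, nh = nh, nw = nw))
}

#' Fuse an upsampled decoder feature grid with a skip feature grid
#'
#' Channel-wise concatenation followed by a 3x3 convolution, normalisation
#' and ReLU. Spatial dimensions are preserved.
#'
#' @param upsampled,skip Arrays `(h, w, C)` with equal spatial dimensions.
#' @param W Convolution weights `((C_up + C_skip) * 9) x C_out`; defaults to
#'   a He-initialised matrix (seeded) for ad-hoc use.
#' @param b Bias vector (default zeros).
#' @return Array `(h, w, C_out)`.
#' @export
fuse <- function(upsampled, skip, W = NULL, b = NULL) {
  du <- dim(upsampled); ds <- dim(skip)
  abort_if(length(du) != 3 || length(ds) != 3, "inputs must be (h, w, C) arrays")
  abort_if(!identical(du[1:2], ds[1:2]), "spatial dimensions must match")
  c_in <- du[3] + ds[3]
  if (is.null(W)) W <- withr::with_seed(1L, conv_init(c_in, max(du[3], 1L)))
  abort_if(nrow(W) != c_in * 9L, "W must have (C_up + C_skip) * 9 rows")
  c_out <- ncol(W)
  if (is.null(b)) b <- numeric(c_out)
  X <- cbind(matrix(upsampled, prod(du[1:2]), du[3]),
             matrix(skip, prod(ds[1:2]), ds[3]))
  cv <- nn_conv(X, W, b, du[1], du[2], 1L)
  # instance normalisation + ReLU for the functional form
  z <- scale(cv$out, center = TRUE, scale = FALSE)
  sds <- sqrt(colMeans(z^2) + 1e-5)
  z <- sweep(z, 2, sds, "/")
  array(pmax(z, 0), dim = c(du[1], du[2], c_out))
}

#' Predict a per-pixel melanin probability map
#'
#' The image is resized (bilinear) to the configured input size if needed,
#' normalised, passed through the network in inference mode, and the
#' probability map is returned at the network's native resolution.
#'
#' @param image Intensity matrix.
#' @param state A `melachip_model`.
#' @return Probability matrix at the configured network size.
#' @export
predict_prob <- function(image, state) {
  check_image(image)
  cfg <- state$config
  if (!identical(dim(image), as.integer(cfg$image_size))) {
    image <- resize_image(image, cfg$image_size, "bilinear")
  }
  imgs <- matrix(as.vector(normalize_image(image)), ncol = 1)
  out <- memvit_fwd(imgs, state, 1L, training = FALSE)
  matrix(out$prob, cfg$image_size[1], cfg$image_size[2])
}

#' Binarise a probability map
#'
#' Probability strictly greater than the threshold maps to 1; a probability
#' exactly at the threshold maps to 0.
#'
#' @param prob Probability matrix in \[0,1\].
#' @param threshold Cutoff (default 0.45).
#' @return 0/1 integer matrix of the same dimensions.
#' @export
binarize <- function(prob, threshold = 0.45) {
  check_image(prob, "prob")
  matrix(as.integer(prob > threshold), nrow(prob), ncol(prob))
}

#' Segment melanin in a brightfield image
#'
#' Resizes internally to the network size, thresholds the probability map at
#' the configured binarisation threshold (strictly greater-than), and
#' resizes the mask back (nearest-neighbour) so the output dimensions equal
#' the input dimensions exactly.
#'
#' @param image Intensity matrix (any size).
#' @param state A `melachip_model`.
#' @param threshold Optional override of `config$binarize_threshold`.
#' @return 0/1 integer matrix with `dim(image)`.
#' @export
segment <- function(image, state, threshold = NULL) {
  check_image(image)
  threshold <- threshold %||% state$config$binarize_threshold
  prob <- predict_prob(image, state)
  mask <- binarize(prob, threshold)
  if (!identical(dim(mask), dim(image))) {
    mask <- resize_image(mask, dim(image), "nearest")
    mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  }
  mask
}

#' Save / load a model checkpoint (single-file archive)
#'
#' @param state A `melachip_model`. @param path Destination path.
#' @export
save_model <- function(state, path) {
  state$format_version <- 1L
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  state <- readRDS(path)
  abort_if(!inherits(state, "melachip_model"), "not a melachip model checkpoint")
  state
}
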