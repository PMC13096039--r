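# Training: augmentation ops, the composite Dice + weighted-BCE loss, and
# the Adam optimisation loop with plateau LR decay and early stopping.

#' Training configuration
#'
#' Defaults follow the published protocol: Adam with initial learning rate
#' 1e-3, beta1 = 0.9, beta2 = 0.99; a 50% learning-rate decay when the
#' validation loss has not decreased for 10 consecutive epochs; batch size
#' 8; at most 200 epochs with early stopping; BCE positive-class weight 0.5.
#' The loss mixing weight `lambda_weight` (BCE share; Dice gets
#' `1 - lambda`) defaults to 0.5.
#'
#' @param lambda_weight BCE share of the composite loss, in \[0,1\].
#' @param bce_positive_weight Weight multiplying the positive-class log term.
#' @param learning_rate,adam_beta1,adam_beta2 Adam hyperparameters.
#' @param lr_decay_factor Multiplier applied on a validation plateau.
#' @param lr_patience_epochs Epochs without val-loss improvement before decay.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param early_stop_patience Epochs without val improvement before stopping.
#' @param augmentations List of [augment_op()] (possibly empty).
#' @param eps Dice smoothing / log clamping constant.
#' @param seed Integer seed controlling shuffling, augmentation and dropout.
#' @return A `melachip_train_config`.
#' @export
train_config <- function(lambda_weight = 0.5, bce_positive_weight = 0.5,
                         learning_rate = 1e-3, adam_beta1 = 0.9,
                         adam_beta2 = 0.99, lr_decay_factor = 0.5,
                         lr_patience_epochs = 10L, batch_size = 8L,
                         max_epochs = 200L, early_stop_patience = 20L,
                         augmentations = list(), eps = 1e-6, seed = 1L) {
  abort_if(lambda_weight < 0 || lambda_weight > 1, "lambda must be in [0,1]")
  structure(list(
    lambda_weight = lambda_weight, bce_positive_weight = bce_positive_weight,
    learning_rate = learning_rate, adam_beta1 = adam_beta1,
    adam_beta2 = adam_beta2, lr_decay_factor = lr_decay_factor,
    lr_patience_epochs = as.integer(lr_patience_epochs),
    batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
    early_stop_patience = as.integer(early_stop_patience),
    augmentations = augmentations, eps = eps, seed = as.integer(seed)
  ), class = "melachip_train_config")
}

#' Describe one augmentation operation
#'
#' Geometric kinds (`flip`, `rotate`, `translate`, `random_crop`, `elastic`)
#' transform image and mask identically (mask via nearest-neighbour, so it
#' stays binary); photometric kinds (`intensity_contrast`, `color_jitter`)
#' touch the image only.
#'
#' @param kind One of `"flip"`, `"rotate"`, `"translate"`, `"random_crop"`,
#'   `"intensity_contrast"`, `"color_jitter"`, `"elastic"`.
#' @param probability Application probability.
#' @param ... Kind-specific parameters: `direction` ("horizontal"/
#'   "vertical") for flip; `quarter_turns` for rotate; `max_shift_px` for
#'   translate; `crop_fraction`
#'   for random_crop; `max_gain`, `max_bias`, `max_gamma_log` for the
#'   photometric ops; `alpha` (displacement px) and `sigma` (field
#'   smoothness) for elastic.
#' @return An `augment_op` list.
#' @export
augment_op <- function(kind, probability = 0.5, ...) {
  kinds <- c("flip", "rotate", "translate", "random_crop",
             "intensity_contrast", "color_jitter", "elastic")
  abort_if(!kind %in% kinds,
           paste0("unknown augmentation kind: ", kind))
  structure(list(kind = kind, probability = probability,
                 parameters = list(...)), class = "melachip_augment_op")
}

#' Default augmentation stack
#'
#' Random flips, 90-degree rotations, small translations, mild intensity /
#' contrast jitter, and gentle elastic deformation.
#'
#' @return List of [augment_op()].
#' @export
default_augmentations <- function() {
  list(
    augment_op("flip", 0.5),
    augment_op("rotate", 0.5),
    augment_op("translate", 0.3, max_shift_px = 8L),
    augment_op("intensity_contrast", 0.5, max_gain = 0.15, max_bias = 0.05),
    augment_op("elastic", 0.2, alpha = 4, sigma = 8)
  )
}

apply_flip <- function(img, mask, direction) {
  if (direction == "horizontal") {
    list(image = img[, rev(seq_len(ncol(img))), drop = FALSE],
         mask = mask[, rev(seq_len(ncol(mask))), drop = FALSE])
  } else {
    list(image = img[rev(seq_len(nrow(img))), , drop = FALSE],
         mask = mask[rev(seq_len(nrow(mask))), , drop = FALSE])
  }
}

# counter-clockwise rotation by k*90 degrees; (r,c) -> (n-c+1, r) for k=1
rot90 <- function(m, k) {
  k <- k %% 4
  if (k == 0) return(m)
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

apply_translate <- function(img, mask, dy, dx, fill) {
  h <- nrow(img); w <- ncol(img)
  out_i <- matrix(fill, h, w); out_m <- matrix(0L, h, w)
  src_r <- seq_len(h) - dy; src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1 & src_r <= h; ok_c <- src_c >= 1 & src_c <= w
  out_i[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out_m[ok_r, ok_c] <- mask[src_r[ok_r], src_c[ok_c], drop = FALSE]
  list(image = out_i, mask = out_m)
}

apply_elastic <- function(img, mask, alpha, sigma) {
  if (alpha == 0) return(list(image = img, mask = mask))
  h <- nrow(img); w <- ncol(img)
  dy <- gaussian_blur(matrix(runif(h * w, -1, 1), h, w), sigma) * alpha
  dx <- gaussian_blur(matrix(runif(h * w, -1, 1), h, w), sigma) * alpha
  ys <- pmin(pmax(row(img) + dy, 1), h)
  xs <- pmin(pmax(col(img) + dx, 1), w)
  # bilinear sample for the image, nearest for the mask
  y0 <- pmin(floor(ys), h - 1); x0 <- pmin(floor(xs), w - 1)
  fy <- ys - y0; fx <- xs - x0
  at <- function(m, r, c) m[cbind(as.vector(r), as.vector(c))]
  vals <- (1 - fy) * (1 - fx) * at(img, y0, x0) +
    fy * (1 - fx) * at(img, y0 + 1, x0) +
    (1 - fy) * fx * at(img, y0, x0 + 1) +
    fy * fx * at(img, y0 + 1, x0 + 1)
  img2 <- matrix(vals, h, w)
  mask2 <- matrix(at(mask, round(ys), round(xs)), h, w)
  list(image = img2, mask = mask2)
}

apply_crop_resize <- function(img, mask, frac) {
  h <- nrow(img); w <- ncol(img)
  ch <- max(2L, round(frac * h)); cw <- max(2L, round(frac * w))
  abort_if(ch > h || cw > w, "crop size larger than image")
  r0 <- sample(h - ch + 1L, 1L); c0 <- sample(w - cw + 1L, 1L)
  ci <- img[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L), drop = FALSE]
  cm <- mask[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L), drop = FALSE]
  m2 <- resize_image(cm, c(h, w), "nearest")
  list(image = resize_image(ci, c(h, w), "bilinear"),
       mask = matrix(as.integer(m2), h, w))
}

#' Apply an augmentation stack to an image/mask pair
#'
#' Deterministic given `seed`; the mask stays binary and geometric
#' consistency between image and mask is preserved.
#'
#' @param image Intensity matrix.
#' @param mask 0/1 matrix.
#' @param ops List of [augment_op()].
#' @param seed Integer seed.
#' @return List with `image` and `mask`.
#' @export
augment <- function(image, mask, ops, seed = 1L) {
  check_image(image); check_mask(mask)
  check_same_dim(image, mask, "image and mask")
  withr::with_seed(seed, {
    cur <- list(image = image, mask = mask)
    for (op in ops) {
      if (runif(1) >= op$probability) next
      pp <- op$parameters
      cur <- switch(op$kind,
        flip = {
          dirn <- pp$direction %||% sample(c("horizontal", "vertical"), 1)
          apply_flip(cur$image, cur$mask, dirn)
        },
        rotate = {
          kk <- pp$quarter_turns %||% sample(0:3, 1)
          if (nrow(cur$image) != ncol(cur$image) && kk %% 2 == 1) kk <- 2L
          list(image = rot90(cur$image, kk), mask = rot90(cur$mask, kk))
        },
        translate = {
          s <- pp$max_shift_px %||% 8L
          apply_translate(cur$image, cur$mask, sample(-s:s, 1), sample(-s:s, 1),
                          fill = median(cur$image))
        },
        random_crop = apply_crop_resize(cur$image, cur$mask,
                                        pp$crop_fraction %||% 0.8),
        intensity_contrast = ,
        color_jitter = {
          gain <- 1 + runif(1, -1, 1) * (pp$max_gain %||% 0.15)
          bias <- runif(1, -1, 1) * (pp$max_bias %||% 0.05)
          gam <- exp(runif(1, -1, 1) * (pp$max_gamma_log %||% 0))
          list(image = clamp01(clamp01(cur$image * gain + bias)^gam),
               mask = cur$mask)
        },
        elastic = apply_elastic(cur$image, cur$mask, pp$alpha %||% 4,
                                pp$sigma %||% 8)
      )
      cur$mask <- matrix(as.integer(cur$mask), nrow(cur$mask), ncol(cur$mask))
    }
    cur
  })
}

#' Composite segmentation loss: weighted BCE plus Dice
#'
#' `total = lambda * bce + (1 - lambda) * dice` with
#' `bce = mean(-(w_pos * y * log p + (1 - y) * log(1 - p)))` (predictions
#' clamped to `[eps, 1 - eps]`) and
#' `dice = 1 - (2 * sum(p y) + eps) / (sum(p) + sum(y) + eps)`.
#'
#' @param pred Probability map (matrix or vector, values in \[0,1\]).
#' @param target Binary mask of the same shape.
#' @param cfg A [train_config()] (uses `lambda_weight`,
#'   `bce_positive_weight`, `eps`).
#' @return List with `total`, `bce`, `dice`, `lambda_weight`.
#' @export
composite_loss <- function(pred, target, cfg = train_config()) {
  abort_if(length(pred) != length(target), "pred/target size mismatch")
  p <- as.vector(pred); y <- as.vector(target)
  eps <- cfg$eps; wp <- cfg$bce_positive_weight; lam <- cfg$lambda_weight
  pc <- pmin(pmax(p, eps), 1 - eps)
  bce <- mean(-(wp * y * log(pc) + (1 - y) * log(1 - pc)))
  dice <- 1 - (2 * sum(p * y) + eps) / (sum(p) + sum(y) + eps)
  list(total = lam * bce + (1 - lam) * dice, bce = bce, dice = dice,
       lambda_weight = lam)
}

# Gradient of the composite loss wrt the predicted probabilities.
composite_loss_grad <- function(pred, target, cfg) {
  p <- as.vector(pred); y <- as.vector(target)
  eps <- cfg$eps; wp <- cfg$bce_positive_weight; lam <- cfg$lambda_weight
  n <- length(p)
  pc <- pmin(pmax(p, eps), 1 - eps)
  inside <- (p > eps) & (p < 1 - eps)
  dbce <- (-(wp * y / pc) + (1 - y) / (1 - pc)) / n
  dbce[!inside] <- 0
  sp <- sum(p); sy <- sum(y); spy <- sum(p * y)
  denom <- sp + sy + eps
  ddice <- -(2 * y * denom - (2 * spy + eps)) / denom^2
  matrix(lam * dbce + (1 - lam) * ddice, ncol = 1)
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, b1, b2, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# Plateau learning-rate schedule: starting from lr0, halve (factor) whenever
# the running-best validation loss has not improved for `patience`
# consecutive epochs. Returns the LR in force at each epoch.
lr_schedule_from_losses <- function(val_losses, lr0, factor = 0.5,
                                    patience = 10L) {
  lr <- lr0
  best <- Inf
  stale <- 0L
  out <- numeric(length(val_losses))
  for (i in seq_along(val_losses)) {
    out[i] <- lr
    if (val_losses[i] < best - 1e-12) {
      best <- val_losses[i]
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) {
        lr <- lr * factor
        stale <- 0L
      }
    }
  }
  out
}

prepare_pairs <- function(set) {
  lapply(set, function(s) {
    abort_if(is.null(s$image) || is.null(s$mask),
             "each sample needs image and mask")
    list(image = normalize_image(s$image), mask = s$mask, raw = s$image)
  })
}

batch_loss_forward <- function(pairs, idx, state, cfg, training) {
  B <- length(idx)
  h <- state$config$image_size[1]; w <- state$config$image_size[2]
  imgs <- matrix(0, h * w * B, 1)
  tgts <- numeric(h * w * B)
  for (i in seq_along(idx)) {
    rows <- ((i - 1L) * h * w + 1L):(i * h * w)
    imgs[rows, 1] <- as.vector(pairs[[idx[i]]]$image)
    tgts[rows] <- as.vector(pairs[[idx[i]]]$mask)
  }
  fwd <- memvit_fwd(imgs, state, B, training)
  loss <- composite_loss(fwd$prob, tgts, cfg)
  list(fwd = fwd, loss = loss, targets = tgts, B = B)
}

#' Train a MEM-ViT model
#'
#' Full-batch bookkeeping per the published protocol: per-epoch train and
#' validation loss are recorded, the learning rate is halved after
#' `lr_patience_epochs` consecutive epochs without validation improvement,
#' training stops early after `early_stop_patience` stale epochs (or at
#' `max_epochs`), and the weights from the best-validation epoch are
#' returned. Fully reproducible for a fixed seed on one device.
#'
#' @param train_set,val_set Non-empty lists of samples (each with `image`
#'   and `mask` of the configured size); `melachip_sample` objects work
#'   directly.
#' @param model_cfg A [memvit_config()] (e.g. [memvit_tiny()]).
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return A trained `melachip_model`; the loss curves tibble (epoch,
#'   train_loss, val_loss, lr) is in `$curves`, and [tidy()]/[glance()]
#'   methods expose them.
#' @export
train <- function(train_set, val_set, model_cfg, cfg = train_config(),
                  verbose = FALSE) {
  abort_if(length(train_set) == 0 || length(val_set) == 0,
           "train and validation sets must be non-empty")
  pairs <- prepare_pairs(train_set)
  vpairs <- prepare_pairs(val_set)
  n <- length(pairs)
  bs <- cfg$batch_size
  if (bs > n) {
    rlang::warn("batch size exceeds training set; falling back to full batch")
    bs <- n
  }
  state <- memvit_init(model_cfg, seed = cfg$seed)
  opt <- adam_init(state$params)
  lr <- cfg$learning_rate
  best_val <- Inf
  best_params <- state$params
  best_buffers <- state$buffers
  best_epoch <- 0L
  stale_lr <- 0L
  stale_stop <- 0L
  curves <- list()
  aug_counter <- 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- withr::with_seed(cfg$seed * 1000L + epoch, sample(n))
    tr_losses <- c()
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      # augmentation (deterministic per step)
      step_pairs <- pairs
      if (length(cfg$augmentations) > 0) {
        for (i in idx) {
          aug_counter <- aug_counter + 1L
          a <- augment(pairs[[i]]$raw, pairs[[i]]$mask, cfg$augmentations,
                       seed = cfg$seed * 10000L + aug_counter)
          step_pairs[[i]] <- list(image = normalize_image(a$image),
                                  mask = a$mask)
        }
      }
      res <- withr::with_seed(
        cfg$seed * 100000L + epoch * 1000L + start,
        batch_loss_forward(step_pairs, idx, state, cfg, training = TRUE))
      # BN running buffers updated during the forward pass
      state$buffers <- as.list(res$fwd$dec$ctx$bufs)[names(state$buffers)]
      dprob <- composite_loss_grad(res$fwd$prob, res$targets, cfg)
      grads <- memvit_bwd(dprob, res$fwd, state, res$B)
      upd <- adam_step(state$params, grads, opt, lr, cfg$adam_beta1,
                       cfg$adam_beta2)
      state$params <- upd$params
      opt <- upd$opt
      tr_losses <- c(tr_losses, res$loss$total)
    }
    val <- batch_loss_forward(vpairs, seq_along(vpairs), state, cfg,
                              training = FALSE)
    state$epochs_completed <- epoch
    curves[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = mean(tr_losses),
      val_loss = val$loss$total, lr = lr)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e",
                      epoch, mean(tr_losses), val$loss$total, lr))
    }
    if (val$loss$total < best_val - 1e-12) {
      best_val <- val$loss$total
      best_params <- state$params
      best_buffers <- state$buffers
      best_epoch <- epoch
      stale_lr <- 0L
      stale_stop <- 0L
    } else {
      stale_lr <- stale_lr + 1L
      stale_stop <- stale_stop + 1L
      if (stale_lr >= cfg$lr_patience_epochs) {
        lr <- lr * cfg$lr_decay_factor
        stale_lr <- 0L
      }
      if (stale_stop >= cfg$early_stop_patience) break
    }
  }
  state$params <- best_params
  state$buffers <- best_buffers
  state$curves <- dplyr::bind_rows(curves)
  state$best_epoch <- best_epoch
  state$train_config <- cfg
  state
}
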