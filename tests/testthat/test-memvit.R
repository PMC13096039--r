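test_that("scaled dot-product attention matches hand-computed values", {
  # single token: softmax of a scalar is 1, output is V
  V <- matrix(c(3, -2), 1, 2)
  expect_equal(attention(matrix(1), matrix(5), V), V)

  # zero queries: uniform weights, output = column means of V
  Q <- matrix(0, 2, 3)
  K <- matrix(rnorm(12), 4, 3)
  V2 <- matrix(rnorm(8), 4, 2)
  out <- attention(Q, K, V2)
  expect_equal(out[1, ], colMeans(V2))
  expect_equal(out[2, ], colMeans(V2))

  # 2 tokens, d_k = 1: weights softmax([1,0]) = (e/(e+1), 1/(e+1))
  Qh <- matrix(c(1, 0), 2, 1)
  Kh <- matrix(c(1, 0), 2, 1)
  Vh <- diag(2)
  w1 <- exp(1) / (exp(1) + 1)
  expect_equal(attention(Qh, Kh, Vh),
               matrix(c(w1, 0.5, 1 - w1, 0.5), 2, 2), tolerance = 1e-12)

  # rows of the attention matrix sum to 1 for random inputs
  set.seed(3)
  for (i in 1:5) {
    Qr <- matrix(rnorm(12), 4, 3); Kr <- matrix(rnorm(15), 5, 3)
    A <- attention(Qr, Kr, diag(5))
    expect_equal(rowSums(A), rep(1, 4), tolerance = 1e-6)
  }
  expect_error(attention(matrix(0, 2, 3), matrix(0, 2, 2), diag(2)), "key")
})

test_that("config validation enforces geometry constraints", {
  expect_error(memvit_config(patch_size = 12), "power of two")
  expect_error(memvit_config(image_size = c(100, 96), patch_size = 16),
               "divisible")
  expect_error(memvit_config(embed_dim = 100, num_heads = 12), "divisible")
  expect_error(memvit_config(image_size = c(64, 64), patch_size = 16,
                             embed_dim = 64, depth = 4, num_heads = 4,
                             skip_layers = c(1, 2, 3, 9),
                             decoder_channels = c(16, 8, 8, 4, 4)),
               "skip_layers")
  # decoder stages must undo the patching: log2(patch)+1 channel entries
  expect_error(memvit_config(image_size = c(64, 64), patch_size = 16,
                             embed_dim = 64, depth = 4, num_heads = 4,
                             skip_layers = 1:4,
                             decoder_channels = c(16, 8, 8)),
               "length")
})

test_that("encoder produces the expected token grid and four skip taps", {
  cfg <- fixture_micro_config()
  state <- memvit_init(cfg, seed = 3)
  set.seed(1)
  img <- matrix(runif(16 * 16), 16, 16)
  enc <- encode(img, state)
  expect_equal(dim(enc$tokens), c(2, 2, 8)) # 16/8 = 2 token positions per axis
  expect_length(enc$skips, 4)
  for (s in enc$skips) expect_equal(dim(s), c(2, 2, 8))
  # deterministic weights + fixed input -> identical outputs
  expect_identical(enc, encode(img, state))
  expect_error(encode(matrix(0.5, 10, 16), state), "image_size")
})

test_that("patch bookkeeping is permutation-equivariant without pos-embedding", {
  cfg <- fixture_micro_config()
  state <- memvit_init(cfg, seed = 5)
  state$params$pos[] <- 0
  set.seed(2)
  img <- matrix(runif(16 * 16), 16, 16)
  # swap patch (1,1) with patch (2,2) (8x8 blocks)
  img2 <- img
  img2[1:8, 1:8] <- img[9:16, 9:16]
  img2[9:16, 9:16] <- img[1:8, 1:8]
  e1 <- encode(img, state)
  e2 <- encode(img2, state)
  # token (1,1) of the swapped image equals token (2,2) of the original
  expect_equal(e2$tokens[1, 1, ], e1$tokens[2, 2, ], tolerance = 1e-10)
  expect_equal(e2$tokens[2, 2, ], e1$tokens[1, 1, ], tolerance = 1e-10)
  expect_equal(e2$tokens[1, 2, ], e1$tokens[1, 2, ], tolerance = 1e-10)
})

test_that("fuse preserves spatial size, sets channels, and ignores zeroed skips", {
  up <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  sk <- array(rnorm(4 * 5, 2), c(4, 5, 2))
  W <- matrix(rnorm(5 * 9 * 6, 0, 0.1), 5 * 9, 6)
  out <- fuse(up, sk, W)
  expect_equal(dim(out), c(4, 5, 6))
  expect_true(all(out >= 0)) # ReLU output

  # ablation probe: zero the skip-channel weights; perturbing the skip
  # input must leave the output unchanged
  W0 <- W
  ch_rows <- rep(rep(c(FALSE, TRUE), c(3, 2)), each = 9)
  W0[ch_rows, ] <- 0
  out_a <- fuse(up, sk, W0)
  out_b <- fuse(up, sk + rnorm(length(sk)), W0)
  expect_equal(out_a, out_b, tolerance = 1e-12)
  expect_error(fuse(up, array(0, c(3, 3, 1))), "spatial")
})

test_that("probability maps are valid and segmentation keeps input resolution", {
  cfg <- fixture_micro_config()
  state <- memvit_init(cfg, seed = 9)
  set.seed(7)
  img <- matrix(runif(16 * 16), 16, 16)
  prob <- predict_prob(img, state)
  expect_true(all(prob >= 0 & prob <= 1))
  expect_identical(prob, predict_prob(img, state))

  # arbitrary input sizes come back at their own resolution
  odd <- matrix(runif(25 * 19), 25, 19)
  m <- segment(odd, state)
  expect_identical(dim(m), dim(odd))
  expect_true(all(m %in% c(0L, 1L)))
  m2 <- segment(matrix(runif(100 * 80), 100, 80), state)
  expect_identical(dim(m2), c(100L, 80L))
})

test_that("binarisation is strictly greater-than the 0.45 threshold", {
  expect_identical(binarize(matrix(0.46, 3, 4)), matrix(1L, 3, 4))
  expect_identical(binarize(matrix(0.44, 3, 4)), matrix(0L, 3, 4))
  expect_identical(binarize(matrix(0.45, 2, 2)), matrix(0L, 2, 2))
})

test_that("analytic gradients agree with finite differences everywhere", {
  cfg <- fixture_micro_config()
  state <- memvit_init(cfg, seed = 2)
  tcfg <- train_config(seed = 2)
  B <- 2
  set.seed(9)
  imgs <- matrix(runif(16 * 16 * B), ncol = 1)
  tgts <- as.numeric(runif(16 * 16 * B) > 0.7)
  loss_fn <- function(st) {
    fwd <- melachip:::memvit_fwd(imgs, st, B, training = TRUE)
    composite_loss(fwd$prob, tgts, tcfg)$total
  }
  fwd <- melachip:::memvit_fwd(imgs, state, B, training = TRUE)
  dprob <- melachip:::composite_loss_grad(fwd$prob, tgts, tcfg)
  grads <- melachip:::memvit_bwd(dprob, fwd, state, B)
  expect_setequal(names(grads), names(state$params))

  h <- 1e-5
  set.seed(42)
  # representative tensors from every part of the network
  check <- c("pe_W", "pos", "L1_Wq", "L2_Wv", "L3_m_W1", "L4_ln2_g",
             "encf_g", "S1_c1_W", "S4_c2_bng", "R_c1_W", "R_c2_b",
             "D0_W", "U1_W", "F1_W", "U3_b", "F3_bnb", "head_W", "head_b")
  for (nm in check) {
    g <- grads[[nm]]
    n <- length(state$params[[nm]])
    for (j in sample(n, min(2, n))) {
      s1 <- state; s1$params[[nm]][j] <- s1$params[[nm]][j] + h
      s2 <- state; s2$params[[nm]][j] <- s2$params[[nm]][j] - h
      num <- (loss_fn(s1) - loss_fn(s2)) / (2 * h)
      expect_equal(g[j], num, tolerance = 1e-4,
                   label = sprintf("analytic grad %s[%d]", nm, j))
    }
  }
})

test_that("a tiny network can overfit four synthetic images", {
  co <- generate_cohort(2, 2, base_seed = 80, image_size = c(64, 64))
  cfg <- train_config(max_epochs = 150, batch_size = 4,
                      early_stop_patience = 200, seed = 3)
  m <- suppressWarnings(train(co, co, memvit_tiny(c(64, 64)), cfg))
  ev <- evaluate_masks(lapply(co, function(s) segment(s$image, m)),
                       lapply(co, `[[`, "mask"))
  expect_gte(ev$iou[ev$sample_id == "macro_average"], 0.95)
})

test_that("checkpoints reload bit-exactly", {
  state <- memvit_init(fixture_micro_config(), seed = 4)
  d <- withr::local_tempdir()
  p <- file.path(d, "model.rds")
  save_model(state, p)
  re <- load_model(p)
  expect_identical(re$params, state$params)
  expect_identical(re$config, state$config)
})
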