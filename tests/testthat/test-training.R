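test_that("geometric augmentations transform image and mask consistently", {
  fx <- fixture_patch_image()
  flip_op <- list(augment_op("flip", probability = 1, direction = "horizontal"))
  once <- augment(fx$image, fx$mask, flip_op, seed = 1)
  twice <- augment(once$image, once$mask, flip_op, seed = 2)
  expect_identical(twice$image, fx$image) # flip is an involution
  expect_identical(twice$mask, fx$mask)
  expect_equal(sum(once$mask), sum(fx$mask)) # flips preserve foreground count

  # elastic with zero displacement is the identity
  el0 <- augment(fx$image, fx$mask,
                 list(augment_op("elastic", 1, alpha = 0, sigma = 4)), seed = 3)
  expect_identical(el0$image, fx$image)
  expect_identical(el0$mask, fx$mask)

  # rotate 90 degrees: single foreground pixel lands on the mapped coordinate
  n <- 5
  m1 <- matrix(0L, n, n); m1[2, 3] <- 1L
  img <- matrix(runif(n * n), n, n)
  rot <- augment(img, m1, list(augment_op("rotate", probability = 1, quarter_turns = 1)), seed = 1)
  # counter-clockwise quarter turn: (r, c) -> (n - c + 1, r)
  expect_equal(which(rot$mask == 1L, arr.ind = TRUE)[1, ],
               c(row = n - 3 + 1, col = 2))
  expect_equal(sum(rot$mask), 1)

  # photometric ops leave the mask untouched
  ph <- augment(fx$image, fx$mask,
                list(augment_op("intensity_contrast", 1, max_gain = 0.3)),
                seed = 5)
  expect_identical(ph$mask, fx$mask)
  expect_false(identical(ph$image, fx$image))

  # determinism given the seed; masks stay binary throughout
  a1 <- augment(fx$image, fx$mask, default_augmentations(), seed = 11)
  a2 <- augment(fx$image, fx$mask, default_augmentations(), seed = 11)
  expect_identical(a1, a2)
  expect_true(all(a1$mask %in% c(0L, 1L)))
  expect_error(augment_op("swirl"), "unknown")
})

test_that("composite loss matches hand-computed values and endpoints", {
  # perfect prediction: both terms vanish (up to the clamping epsilon)
  y <- matrix(c(1, 0, 1, 0), 2, 2)
  l <- composite_loss(y, y, train_config())
  expect_lt(l$total, 1e-5)
  expect_lt(l$bce, 1e-5)
  expect_lt(l$dice, 1e-5)

  # lambda endpoints select a single term
  p <- matrix(c(0.7, 0.3, 0.9, 0.1), 2, 2)
  l1 <- composite_loss(p, y, train_config(lambda_weight = 1))
  expect_equal(l1$total, l1$bce, tolerance = 1e-12)
  l0 <- composite_loss(p, y, train_config(lambda_weight = 0))
  expect_equal(l0$total, l0$dice, tolerance = 1e-12)

  # 2-pixel case, hand-evaluated: y = (1,0), p = (0.8,0.2), lambda = 0.5,
  # w+ = 0.5: bce = -(0.5 ln 0.8 + ln 0.8)/2, dice = 1 - 1.6/2.0
  l2 <- composite_loss(c(0.8, 0.2), c(1, 0),
                       train_config(lambda_weight = 0.5))
  expect_equal(l2$bce, -(0.5 * log(0.8) + log(0.8)) / 2, tolerance = 1e-6)
  expect_equal(l2$dice, 1 - 1.6 / 2.0, tolerance = 1e-6)
  expect_equal(l2$total, 0.5 * l2$bce + 0.5 * l2$dice, tolerance = 1e-9)
})

test_that("composite loss is non-negative and decreases toward the target", {
  set.seed(6)
  cfg <- train_config(lambda_weight = 0.4)
  for (i in 1:20) {
    y <- as.numeric(runif(16) > 0.5)
    p <- runif(16, 0.01, 0.99)
    l <- composite_loss(p, y, cfg)
    expect_gte(l$total, 0)
    expect_equal(l$total, cfg$lambda_weight * l$bce +
                   (1 - cfg$lambda_weight) * l$dice, tolerance = 1e-9)
    # move one pixel toward its target: loss must strictly decrease
    j <- sample(16, 1)
    p2 <- p
    p2[j] <- p[j] + 0.05 * (y[j] - p[j])
    expect_lt(composite_loss(p2, y, cfg)$total, l$total)
  }
})

test_that("plateau schedule halves the learning rate after 10 stale epochs", {
  lrs <- melachip:::lr_schedule_from_losses(rep(1, 12), lr0 = 1e-3)
  expect_equal(lrs[1:11], rep(1e-3, 11))
  expect_equal(lrs[12], 5e-4)
  # an improving sequence never decays
  expect_equal(melachip:::lr_schedule_from_losses(seq(1, 0.5, length.out = 15),
                                                  lr0 = 1e-3),
               rep(1e-3, 15))
  # defaults follow the published protocol
  tc <- train_config()
  expect_equal(tc$learning_rate, 1e-3)
  expect_equal(tc$adam_beta1, 0.9)
  expect_equal(tc$adam_beta2, 0.99)
  expect_equal(tc$lr_decay_factor, 0.5)
  expect_equal(tc$lr_patience_epochs, 10L)
  expect_equal(tc$batch_size, 8L)
  expect_equal(tc$max_epochs, 200L)
  expect_equal(tc$bce_positive_weight, 0.5)
})

test_that("training reduces the loss, records curves, and is reproducible", {
  co <- generate_cohort(3, 3, base_seed = 60, image_size = c(32, 32))
  cfg <- train_config(max_epochs = 3, batch_size = 8, seed = 5)
  mcfg <- memvit_tiny(c(32, 32))
  expect_warning(m <- train(co[1:4], co[5:6], mcfg, cfg), "full batch")
  cv <- tidy(m)
  expect_equal(nrow(cv), 3)
  expect_named(cv, c("epoch", "train_loss", "val_loss", "lr"))
  expect_lt(cv$train_loss[3], cv$train_loss[1])

  m2 <- suppressWarnings(train(co[1:4], co[5:6], mcfg, cfg))
  expect_identical(tidy(m2), cv) # same seed, same device -> same curves
  expect_identical(m2$params, m$params)

  g <- glance(m)
  expect_equal(g$epochs_completed, 3L)
  expect_error(train(list(), co[5:6], mcfg, cfg), "non-empty")
})
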