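test_that("image loading scales 8- and 16-bit data to [0,1]", {
  d <- withr::local_tempdir()
  p8 <- file.path(d, "white.png")
  png::writePNG(matrix(1, 4, 4), p8)
  expect_equal(load_image(p8), matrix(1, 4, 4))

  p16 <- file.path(d, "half.tiff")
  tiff::writeTIFF(matrix(32768 / 65535, 5, 6), p16, bits.per.sample = 16L)
  expect_equal(load_image(p16), matrix(32768 / 65535, 5, 6), tolerance = 1e-6)

  prgb <- file.path(d, "red.png")
  arr <- array(0, c(3, 3, 3)); arr[, , 1] <- 1
  png::writePNG(arr, prgb)
  # declared BT.601 red weight, applied by hand
  expect_equal(load_image(prgb), matrix(0.299, 3, 3), tolerance = 1e-6)

  if (requireNamespace("jpeg", quietly = TRUE)) {
    pj <- file.path(d, "grey.jpg")
    jpeg::writeJPEG(matrix(0.5, 8, 8), pj, quality = 1)
    expect_equal(load_image(pj), matrix(0.5, 8, 8), tolerance = 0.02)
  }

  expect_error(load_image(file.path(d, "missing.png")), "not found")
  expect_error(load_image({f <- file.path(d, "x.bmp"); file.create(f); f}),
               "unsupported")
})

test_that("mask files round-trip through 0/255 PNG", {
  d <- withr::local_tempdir()
  set.seed(4)
  mask <- matrix(rbinom(30 * 20, 1, 0.3), 30, 20)
  p <- file.path(d, "m.png")
  write_mask(mask, p)
  expect_identical(load_mask(p), matrix(as.integer(mask), 30, 20))
})

test_that("LabelMe polygons rasterise with the pixel-centre rule", {
  d <- withr::local_tempdir()
  # empty shape list
  p0 <- write_labelme_json(file.path(d, "empty.json"), list(), 6, 6)
  expect_equal(sum(import_labelme(p0, c(6, 6))), 0)

  # axis-aligned rectangle (1,1)-(4,3), checked against a brute-force
  # point-in-polygon oracle over all 36 pixel centres
  rect <- cbind(c(1, 4, 4, 1), c(1, 1, 3, 3))
  p1 <- write_labelme_json(file.path(d, "rect.json"), list(rect), 6, 6)
  got <- import_labelme(p1, c(6, 6))
  want <- oracle_polygon_mask(6, 6, rect[, 1], rect[, 2])
  expect_identical(got, want)
  expect_equal(sum(got), 6) # 3 x 2 interior pixel centres

  # two disjoint triangles: union equals each rasterised alone
  t1 <- cbind(c(0.5, 5.5, 0.5), c(0.5, 0.5, 5.5))
  t2 <- cbind(c(8, 11.5, 11.5), c(8, 8, 11.5))
  pu <- write_labelme_json(file.path(d, "two.json"), list(t1, t2), 12, 12)
  pa <- write_labelme_json(file.path(d, "a.json"), list(t1), 12, 12)
  pb <- write_labelme_json(file.path(d, "b.json"), list(t2), 12, 12)
  mu <- import_labelme(pu, c(12, 12))
  expect_identical(mu, pmax(import_labelme(pa, c(12, 12)),
                            import_labelme(pb, c(12, 12))))

  # degenerate polygon and out-of-bounds clipping
  p2 <- write_labelme_json(file.path(d, "deg.json"),
                           list(cbind(c(1, 2), c(1, 2))), 6, 6)
  expect_error(import_labelme(p2, c(6, 6)), "3 points")
  p3 <- write_labelme_json(file.path(d, "oob.json"),
                           list(cbind(c(-2, 9, 9, -2), c(-2, -2, 9, 9))), 6, 6)
  expect_warning(m3 <- import_labelme(p3, c(6, 6)), "clip")
  expect_equal(sum(m3), 36)
})

test_that("inter-annotator QC applies the 80% IoU rule inclusively", {
  a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L
  expect_equal(interannotator_qc(a, a), list(iou = 1.0, pass = TRUE))

  b <- matrix(0L, 4, 4); b[3:4, 3:4] <- 1L
  r <- interannotator_qc(a, b)
  expect_equal(r$iou, 0)
  expect_false(r$pass)

  # overlap 4 px, union 5 px -> exactly 0.80, boundary passes
  c1 <- matrix(0L, 5, 1); c1[1:4] <- 1L
  c2 <- matrix(0L, 5, 1); c2[1:5] <- 1L
  r2 <- interannotator_qc(c1, c2)
  expect_equal(r2$iou, 0.8)
  expect_true(r2$pass)

  # symmetry
  expect_equal(interannotator_qc(c1, c2)$iou, interannotator_qc(c2, c1)$iou)
  expect_error(interannotator_qc(a, matrix(0L, 3, 3)), "dimensions")
})

test_that("per-sample splits use floor boundaries and are seed-deterministic", {
  s10 <- split_dataset(letters[1:10], seed = 2)
  expect_length(s10$train_ids, 5)
  expect_length(s10$val_ids, 2)
  expect_length(s10$test_ids, 3)

  s30 <- split_dataset(1:30, seed = 9)
  expect_length(s30$train_ids, 15)
  expect_length(s30$val_ids, 6)
  expect_length(s30$test_ids, 9)
  all_ids <- c(s30$train_ids, s30$val_ids, s30$test_ids)
  expect_setequal(all_ids, 1:30)
  expect_equal(anyDuplicated(all_ids), 0)

  expect_identical(split_dataset(1:10, seed = 4), split_dataset(1:10, seed = 4))
  expect_error(split_dataset(1:2, seed = 1), "at least 3")

  d <- withr::local_tempdir()
  write_split(s10, file.path(d, "split.json"))
  expect_equal(read_split(file.path(d, "split.json"))$train_ids, s10$train_ids)
})

test_that("focus stacking selects the locally sharpest plane", {
  set.seed(8)
  sharp <- matrix(runif(40 * 40), 40, 40)
  expect_identical(focus_stack(list(sharp)), sharp)

  blurred <- gaussian_blur(sharp, 2)
  out <- focus_stack(list(blurred, sharp))
  # wherever energies differ, the sharp plane must win
  differ <- abs(sharp - out) < abs(blurred - out)
  expect_gt(mean(out == sharp), 0.95)

  # ties go to the lowest plane index
  expect_identical(focus_stack(list(sharp, sharp)), sharp)
  expect_error(focus_stack(list()), "at least one")
  expect_error(focus_stack(list(sharp, matrix(0, 2, 2))), "dimensions")
})
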