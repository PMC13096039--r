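test_that("patch extraction matches hand flood-fill on small cases", {
  # empty mask
  expect_equal(nrow(extract_patches(matrix(0, 4, 4))), 0)

  # one 2x2 block: area 4, centroid at the block centre
  m <- matrix(0L, 6, 6); m[3:4, 2:3] <- 1L
  p <- extract_patches(m, min_patch_size = 1)
  expect_equal(nrow(p), 1)
  expect_equal(p$area_px, 4L)
  expect_equal(p$centroid_row, 3.5)
  expect_equal(p$centroid_col, 2.5)
  expect_equal(unlist(p[, c("bbox_r0", "bbox_c0", "bbox_r1", "bbox_c1")],
                      use.names = FALSE), c(3L, 2L, 4L, 3L))

  # diagonal adjacency: 4-connectivity separates, 8-connectivity joins
  d <- matrix(0L, 4, 4); d[2, 2] <- 1L; d[3, 3] <- 1L
  expect_equal(nrow(extract_patches(d, connectivity = 4, min_patch_size = 1)), 2)
  expect_equal(nrow(extract_patches(d, connectivity = 8, min_patch_size = 1)), 1)

  # patches are ordered by bounding-box corner and small ones filtered
  m2 <- matrix(0L, 10, 10)
  m2[7:9, 1:3] <- 1L  # area 9
  m2[1:2, 6:9] <- 1L  # area 8
  m2[5, 5] <- 1L      # area 1, below default min size
  p2 <- extract_patches(m2)
  expect_equal(nrow(p2), 2)
  expect_equal(p2$bbox_r0, c(1L, 7L))
})

test_that("component labelling agrees with an igraph adjacency oracle", {
  skip_if_not_installed("igraph")
  set.seed(21)
  for (conn in c(4L, 8L)) {
    for (rep in 1:5) {
      m <- matrix(rbinom(15 * 12, 1, 0.35), 15, 12)
      got <- extract_patches(m, connectivity = conn, min_patch_size = 1)
      fg <- which(m == 1)
      if (length(fg) == 0) {
        expect_equal(nrow(got), 0)
        next
      }
      r <- (fg - 1) %% 15 + 1; c <- (fg - 1) %/% 15 + 1
      adj <- outer(seq_along(fg), seq_along(fg), function(i, j) {
        dr <- abs(r[i] - r[j]); dc <- abs(c[i] - c[j])
        if (conn == 4) (dr + dc) == 1 else (pmax(dr, dc) == 1)
      })
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      expect_equal(nrow(got), igraph::components(g)$no)
      expect_equal(sum(got$area_px), length(fg))
    }
  }
})

test_that("area statistics satisfy the sum/mean identities", {
  p <- tibble::tibble(area_px = c(4, 6))
  expect_equal(total_area(p), 10)
  expect_equal(mean_area(p), 5)
  expect_warning(t0 <- total_area(tibble::tibble(area_px = numeric())), "no patches")
  expect_equal(t0, 0)
  expect_warning(m0 <- mean_area(tibble::tibble(area_px = numeric())), "no patches")
  expect_equal(m0, 0)

  set.seed(22)
  areas <- tibble::tibble(area_px = sample(1:500, 100, replace = TRUE))
  expect_equal(total_area(areas), mean_area(areas) * 100, tolerance = 1e-9)
})

test_that("background estimation honours strategy and margins", {
  img <- matrix(0.8, 10, 10)
  mask <- matrix(0L, 10, 10); mask[4:6, 4:6] <- 1L
  expect_equal(estimate_background(img, mask, border_margin = 0), 0.8)

  # checkerboard: mask covers exactly the dark squares
  chk <- matrix(0.8, 8, 8)
  dark <- (row(chk) + col(chk)) %% 2 == 0
  chk[dark] <- 0.2
  cm <- matrix(as.integer(dark), 8, 8)
  expect_equal(estimate_background(chk, cm, border_margin = 0), 0.8)

  expect_error(estimate_background(img, matrix(1L, 10, 10)), "empty background")
  region <- matrix(0L, 10, 10); region[1:2, 1:2] <- 1L
  expect_equal(estimate_background(img, mask, strategy = "region",
                                   region = region), 0.8)
})

test_that("transmittance and optical density follow the printed formulas", {
  img <- matrix(0.8, 12, 12)
  mask <- matrix(0L, 12, 12); mask[4:7, 4:7] <- 1L
  img[mask == 1] <- 0.4
  p <- extract_patches(mask, image = img)
  expect_equal(transmittance(img, p, 0.8), 50)       # T = I/I0 * 100
  expect_equal(transmittance(img, p, mean(img[mask == 0])), 50)
  expect_equal(optical_density(img, p, 0.8), -log10(0.5))
  # forced endpoints: I = I0 -> T = 100, OD = 0; I = I0/10 -> OD = 1
  img2 <- matrix(0.8, 12, 12)
  p2 <- extract_patches(mask, image = img2)
  expect_equal(transmittance(img2, p2, 0.8), 100)
  expect_equal(optical_density(img2, p2, 0.8), 0)
  img3 <- img2; img3[mask == 1] <- 0.08
  p3 <- extract_patches(mask, image = img3)
  expect_equal(optical_density(img3, p3, 0.8), 1.0, tolerance = 1e-12)
  img4 <- img2; img4[mask == 1] <- 0.008
  expect_equal(optical_density(img4, extract_patches(mask, image = img4), 0.8),
               2.0, tolerance = 1e-12)
  expect_error(transmittance(img, p, 0), "positive")
})

test_that("sample quantification composes the four indicators coherently", {
  # empty mask: zero areas, transmittance/OD reported missing
  img <- matrix(0.8, 16, 16)
  q0 <- quantify_sample(img, matrix(0L, 16, 16))
  expect_equal(q0$n_patches, 0)
  expect_equal(q0$a_total_px, 0)
  expect_true(is.na(q0$transmittance_pct))
  expect_true(is.na(q0$optical_density))

  # synthetic sample: total area equals the generator's mask area
  s <- generate_sample(synth_preset("good", c(96, 96), seed = 31))
  q <- quantify_sample(s$image, s$mask, min_patch_size = 1,
                       pixels_per_mm = 100)
  expect_equal(q$a_total_px, sum(s$mask))
  expect_equal(q$a_total_mm2, sum(s$mask) / 100^2)
  # melanin darker than background: T < 100 and OD > 0
  expect_lt(q$transmittance_pct, 100)
  expect_gt(q$optical_density, 0)
  # OD and T derive from the same intensities: OD = -log10(T/100)
  expect_equal(q$optical_density, -log10(q$transmittance_pct / 100),
               tolerance = 1e-9)
})

test_that("poor cohorts show more deposition than good cohorts", {
  co <- generate_cohort(20, 20, base_seed = 900, image_size = c(96, 96))
  m <- quantify_cohort(co)
  good <- m$label == "good"
  expect_gt(mean(m$a_total_px[!good]), mean(m$a_total_px[good]))
  expect_gt(mean(m$optical_density[!good]), mean(m$optical_density[good]))
})
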