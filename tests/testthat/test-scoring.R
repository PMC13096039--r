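test_that("min-max rescaling is the printed affine map", {
  expect_equal(minmax_rescale(2, bounds = c(2, 10)), 0)
  expect_equal(minmax_rescale(10, bounds = c(2, 10)), 100)
  expect_equal(minmax_rescale(6, bounds = c(2, 10)), 50)
  # cohort mode uses the data range
  x <- c(1, 3, 5)
  expect_equal(minmax_rescale(x), c(0, 50, 100))
  # strictly monotone on its source interval
  set.seed(31)
  xs <- sort(runif(20))
  expect_true(all(diff(minmax_rescale(xs)) > 0))
  # fixed calibration clips out-of-range values with a warning
  expect_warning(v <- minmax_rescale(c(-5, 20), bounds = c(0, 10)), "clipped")
  expect_equal(v, c(0, 100))
  expect_error(minmax_rescale(1, bounds = c(3, 3)), "degenerate")
})

test_that("composite score combines the printed weights", {
  w <- default_score_weights()
  expect_equal(unname(w), c(0.35, 0.10, 0.15, 0.30))
  expect_equal(composite_score(c(0, 0, 0, 0)), 0)
  # all metrics at 100: the reachable maximum is the weight sum * 100 = 90
  expect_equal(composite_score(c(100, 100, 100, 100)), 90)
  expect_equal(composite_score(c(100, 0, 0, 0)), 35)
  # monotone non-decreasing in every normalised metric
  set.seed(32)
  for (i in 1:20) {
    x <- runif(4, 0, 100)
    j <- sample(4, 1)
    x2 <- x; x2[j] <- min(100, x[j] + 5)
    expect_gte(composite_score(x2), composite_score(x))
  }
  expect_error(composite_score(c(1, 2, 3)), "length")
})

test_that("classification uses an inclusive poor boundary", {
  expect_equal(classify(0, 45), "good")
  expect_equal(classify(90, 45), "poor")
  expect_equal(classify(45, 45), "poor") # boundary inclusive
  expect_error(classify(NaN), "finite")
})

test_that("cohort scoring separates phenotypes and pipes tidily", {
  co <- generate_cohort(8, 8, base_seed = 70, image_size = c(96, 96))
  scores <- quantify_cohort(co) |> score_samples()
  expect_true(all(c("score", "classification", "cutoff_used") %in%
                    names(scores)))
  expect_true(all(scores$score >= 0 & scores$score <= 90 + 1e-9))
  # recomputing the weighted sum reproduces the score column
  w <- default_score_weights()
  manual <- scores$a_total_norm * w[1] + scores$a_mean_norm * w[2] +
    scores$t_norm * w[3] + scores$od_norm * w[4]
  expect_equal(scores$score, manual, tolerance = 1e-9)
})

test_that("cohort analysis reproduces agreement and correlations", {
  # identical predictions -> 100%
  r0 <- cohort_analysis(rep(c("good", "poor"), 5), rep(c("good", "poor"), 5))
  expect_equal(r0$agreement_pct, 100)

  # printed-count worked example: 148 + 2 manual good, 146 + 4 manual bad
  pred <- c(rep("good", 148), rep("poor", 2), rep("poor", 146), rep("good", 4))
  manual <- c(rep("good", 150), rep("bad", 150))
  r <- cohort_analysis(pred, manual)
  expect_equal(r$agreement_pct, 98.0)
  expect_equal(unname(as.vector(r$confusion)), c(148, 2, 4, 146))

  # a metric equal to the label column correlates perfectly
  tbl <- tibble::tibble(
    classification = rep(c("good", "poor"), each = 5),
    a_total_px = rep(c(0, 1), each = 5),
    a_mean_px = c(2, 1, 2, 1, 2, 1, 2, 1, 2, 1),
    transmittance_pct = runif(10),
    optical_density = runif(10)
  )
  rr <- cohort_analysis(tbl, tbl$classification)
  expect_equal(rr$pearson["a_total", "label"], 1)
  expect_true(isSymmetric(unname(rr$pearson)))
  expect_equal(unname(diag(rr$pearson)), rep(1, nrow(rr$pearson)))

  # constant columns yield missing correlations
  tbl2 <- dplyr::mutate(tbl, optical_density = 1)
  r2 <- cohort_analysis(tbl2, tbl2$classification)
  expect_true(is.na(r2$pearson["od", "label"]))

  # tidy/glance accessors
  g <- glance(r)
  expect_equal(g$agreement_pct, 98.0)
  expect_equal(g$n, 300)
  td <- tidy(rr)
  expect_true(all(c("var1", "var2", "r") %in% names(td)))
})
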