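test_that("profile means are exact on constant rows and zero after matched background", {
  img <- tiny_image(rep(1:10, each = 8), 8, 10, px = 100)   # columns constant
  # horizontal line through row 4 (y = 350 nm), width 1
  tr <- tibble::tibble(x_nm = c(50, 950), y_nm = c(350, 350))
  pm <- profile_mean(img, tr, width_px = 1, background_roi = c(0, 6, 10, 2))
  expect_equal(pm$raw_mean, mean(1:10))

  uni <- tiny_image(7, 8, 10, px = 100)
  pm2 <- profile_mean(uni, tr, width_px = 3, background_roi = c(0, 6, 10, 2))
  expect_equal(pm2$corrected_mean, 0)
  expect_false(pm2$negative_flag)
})

test_that("a band of excess signal under the polyline is recovered to within interpolation error", {
  b <- 10; k <- 25
  mat <- matrix(b, 20, 60)
  mat[9:12, ] <- b + k
  img <- pixel_image(mat, 100)
  tr <- tibble::tibble(x_nm = c(100, 5900), y_nm = c(1000, 1000))
  pm <- profile_mean(img, tr, width_px = 4, background_roi = c(0, 0, 60, 3))
  expect_equal(pm$corrected_mean, k, tolerance = 0.01)
})

test_that("profile geometry and ROI violations raise errors", {
  img <- tiny_image(1, 8, 10, px = 100)
  outside <- tibble::tibble(x_nm = c(0, 2000), y_nm = c(-500, 300))
  expect_error(profile_mean(img, outside, 1, c(0, 6, 10, 2)),
               class = "axc_error_geometry")
  mid <- tibble::tibble(x_nm = c(50, 950), y_nm = c(350, 350))
  expect_error(profile_mean(img, mid, 1, c(0, 3, 10, 1)),
               class = "axc_error_parameter")   # ROI overlaps the band
  expect_error(profile_mean(img, mid, 1, c(0, 20, 5, 5)),
               class = "axc_error_parameter")   # ROI outside image
})

test_that("percent change matches hand arithmetic", {
  expect_equal(percent_change(c(100), c(71)), 29)
  expect_equal(percent_change(c(3, 5), c(3, 5)), 0)
  expect_equal(percent_change(c(2, 4), c(1, 2)), 50)
  expect_error(percent_change(c(0), c(1)), class = "axc_error_degenerate")
  expect_error(percent_change(numeric(0), 1), class = "axc_error_parameter")
})

test_that("the polarity index matches its formula, extremes and antisymmetry", {
  expect_equal(polarity_index(50, c(50, 50, 50))$pi, 0)
  expect_equal(polarity_index(0, c(30, 30, 30))$pi, 1)
  expect_equal(polarity_index(30, c(0, 0, 0))$pi, -1)
  expect_equal(polarity_index(10, c(30, 30, 30))$pi, 0.5)

  # antisymmetry under swapping the axonal and dendritic roles
  set.seed(5)
  for (i in 1:10) {
    a <- runif(1, 0, 50); d <- runif(3, 0, 50)
    expect_equal(polarity_index(a, d)$pi,
                 -polarity_index(mean(d), rep(a, 3))$pi)
  }

  expect_error(polarity_index(1, c(1, 2)), class = "axc_error_parameter")
  expect_error(polarity_index(0, c(0, 0, 0)), class = "axc_error_degenerate")
  expect_error(polarity_index(-1, c(1, 1, 1)), class = "axc_error_parameter")
})

test_that("split-APEX normalization anchors each batch's control mean at one", {
  df <- tibble::tibble(
    strep = c(2, 2, 3, 4, 4, 6),
    condition = rep(c("ctrl", "ctrl", "kd"), 2),
    batch_id = rep(c("A", "B"), each = 3))
  out <- normalize_apex(df, "ctrl")
  expect_equal(out$strep_normalized[out$condition == "kd"], c(1.5, 1.5))
  ctrl_means <- tapply(out$strep_normalized[out$condition == "ctrl"],
                       out$batch_id[out$condition == "ctrl"], mean)
  expect_equal(as.numeric(ctrl_means), c(1, 1))

  # all-equal intensities normalize to exactly one
  same <- tibble::tibble(strep = 5, condition = c("ctrl", "kd"),
                         batch_id = "A")
  expect_equal(normalize_apex(same, "ctrl")$strep_normalized, c(1, 1))

  # a batch without controls is an error
  bad <- tibble::tibble(strep = 1:2, condition = "kd", batch_id = "C")
  expect_error(normalize_apex(bad, "ctrl"), class = "axc_error_normalization")
})

test_that("expression correction divides by V5 x HA and excludes zero markers", {
  df <- tibble::tibble(
    strep = c(8, 8, 24, 5),
    v5 = c(2, 2, 2, 0),
    ha = c(2, 2, 3, 1),
    condition = c("ctrl", "ctrl", "kd", "kd"),
    batch_id = "A")
  out <- normalize_apex(df, "ctrl", correct_expression = TRUE)
  expect_equal(out$expression_corrected[1:3], c(2, 2, 4))
  expect_equal(out$strep_normalized[3], 2)
  expect_true(out$excluded[4])
  expect_true(is.na(out$strep_normalized[4]))
})

test_that("branch enrichment matches hand arithmetic", {
  expect_equal(branch_enrichment(c(2, 2), c(2, 2)), 1)
  expect_equal(branch_enrichment(c(3.5), c(2)), 1.75)
  expect_error(branch_enrichment(1, c(0)), class = "axc_error_degenerate")
})

test_that("ratio statistics are invariant under global intensity rescaling", {
  c_vals <- c(10, 12, 9); t_vals <- c(7, 8, 6)
  for (s in c(0.5, 3, 1000)) {
    expect_equal(percent_change(s * c_vals, s * t_vals),
                 percent_change(c_vals, t_vals))
    expect_equal(branch_enrichment(s * c_vals, s * t_vals),
                 branch_enrichment(c_vals, t_vals))
    expect_equal(polarity_index(s * 10, s * c(30, 20, 10))$pi,
                 polarity_index(10, c(30, 20, 10))$pi)
  }
  df <- tibble::tibble(strep = c(2, 2, 3), condition = c("c", "c", "t"),
                       batch_id = "A")
  df2 <- dplyr::mutate(df, strep = strep * 7)
  expect_equal(normalize_apex(df2, "c")$strep_normalized,
               normalize_apex(df, "c")$strep_normalized)
})

test_that("programmed branch enrichment is recovered from rendered segments", {
  bm <- simulate_branch_measurements("fig3-branch", 6, seed = 12)
  fold <- branch_enrichment(bm$branch_mean, bm$shaft_mean)
  expect_gt(fold, 1.4)
  expect_lt(fold, 2.1)
})
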