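test_that("thresholding recovers a two-level image exactly and rejects degenerate input", {
  set.seed(1)
  vals <- c(rep(10, 40), rep(200, 10))
  img <- tiny_image(sample(vals), 5, 10)
  m <- segment_er_mask(img)
  th <- attr(m, "threshold")
  expect_identical(bare(m), bare(img) > th)
  expect_true(th > 10 && th < 200)
  expect_setequal(bare(img)[bare(m)], 200)

  expect_error(segment_er_mask(tiny_image(0, 4, 4)),
               class = "axc_error_degenerate")
  expect_error(segment_er_mask(tiny_image(7, 4, 4)),
               class = "axc_error_degenerate")
})

test_that("fixed thresholds use a strict inequality", {
  img <- tiny_image(1:12, 3, 4)
  m <- segment_er_mask(img, method = "fixed", fixed_threshold = max(img))
  expect_equal(sum(m), 0)
  m2 <- segment_er_mask(img, method = "fixed", fixed_threshold = 6)
  expect_equal(sum(m2), 6)
  expect_error(segment_er_mask(img, method = "fixed"),
               class = "axc_error_parameter")
})

test_that("dilation matches the enumerated disk and the brute-force oracle", {
  # single pixel, 10 nm pixels, 5 nm distance: the 5-pixel cross
  m <- binary_mask(matrix(c(rep(FALSE, 4), TRUE, rep(FALSE, 4)), 3, 3), 10)
  d <- dilate_mask(m, 5)
  expect_identical(bare(d),
                   matrix(c(FALSE, TRUE, FALSE,
                            TRUE,  TRUE, TRUE,
                            FALSE, TRUE, FALSE), 3, 3, byrow = TRUE))
  # identity at zero distance
  expect_identical(bare(dilate_mask(m, 0)), bare(m))

  # exhaustive check against the brute-force oracle on small grids
  set.seed(42)
  for (trial in 1:20) {
    mm <- matrix(runif(25) < 0.3, 5, 5)
    bm <- binary_mask(mm, 10)
    for (dist_nm in c(5, 10, 20)) {
      r_px <- max(1, ceiling(dist_nm / 10))
      expect_identical(bare(dilate_mask(bm, dist_nm)),
                       brute_dilate(mm, r_px))
    }
  }
})

test_that("dilation output always contains its input", {
  set.seed(7)
  for (trial in 1:10) {
    mm <- matrix(runif(48) < 0.2, 6, 8)
    d <- dilate_mask(binary_mask(mm, 20), 30)
    expect_true(all(d[mm]))
  }
})

test_that("contact fraction matches hand arithmetic and the brute-force oracle", {
  # uniform image, mask covering half the pixels
  img <- tiny_image(1, 2, 4)
  mask <- binary_mask(matrix(c(rep(TRUE, 4), rep(FALSE, 4)), 2, 4), 20)
  expect_equal(contact_fraction(img, mask), 0.5)

  # all intensity inside the mask
  img2 <- tiny_image(c(5, 0, 0, 0, 3, 0, 0, 0), 2, 4)
  mask2 <- binary_mask(matrix(c(TRUE, rep(FALSE, 3), TRUE, rep(FALSE, 3)), 2, 4), 20)
  expect_equal(contact_fraction(img2, mask2), 1)

  # 3x3 with one bright pixel in a 3-pixel mask: (8 + 2) / 16
  img3 <- tiny_image(c(8, rep(1, 8)), 3, 3)
  mask3 <- binary_mask(matrix(c(TRUE, TRUE, TRUE, rep(FALSE, 6)), 3, 3), 20)
  expect_equal(contact_fraction(img3, mask3), 0.625)

  set.seed(13)
  for (trial in 1:20) {
    img_r <- tiny_image(runif(25), 5, 5)
    mask_r <- binary_mask(matrix(runif(25) < 0.4, 5, 5), 20)
    expect_equal(contact_fraction(img_r, mask_r),
                 brute_fraction(unclass(img_r), unclass(mask_r)))
  }

  expect_error(contact_fraction(tiny_image(0, 2, 2),
                                binary_mask(matrix(TRUE, 2, 2), 20)),
               class = "axc_error_degenerate")
  expect_error(contact_fraction(tiny_image(1, 2, 2),
                                binary_mask(matrix(TRUE, 2, 3), 20)),
               class = "axc_error_shape")
})

test_that("the flip null is a no-op for mirror-symmetric and uniform images", {
  mask <- binary_mask(matrix(runif(24) < 0.5, 4, 6), 20)
  sym <- tiny_image(rep(c(1, 2, 5, 5, 2, 1), each = 4), 4, 6)
  expect_equal(flip_null(sym, mask), contact_fraction(sym, mask))

  uni <- tiny_image(3, 4, 6)
  expect_equal(flip_null(uni, mask), mean(mask))
  expect_equal(contact_fraction(uni, mask), mean(mask))
})

test_that("analyze_segment returns nested measures with the enlarged mask at least as large", {
  segs <- simulate_contact_segments("fig2-sted-contact", 4, seed = 8)
  res <- analyze_segments(segs)
  expect_true(all(res$fraction_in_enlarged >= res$fraction_in_mask))
  expect_true(all(res$fraction_in_mask >= 0 & res$fraction_in_mask <= 1))
  expect_true(all(res$fraction_flipped >= 0 & res$fraction_flipped <= 1))

  # uniform ribosome channel: in-mask fraction equals the mask area fraction
  er <- segs$er_image[[1]]
  uni <- pixel_image(matrix(2, nrow(er), ncol(er)),
                     pixel_size_nm = pixel_size_nm(er))
  one <- analyze_segment(er, uni)
  expect_equal(one$fraction_in_mask, one$mask_area_fraction)
})

test_that("contact fraction is non-decreasing in dilation distance", {
  segs <- simulate_contact_segments("fig2-sted-contact", 2, seed = 21)
  for (i in 1:2) {
    mask <- segment_er_mask(segs$er_image[[i]])
    fr <- vapply(c(0, 5, 20, 40, 80, 160), function(d) {
      contact_fraction(segs$ribo_image[[i]], dilate_mask(mask, d))
    }, numeric(1))
    expect_true(all(diff(fr) >= -1e-12))
  }
})

test_that("measured contact fraction increases strictly with the programmed bound fraction", {
  p <- simulation_preset("fig2-sted-contact")
  means <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(bf) {
    p$scene$bound_fraction <- bf
    segs <- simulate_contact_segments(p, 10, seed = 31)
    mean(analyze_segments(segs)$fraction_in_mask)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("the flip statistic is centered on zero for uniform scenes", {
  p <- simulation_preset("fig2-sted-contact")
  p$scene$bound_fraction <- 0
  p$scene$bind_distance_nm <- 0
  segs <- simulate_contact_segments(p, 50, seed = 17)
  res <- analyze_segments(segs)
  diff_ <- res$fraction_in_mask - res$fraction_flipped
  bias <- mean(diff_)
  sem <- sd(diff_) / sqrt(length(diff_))
  expect_lt(abs(bias), 2 * sem + 1e-12)
})
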