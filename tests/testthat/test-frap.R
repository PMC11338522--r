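test_that("normalization anchors hold for any valid trace", {
  for (seed in 1:5) {
    fs <- simulate_frap(80, 0.85, 0.5, 150, acq_bleach_rate = 0.01,
                        noise_sd = 1.5, background_level = 4, seed = seed)
    nc <- normalize_frap(fs)
    bi <- attr(nc, "bleach_index")
    expect_equal(mean(nc$percent[(bi - 3):(bi - 1)]), 100, tolerance = 1e-9)
    expect_identical(nc$percent[bi], 0)
  }
})

test_that("a trace returning to its pre-bleach level normalizes to 100 percent", {
  fs <- simulate_frap(100, 1, 1, 20, acq_bleach_rate = 0, noise_sd = 0,
                      n_frames = 40, frame_interval_s = 30, seed = 1)
  nc <- normalize_frap(fs, correct_acquisition = FALSE)
  expect_equal(nc$percent[nrow(nc)], 100, tolerance = 1e-6)
})

test_that("normalization is affine-invariant in the raw intensities", {
  fs <- simulate_frap(100, 0.9, 0.4, 120, noise_sd = 2, seed = 3)
  nc <- normalize_frap(fs)

  scaled <- fs
  scaled$raw <- 3 * scaled$raw
  scaled$reference <- 3 * scaled$reference
  nc3 <- normalize_frap(frap_series(scaled, attr(fs, "bleach_index")))
  expect_equal(nc3$percent, nc$percent, tolerance = 1e-9)

  shifted <- fs
  shifted$raw <- 2 * shifted$raw + 5
  shifted$reference <- 2 * shifted$reference + 5
  shifted$background <- 2 * shifted$background + 5
  ncs <- normalize_frap(frap_series(shifted, attr(fs, "bleach_index")))
  expect_equal(ncs$percent, nc$percent, tolerance = 1e-9)
})

test_that("the reference-ratio correction removes acquisition bleaching exactly", {
  base <- simulate_frap(100, 0.9, 0.6, 100, acq_bleach_rate = 0,
                        noise_sd = 0, seed = 1)
  bleached <- simulate_frap(100, 0.9, 0.6, 100, acq_bleach_rate = 0.03,
                            noise_sd = 0, seed = 1)
  a <- normalize_frap(base, correct_acquisition = FALSE)
  b <- normalize_frap(bleached, correct_acquisition = TRUE)
  expect_equal(b$percent, a$percent, tolerance = 1e-8)
})

test_that("normalization validates its inputs", {
  fs <- simulate_frap(100, 0.9, 0.4, 120, seed = 1)
  expect_error(normalize_frap(fs, bleach_index = 3),
               class = "axc_error_parameter")
  flat <- frap_series(tibble::tibble(time_s = 0:9 * 30, raw = rep(5, 10),
                                     background = 0), 4)
  expect_error(normalize_frap(flat, correct_acquisition = FALSE),
               class = "axc_error_degenerate")
  no_ref <- frap_series(tibble::tibble(time_s = 0:9 * 30,
                                       raw = c(5, 5, 5, rep(1, 7)),
                                       background = 0), 4)
  expect_error(normalize_frap(no_ref), class = "axc_error_parameter")
})

test_that("curve averaging matches hand arithmetic and rejects mismatched grids", {
  fs1 <- simulate_frap(100, 0.9, 0.3, 120, noise_sd = 1, seed = 1)
  fs2 <- simulate_frap(100, 0.9, 0.3, 120, noise_sd = 1, seed = 2)
  avg <- average_recovery(list(normalize_frap(fs1), normalize_frap(fs2)))
  expect_equal(avg$mean_percent,
               (normalize_frap(fs1)$percent + normalize_frap(fs2)$percent) / 2)
  expect_equal(avg$n, rep(2, nrow(avg)))

  same <- average_recovery(list(normalize_frap(fs1), normalize_frap(fs1)))
  expect_equal(same$sd_percent, rep(0, nrow(same)))

  short <- simulate_frap(100, 0.9, 0.3, 120, n_frames = 10, seed = 3)
  expect_error(average_recovery(list(normalize_frap(fs1),
                                     normalize_frap(short))),
               class = "axc_error_alignment")
  expect_error(average_recovery(list()), class = "axc_error_parameter")
})

test_that("recovery_at reads the nearest sampled timepoint", {
  fs <- simulate_frap(100, 1, 0.4, 120, n_prebleach = 3, n_frames = 34,
                      frame_interval_s = 30, noise_sd = 0, seed = 1)
  nc <- normalize_frap(fs)
  bi <- attr(nc, "bleach_index")

  expect_equal(recovery_at(nc, nc$time_s[bi])$percent, 0)
  expect_equal(recovery_at(nc, 0)$percent, 100, tolerance = 1e-9)

  # 15 min after the bleach: 100 * 0.4 * (1 - exp(-900/120))
  t15 <- nc$time_s[bi] + 900
  expect_equal(recovery_at(nc, t15)$percent,
               100 * 0.4 * (1 - exp(-900 / 120)), tolerance = 1e-6)
  expect_error(recovery_at(nc, max(nc$time_s) + 60),
               class = "axc_error_range")
})

test_that("recovery fractions are recovered across a sweep with realistic noise", {
  for (rf in c(0, 0.25, 0.5, 0.75, 1)) {
    curves <- lapply(1:8, function(s) {
      normalize_frap(simulate_frap(100, 0.9, rf, 120, acq_bleach_rate = 0.005,
                                   noise_sd = 2, n_frames = 34, seed = s * 7))
    })
    avg <- average_recovery(curves)
    bi <- attr(avg, "bleach_index")
    got <- recovery_at(avg, avg$time_s[bi] + 900)$percent
    want <- 100 * rf * (1 - exp(-900 / 120))
    expect_lt(abs(got - want), 5)
  }
})
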