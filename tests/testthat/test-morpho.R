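test_that("Sholl of an empty mask is all zeros and the total matches the sum", {
  m <- binary_mask(matrix(FALSE, 40, 40), 1000)
  sp <- sholl(m, c(20, 20), step_um = 10, max_radius_um = 30)
  expect_equal(sp$intersections, rep(0L, 3))
  expect_equal(attr(sp, "total"), 0)

  mo <- simulate_morphology(4, 45, branch_prob = 0.4, seed = 6)
  sp2 <- sholl(mo$mask, mo$soma_px)
  expect_equal(attr(sp2, "total"), sum(sp2$intersections))
})

test_that("a straight 35 um neurite intersects circles at 10, 20 and 30 um once", {
  mo <- simulate_morphology(1, 35, branch_prob = 0, seed = 3)
  sp <- sholl(mo$mask, mo$soma_px, step_um = 10, max_radius_um = 50)
  expect_equal(sp$intersections[1:4], c(1L, 1L, 1L, 0L))
})

test_that("Sholl counts match the analytic circle-segment oracle across seeds", {
  hits <- 0L; n_ok <- 0L
  for (s in 1:20) {
    mo <- simulate_morphology(4, 50, branch_prob = 0.35, seed = s)
    sp <- sholl(mo$mask, mo$soma_px, step_um = 10,
                max_radius_um = max(mo$ground_truth$radius_um))
    gt <- mo$ground_truth
    # exclude radii grazing a segment endpoint (discretization tangencies)
    endd <- with(mo$segments, sqrt(c(x0, x1)^2 + c(y0, y1)^2))
    ok <- vapply(gt$radius_um,
                 function(r) all(abs(endd - r) > 1.5 * mo$pixel_size_um),
                 logical(1))
    hits <- hits + sum(sp$intersections[ok] == gt$intersections[ok])
    n_ok <- n_ok + sum(ok)
  }
  expect_gte(hits / n_ok, 0.95)
})

test_that("Sholl is unchanged by a quarter rotation and validates the center", {
  mo <- simulate_morphology(3, 40, branch_prob = 0.5, seed = 4)
  msk <- unclass(mo$mask)
  n <- nrow(msk)     # square grid, soma at the central pixel
  rot <- t(msk)[, n:1]   # 90 degree rotation
  sp <- sholl(mo$mask, mo$soma_px, step_um = 10, max_radius_um = 60)
  spr <- sholl(binary_mask(rot, pixel_size_nm = mo$pixel_size_um * 1000),
               mo$soma_px, step_um = 10, max_radius_um = 60)
  expect_identical(sp$intersections, spr$intersections)

  expect_error(sholl(mo$mask, c(-5, 10)), class = "axc_error_geometry")
})

test_that("a static punctum yields a constant bright kymograph row", {
  frames <- lapply(1:6, function(i) {
    m <- matrix(0, 9, 30); m[5, 12] <- 7
    pixel_image(m, 100)
  })
  path <- tibble::tibble(x_nm = c(50, 2950), y_nm = c(450, 450))
  k <- kymograph(frames, path, thickness_px = 1)
  bright <- which(unclass(k) > 3, arr.ind = TRUE)
  expect_equal(unique(bright[, "col"]), 1:6)        # present in every frame
  expect_equal(length(unique(bright[, "row"])), 1)  # always the same position
})

test_that("a punctum moving one pixel per frame traces the diagonal", {
  n_frames <- 8
  frames <- lapply(seq_len(n_frames), function(i) {
    m <- matrix(0, 5, 20); m[3, 5 + i] <- 10
    pixel_image(m, 100)
  })
  path <- tibble::tibble(x_nm = c(550, 1950), y_nm = c(250, 250))
  k <- kymograph(frames, path, thickness_px = 1)
  for (f in seq_len(n_frames)) {
    expect_equal(which.max(unclass(k)[, f]), f)
  }
})

test_that("uniform stacks give constant kymographs and reversed paths reverse rows", {
  frames <- lapply(1:4, function(i) pixel_image(matrix(4, 6, 25), 100))
  path <- tibble::tibble(x_nm = c(150, 2350), y_nm = c(300, 300))
  k <- kymograph(frames, path)
  expect_true(all(abs(unclass(k) - 4) < 1e-12))

  set.seed(8)
  noisy <- lapply(1:3, function(i) pixel_image(matrix(runif(150), 6, 25), 100))
  fwd <- kymograph(noisy, path, thickness_px = 3)
  rev_path <- path[2:1, ]
  bwd <- kymograph(noisy, rev_path, thickness_px = 3)
  expect_equal(bare(bwd), bare(fwd)[nrow(fwd):1, ], tolerance = 1e-12)

  outside <- tibble::tibble(x_nm = c(-500, 1000), y_nm = c(300, 300))
  expect_error(kymograph(noisy, outside), class = "axc_error_geometry")
})
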