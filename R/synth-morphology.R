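#' Simulate a neuron fill mask for Sholl analysis
#'
#' Grows a planar tree of straight neurite segments from a soma, rasterizes
#' it into a binary fill mask (as a thresholded cell-fill image would give)
#' and co-emits the analytic circle-crossing counts computed directly from
#' the segment list — the ground truth against which raster Sholl counting
#' is validated.
#'
#' @param n_primary Number of primary neurites (>= 1).
#' @param mean_length_um Mean primary neurite length (um).
#' @param branch_prob Probability that a segment tip bifurcates (child
#'   segments are shorter by a fixed ratio; three generations maximum).
#' @param seed Integer seed.
#' @param pixel_size_um Raster pixel size (um).
#' @param step_um Radius step for the co-emitted ground truth (um).
#' @param soma_radius_um Radius of the filled soma disk (um).
#' @return A list of class `morphology_sim`: `mask` ([binary_mask()]),
#'   `soma_px` (continuous pixel coordinates `c(x, y)` of the soma center),
#'   `segments` (tibble `x0,y0,x1,y1` in um, soma at the origin),
#'   `ground_truth` (tibble `radius_um`, `intersections`).
#' @examples
#' m <- simulate_morphology(3, 40, branch_prob = 0.4, seed = 2)
#' m$ground_truth
#' @export
simulate_morphology <- function(n_primary, mean_length_um = 60,
                                branch_prob = 0.3, seed = 1L,
                                pixel_size_um = 0.5, step_um = 10,
                                soma_radius_um = 4) {
  if (n_primary < 1) abort("`n_primary` must be >= 1.",
                           class = "axc_error_parameter")
  if (branch_prob < 0 || branch_prob > 1) {
    abort("`branch_prob` must lie in [0, 1].", class = "axc_error_parameter")
  }
  if (mean_length_um <= 0 || pixel_size_um <= 0) {
    abort("Lengths must be positive.", class = "axc_error_parameter")
  }

  segments <- with_seed(seed_stream(seed, "morpho"), {
    segs <- list()
    grow <- function(p0, angle, len, depth) {
      p1 <- p0 + len * c(cos(angle), sin(angle))
      segs[[length(segs) + 1L]] <<- c(p0, p1)
      if (depth < 3L && runif(1) < branch_prob) {
        spread <- runif(2, 0.3, 0.7)
        grow(p1, angle + spread[1], len * 0.6, depth + 1L)
        grow(p1, angle - spread[2], len * 0.6, depth + 1L)
      }
    }
    base <- runif(1, 0, 2 * pi)
    for (k in seq_len(n_primary)) {
      ang <- base + 2 * pi * (k - 1) / n_primary + runif(1, -0.25, 0.25)
      grow(c(0, 0), ang, mean_length_um * runif(1, 0.8, 1.2), 1L)
    }
    m <- do.call(rbind, segs)
    tibble(x0 = m[, 1], y0 = m[, 2], x1 = m[, 3], y1 = m[, 4])
  })

  reach <- max(sqrt(segments$x1^2 + segments$y1^2), soma_radius_um)
  half_px <- ceiling((reach + 2 * step_um) / pixel_size_um)
  n <- 2L * half_px + 1L
  center <- half_px + 1    # soma sits at the central pixel's center (x = y)
  mask <- matrix(FALSE, n, n)

  # soma disk
  cx <- center; cy <- center
  ii <- seq_len(n)
  dist2 <- outer((ii - cy)^2, (ii - cx)^2, "+")
  mask[dist2 <= (soma_radius_um / pixel_size_um)^2] <- TRUE

  # rasterize segments by dense sampling (quarter-pixel steps)
  for (i in seq_len(nrow(segments))) {
    p0 <- c(segments$x0[i], segments$y0[i]) / pixel_size_um
    p1 <- c(segments$x1[i], segments$y1[i]) / pixel_size_um
    len <- sqrt(sum((p1 - p0)^2))
    ts <- seq(0, 1, length.out = max(2L, ceiling(len / 0.25) + 1L))
    xs <- cx + p0[1] + ts * (p1[1] - p0[1])
    ys <- cy + p0[2] + ts * (p1[2] - p0[2])
    rc <- unique(cbind(pmin(pmax(round(ys), 1L), n),
                       pmin(pmax(round(xs), 1L), n)))
    mask[rc] <- TRUE
  }

  radii <- seq(step_um, ceiling(reach / step_um) * step_um, by = step_um)
  gt <- sholl_from_segments(segments, center = c(0, 0), radii_um = radii)

  structure(
    list(mask = binary_mask(mask, pixel_size_nm = pixel_size_um * 1000),
         soma_px = c(x = cx, y = cy),
         segments = segments,
         ground_truth = gt,
         pixel_size_um = pixel_size_um,
         seed = as.integer(seed)),
    class = "morphology_sim"
  )
}

#' @export
print.morphology_sim <- function(x, ...) {
  cat(sprintf("<morphology_sim> %d segment(s), mask %d x %d px (%.2g um/px)\n",
              nrow(x$segments), nrow(x$mask), ncol(x$mask), x$pixel_size_um))
  invisible(x)
}

#' Analytic circle-crossing counts for a segment list
#'
#' Counts the intersection points of each concentric circle with a set of
#' straight segments by solving the circle-line quadratic per segment — the
#' closed-form oracle for raster Sholl counting.
#'
#' @param segments Tibble/data frame with `x0, y0, x1, y1` (same units as
#'   `radii_um`).
#' @param center Circle center `c(x, y)`.
#' @param radii_um Radii at which to count.
#' @return A [sholl_profile] tibble (`radius_um`, `intersections`).
#' @export
sholl_from_segments <- function(segments, center, radii_um) {
  counts <- vapply(radii_um, function(r) {
    n <- 0L
    for (i in seq_len(nrow(segments))) {
      p0 <- c(segments$x0[i], segments$y0[i]) - center
      d <- c(segments$x1[i], segments$y1[i]) - center - p0
      a <- sum(d^2)
      b <- 2 * sum(d * p0)
      cc <- sum(p0^2) - r^2
      disc <- b^2 - 4 * a * cc
      if (disc < 0) next
      tt <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
      n <- n + sum(tt >= 0 & tt <= 1)
    }
    n
  }, integer(1))
  new_sholl_profile(radii_um, counts, step_um = if (length(radii_um) > 1)
    radii_um[2] - radii_um[1] else radii_um[1])
}
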