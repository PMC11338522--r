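new_sholl_profile <- function(radii_um, intersections, step_um) {
  structure(
    tibble(radius_um = radii_um, intersections = as.integer(intersections)),
    total = sum(intersections),
    step_um = step_um,
    class = c("sholl_profile", class(tibble()))
  )
}

#' @export
print.sholl_profile <- function(x, ...) {
  cat(sprintf("<sholl_profile> step %.3g um, %d radii, total %d intersections\n",
              attr(x, "step_um"), nrow(x), attr(x, "total")))
  NextMethod()
}

#' Sholl analysis of a thresholded neuron fill
#'
#' Counts neurite intersections with concentric circles around the soma.
#' For each radius the discretized circle (an annulus of 1.5 px width
#' around `r`, wide enough that an 8-connected neurite path cannot step
#' across it) is intersected with the mask, and each 8-connected component
#' of foreground pixels counts as one intersection — the standard Sholl
#' definition, robust to neurite thickness in pixels.
#' Radii advance in fixed steps (conventionally 10 um) from one step
#' outward; the default maximum is the image diagonal so the whole arbor is
#' covered.
#'
#' @param fill_mask A [binary_mask()] (thresholded cell fill).
#' @param center Soma center `c(x, y)` in continuous pixel coordinates
#'   (integer coordinates address pixel centers).
#' @param step_um Radius step in micrometres.
#' @param max_radius_um Largest radius; defaults to the image diagonal.
#' @return A `sholl_profile` tibble (`radius_um`, `intersections`) with
#'   attribute `total` (their sum).
#' @examples
#' m <- simulate_morphology(3, 40, branch_prob = 0, seed = 1)
#' sholl(m$mask, m$soma_px)
#' @export
sholl <- function(fill_mask, center, step_um = 10, max_radius_um = NULL) {
  if (step_um <= 0) abort("`step_um` must be > 0.",
                          class = "axc_error_parameter")
  m <- unclass(fill_mask)
  px_um <- pixel_size_nm(fill_mask) / 1000
  nr <- nrow(m); nc <- ncol(m)
  cx <- center[1]; cy <- center[2]
  if (cx < 0.5 || cx > nc + 0.5 || cy < 0.5 || cy > nr + 0.5) {
    abort("`center` lies outside the mask.", class = "axc_error_geometry")
  }
  max_radius_um <- max_radius_um %||% (sqrt(nr^2 + nc^2) * px_um)
  radii <- seq(step_um, max_radius_um, by = step_um)
  if (length(radii) == 0) {
    return(new_sholl_profile(numeric(0), integer(0), step_um))
  }

  # pixel-center distances and angles from the soma, computed once
  dx <- matrix(rep(seq_len(nc) - cx, each = nr), nr, nc)
  dy <- matrix(rep(seq_len(nr) - cy, times = nc), nr, nc)
  dist <- sqrt(dx^2 + dy^2)

  counts <- vapply(radii, function(r_um) {
    r_px <- r_um / px_um
    # annulus half-width 0.75 px: wider than sqrt(2)/2, so an 8-connected
    # neurite path cannot step across the ring without leaving a pixel in it
    ring <- which(dist >= r_px - 0.75 & dist < r_px + 0.75)
    on <- ring[m[ring]]
    count_components_8(on, nr)
  }, integer(1))

  new_sholl_profile(radii, counts, step_um)
}

# Number of 8-connected components among the pixels with the given linear
# indices (column-major, `nr` rows). Union-find with path halving; the
# per-ring pixel sets are small.
count_components_8 <- function(idx, nr) {
  n <- length(idx)
  if (n == 0L) return(0L)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    nb <- match((cc + off[2] - 1L) * nr + (rr + off[1]), idx)
    nb[rr + off[1] < 1L | rr + off[1] > nr] <- NA_integer_   # no row wrap
    for (i in which(!is.na(nb))) {
      a <- find(i); b <- find(nb[i])
      if (a != b) parent[a] <- b
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Kymograph from a time-lapse stack along a traced path
#'
#' Reslices the movie along a path: each frame is resampled by bilinear
#' interpolation at one-pixel arc steps, intensities across the stated
#' perpendicular thickness are projected (maximum by default, matching a
#' z-projection of the resliced band), and the per-frame profiles are
#' stacked as columns. Row 0 corresponds to the path start, so anterograde
#' movement along the trace appears as streaks advancing down the rows over
#' time.
#'
#' @param stack List of congruent [pixel_image()] frames, or a 3D array
#'   (y, x, frame) plus `pixel_size_nm`.
#' @param path An [make_axon_trace()] result or vertex data frame
#'   (`x_nm`, `y_nm`).
#' @param thickness_px Perpendicular band thickness in pixels (>= 1).
#' @param projection `"max"` (default) or `"mean"` across the band.
#' @param pixel_size_nm Required when `stack` is a bare array.
#' @param frame_interval_s Optional frame interval, recorded on the result.
#' @return A `kymograph`: matrix (rows = positions along the path, columns
#'   = frames) with pixel size and interval attributes.
#' @export
kymograph <- function(stack, path, thickness_px = 1L,
                      projection = c("max", "mean"),
                      pixel_size_nm = NULL, frame_interval_s = NA_real_) {
  projection <- match.arg(projection)
  if (thickness_px < 1) abort("`thickness_px` must be >= 1.",
                              class = "axc_error_parameter")
  if (is.array(stack) && length(dim(stack)) == 3L) {
    if (is.null(pixel_size_nm)) {
      abort("Supply `pixel_size_nm` with an array stack.",
            class = "axc_error_parameter")
    }
    frames <- lapply(seq_len(dim(stack)[3]), function(i) {
      pixel_image(stack[, , i], pixel_size_nm)
    })
  } else if (is.list(stack) && length(stack) > 0 &&
             all(vapply(stack, inherits, logical(1), "pixel_image"))) {
    frames <- stack
  } else {
    abort("`stack` must be a list of pixel_image frames or a 3D array.",
          class = "axc_error_parameter")
  }
  px <- pixel_size_nm(frames[[1]])
  or <- attr(frames[[1]], "origin_nm") %||% c(0, 0)
  xy <- trace_vertices(path)
  rs <- resample_polyline(xy, step = px)
  ccol <- (rs$points[, 1] - or[1]) / px + 0.5
  crow <- (rs$points[, 2] - or[2]) / px + 0.5
  normal <- cbind(-rs$tangents[, 2], rs$tangents[, 1])
  offsets <- seq(-(thickness_px - 1) / 2, (thickness_px - 1) / 2, by = 1)

  prof <- function(mat) {
    band <- vapply(offsets, function(o) {
      bilinear(mat, crow + o * normal[, 2], ccol + o * normal[, 1])
    }, numeric(length(ccol)))
    band <- matrix(band, nrow = length(ccol))
    if (projection == "max") apply(band, 1, max) else rowMeans(band)
  }
  k <- vapply(frames, function(f) prof(unclass(f)), numeric(length(ccol)))
  structure(matrix(k, nrow = length(ccol)),
            pixel_size_nm = px,
            frame_interval_s = frame_interval_s,
            path_length_nm = rs$total_length,
            class = c("kymograph", "matrix", "array"))
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d positions x %d frames (path %.2g um)\n",
              nrow(x), ncol(x), attr(x, "path_length_nm") / 1000))
  invisible(x)
}
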