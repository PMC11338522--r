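#' Threshold the ER channel into a binary mask
#'
#' Pixels strictly above the threshold become foreground. The default
#' threshold is Otsu's method (parameter-free and reproducible); a fixed
#' threshold can be supplied instead. The same operation serves to
#' threshold neuron fill images upstream of Sholl analysis, so one
#' thresholding implementation is used repo-wide.
#'
#' @param er_image A [pixel_image()].
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Threshold value, required for `method = "fixed"`.
#' @return A [binary_mask()] with attribute `threshold` recording the value
#'   used.
#' @examples
#' img <- pixel_image(matrix(c(rep(10, 6), rep(200, 3)), 3, 3), 20)
#' segment_er_mask(img)
#' @export
segment_er_mask <- function(er_image, method = c("otsu", "fixed"),
                            fixed_threshold = NULL) {
  method <- match.arg(method)
  if (length(er_image) == 0) {
    abort("Empty image.", class = "axc_error_parameter")
  }
  mx <- max(er_image)
  if (method == "otsu") {
    if (mx == min(er_image)) {
      abort("Constant image: Otsu thresholding needs a bimodal histogram.",
            class = "axc_error_degenerate")
    }
    th <- EBImage::otsu(EBImage::Image(unclass(er_image) / mx),
                        range = c(0, 1), levels = 256L) * mx
  } else {
    if (is.null(fixed_threshold) || !is.numeric(fixed_threshold)) {
      abort("`fixed_threshold` is required for method = \"fixed\".",
            class = "axc_error_parameter")
    }
    th <- fixed_threshold
  }
  binary_mask(unclass(er_image) > th, pixel_size_nm = pixel_size_nm(er_image),
              threshold = th)
}

#' Morphologically dilate a mask by a physical distance
#'
#' Dilation with a disk of pixel radius `ceiling(distance_nm /
#' pixel_size_nm)`, with a minimum of one pixel for any positive distance: a
#' sub-pixel enlargement (such as 5 nm at 20 nm pixels) still grows the mask
#' by one pixel, so the enlarged measure is never identical to the plain
#' mask. `distance_nm = 0` is the identity. The disk contains the offsets
#' with `dx^2 + dy^2 <= r^2`.
#'
#' @param mask A [binary_mask()].
#' @param distance_nm Enlargement distance in nanometres (>= 0).
#' @return The dilated [binary_mask()] (always a superset of the input).
#' @examples
#' m <- binary_mask(matrix(c(rep(FALSE, 4), TRUE, rep(FALSE, 4)), 3, 3), 10)
#' sum(dilate_mask(m, 5))   # 5-pixel cross
#' @export
dilate_mask <- function(mask, distance_nm) {
  if (distance_nm < 0) abort("`distance_nm` must be >= 0.",
                             class = "axc_error_parameter")
  if (distance_nm == 0) return(mask)
  px <- pixel_size_nm(mask)
  r <- max(1L, as.integer(ceiling(distance_nm / px)))
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= r^2, ]
  m <- unclass(mask)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(off))) {
    dy <- off$dy[i]; dx <- off$dx[i]
    sr <- max(1L, 1L - dy):min(nr, nr - dy)
    sc <- max(1L, 1L - dx):min(nc, nc - dx)
    out[sr + dy, sc + dx] <- out[sr + dy, sc + dx] | m[sr, sc]
  }
  binary_mask(out, pixel_size_nm = px, threshold = attr(mask, "threshold"))
}

#' Fraction of channel intensity falling inside a mask
#'
#' The core association statistic: the sum of ribosome-channel intensities
#' over mask pixels divided by the sum over all pixels.
#'
#' @param ribo_image A [pixel_image()].
#' @param mask A congruent [binary_mask()].
#' @return A single number in `[0, 1]`.
#' @examples
#' img <- pixel_image(matrix(1, 2, 4), 20)
#' m <- binary_mask(matrix(c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 4)), 2, 4), 20)
#' contact_fraction(img, m)
#' @export
contact_fraction <- function(ribo_image, mask) {
  check_congruent(ribo_image, mask)
  tot <- sum(ribo_image)
  if (tot <= 0) {
    abort("Zero total intensity: the fraction is undefined.",
          class = "axc_error_degenerate")
  }
  sum(ribo_image[unclass(mask)]) / tot
}

#' Mirror an image about its vertical midline
#'
#' Reverses the column (along-axon) order; in straightened segments this is
#' the horizontal flip used to build the chance-overlap null.
#'
#' @param image A [pixel_image()].
#' @return The flipped [pixel_image()].
#' @export
flip_image <- function(image) {
  pixel_image(unclass(image)[, rev(seq_len(ncol(image))), drop = FALSE],
              pixel_size_nm = pixel_size_nm(image),
              channel = attr(image, "channel"),
              origin_nm = attr(image, "origin_nm") %||% c(0, 0))
}

#' Flipped-channel chance-overlap null
#'
#' Computes [contact_fraction()] after mirroring the ribosome channel
#' left-right while keeping the ER mask in place. Any overlap that survives
#' the flip reflects chance coincidence of the two channels, so a genuine
#' association shows up as flipped < unflipped.
#'
#' @inheritParams contact_fraction
#' @return A single number in `[0, 1]`.
#' @export
flip_null <- function(ribo_image, mask) {
  contact_fraction(flip_image(ribo_image), mask)
}

#' Render a localization table into a pixel image
#'
#' 2D histogram of localization positions with half-open pixel bins
#' (`[i*px, (i+1)*px)`), optionally blurred with a Gaussian; the blur is
#' mass-conserving, so total intensity equals the localization count up to
#' kernel truncation.
#'
#' @param table Localization tibble with `x_nm`, `y_nm` and `channel`.
#' @param pixel_size_nm Reconstruction pixel size (nm).
#' @param blur_sd_nm Gaussian rendering blur sd (nm; 0 = raw histogram).
#' @param channel Channel to render (required if the table has several).
#' @param xlim,ylim Optional world-coordinate limits `c(lo, hi)` (nm); by
#'   default the pixel grid starts at the floor of the data range.
#' @return A [pixel_image()].
#' @examples
#' locs <- tibble::tibble(x_nm = c(5, 25), y_nm = c(5, 5), channel = "ribo")
#' render_localizations(locs, pixel_size_nm = 20, channel = "ribo")
#' @export
render_localizations <- function(table, pixel_size_nm, blur_sd_nm = 0,
                                 channel = NULL, xlim = NULL, ylim = NULL) {
  if (!is.data.frame(table) || !all(c("x_nm", "y_nm") %in% names(table))) {
    abort("`table` must have columns x_nm and y_nm.",
          class = "axc_error_parameter")
  }
  if (!is.null(channel)) {
    if (!"channel" %in% names(table)) {
      abort("`table` has no channel column.", class = "axc_error_parameter")
    }
    table <- table[table$channel == channel, , drop = FALSE]
  } else if ("channel" %in% names(table) &&
             length(unique(table$channel)) > 1L) {
    abort("Multiple channels present: specify `channel`.",
          class = "axc_error_parameter")
  }
  if (nrow(table) == 0) {
    abort("No localizations for the requested channel.",
          class = "axc_error_empty")
  }
  px <- pixel_size_nm
  xlim <- xlim %||% c(floor(min(table$x_nm) / px) * px,
                      ceiling(max(table$x_nm) / px + 1e-9) * px)
  ylim <- ylim %||% c(floor(min(table$y_nm) / px) * px,
                      ceiling(max(table$y_nm) / px + 1e-9) * px)
  nx <- max(1L, as.integer(round((xlim[2] - xlim[1]) / px)))
  ny <- max(1L, as.integer(round((ylim[2] - ylim[1]) / px)))
  col <- floor((table$x_nm - xlim[1]) / px) + 1L
  row <- floor((table$y_nm - ylim[1]) / px) + 1L
  keep <- col >= 1L & col <= nx & row >= 1L & row <= ny
  counts <- matrix(0, ny, nx)
  for (i in which(keep)) {
    counts[row[i], col[i]] <- counts[row[i], col[i]] + 1
  }
  if (blur_sd_nm > 0) counts <- blur_gaussian(counts, blur_sd_nm / px)
  lab <- channel %||%
    (if ("channel" %in% names(table)) table$channel[1] else "")
  pixel_image(counts, px, channel = lab, origin_nm = c(xlim[1], ylim[1]))
}

#' Full contact analysis of one two-channel segment
#'
#' Composition of the per-segment workflow: threshold the ER channel,
#' enlarge the mask, and measure the ribosome-channel intensity proportion
#' in the plain mask, the enlarged mask and under the flipped-channel null.
#'
#' @param er_image ER-channel [pixel_image()].
#' @param ribo_image Ribosome-channel [pixel_image()], congruent with
#'   `er_image`.
#' @param dilate_nm Mask enlargement distance (nm; the conventional value
#'   is 5 nm, which at super-resolution pixel sizes rounds up to one pixel).
#' @param threshold,fixed_threshold Passed to [segment_er_mask()].
#' @return One-row tibble: `fraction_in_mask`, `fraction_in_enlarged`,
#'   `fraction_flipped`, `mask_area_fraction`, `threshold_used`.
#' @examples
#' segs <- simulate_contact_segments("fig2-sted-contact", 1, seed = 5)
#' analyze_segment(segs$er_image[[1]], segs$ribo_image[[1]])
#' @export
analyze_segment <- function(er_image, ribo_image, dilate_nm = 5,
                            threshold = c("otsu", "fixed"),
                            fixed_threshold = NULL) {
  check_congruent(er_image, ribo_image, "the two channels")
  if (!isTRUE(all.equal(pixel_size_nm(er_image), pixel_size_nm(ribo_image)))) {
    abort("The two channels must share a pixel size.",
          class = "axc_error_parameter")
  }
  mask <- segment_er_mask(er_image, method = threshold,
                          fixed_threshold = fixed_threshold)
  enlarged <- dilate_mask(mask, dilate_nm)
  tibble(
    fraction_in_mask = contact_fraction(ribo_image, mask),
    fraction_in_enlarged = contact_fraction(ribo_image, enlarged),
    fraction_flipped = flip_null(ribo_image, mask),
    mask_area_fraction = mean(mask),
    threshold_used = attr(mask, "threshold")
  )
}

#' Batch contact analysis over simulated or listed segments
#'
#' Maps [analyze_segment()] over a tibble holding `er_image` and
#' `ribo_image` list-columns (as produced by
#' [simulate_contact_segments()]), binding the per-segment results onto the
#' identifying columns.
#'
#' @param segments Tibble with `er_image` and `ribo_image` list-columns.
#' @param ... Passed to [analyze_segment()].
#' @return The input identifying columns plus the [analyze_segment()]
#'   columns, one row per segment.
#' @export
analyze_segments <- function(segments, ...) {
  if (!all(c("er_image", "ribo_image") %in% names(segments))) {
    abort("`segments` needs er_image and ribo_image list-columns.",
          class = "axc_error_parameter")
  }
  res <- purrr::map2(segments$er_image, segments$ribo_image,
                     function(er, ribo) analyze_segment(er, ribo, ...)) |>
    purrr::list_rbind()
  dplyr::bind_cols(
    segments[, setdiff(names(segments),
                       c("er_image", "ribo_image", "scene")), drop = FALSE],
    res
  )
}
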