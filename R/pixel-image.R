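#' Single-channel intensity image with physical pixel size
#'
#' The carrier type for every imaged channel. Intensities are stored as a
#' numeric matrix with rows indexing the transverse (y) direction and columns
#' the along-axon (x) direction. Pixel `[i, j]` has its center at world
#' coordinate `origin_nm + (j - 0.5, i - 0.5) * pixel_size_nm`, i.e. pixel
#' centers sit at half-integer multiples of the pixel size.
#'
#' @param intensities Numeric matrix of non-negative intensities.
#' @param pixel_size_nm Physical edge length of one pixel, in nanometres.
#' @param channel Channel label (free text, e.g. `"er"` or `"ribo"`).
#' @param origin_nm Length-2 numeric, world coordinate (x, y) of the outer
#'   corner of pixel `[1, 1]`, in nanometres.
#' @return A `pixel_image` object.
#' @examples
#' img <- pixel_image(matrix(0, 4, 8), pixel_size_nm = 20)
#' dim(img)
#' @export
pixel_image <- function(intensities, pixel_size_nm, channel = "",
                        origin_nm = c(0, 0)) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    abort("`intensities` must be a numeric matrix.", class = "axc_error_parameter")
  }
  if (anyNA(intensities) || any(intensities < 0)) {
    abort("Image intensities must be finite and non-negative.",
          class = "axc_error_parameter")
  }
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      pixel_size_nm <= 0) {
    abort("`pixel_size_nm` must be a single positive number.",
          class = "axc_error_parameter")
  }
  structure(intensities,
            pixel_size_nm = as.numeric(pixel_size_nm),
            channel = as.character(channel),
            origin_nm = as.numeric(origin_nm),
            class = c("pixel_image", "matrix", "array"))
}

#' @export
print.pixel_image <- function(x, ...) {
  cat(sprintf("<pixel_image> %d x %d px, %.4g nm/px, channel \"%s\"\n",
              nrow(x), ncol(x), attr(x, "pixel_size_nm"), attr(x, "channel")))
  cat(sprintf("  intensity range [%.4g, %.4g], total %.6g\n",
              min(x), max(x), sum(x)))
  invisible(x)
}

#' @describeIn pixel_image Pixel size accessor (nm).
#' @param image,x A `pixel_image`.
#' @export
pixel_size_nm <- function(image) {
  ps <- attr(image, "pixel_size_nm")
  if (is.null(ps)) abort("Object carries no pixel size.",
                         class = "axc_error_parameter")
  ps
}

#' Long-format view of a pixel image
#'
#' @param x A `pixel_image`.
#' @param ... Unused.
#' @return Tibble with `x_nm`, `y_nm` (pixel centers) and `intensity`.
#' @exportS3Method tibble::as_tibble
as_tibble.pixel_image <- function(x, ...) {
  ps <- pixel_size_nm(x)
  or <- attr(x, "origin_nm") %||% c(0, 0)
  tibble(
    x_nm = rep(or[1] + (seq_len(ncol(x)) - 0.5) * ps, each = nrow(x)),
    y_nm = rep(or[2] + (seq_len(nrow(x)) - 0.5) * ps, times = ncol(x)),
    intensity = as.vector(unclass(x))
  )
}

#' Binary segmentation mask congruent with a pixel image
#'
#' @param mask Logical matrix.
#' @param pixel_size_nm Pixel edge length in nanometres.
#' @param threshold Threshold that produced the mask (`NA` if not applicable).
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(mask, pixel_size_nm, threshold = NA_real_) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort("`mask` must be a logical matrix.", class = "axc_error_parameter")
  }
  structure(mask,
            pixel_size_nm = as.numeric(pixel_size_nm),
            threshold = as.numeric(threshold),
            class = c("binary_mask", "matrix", "array"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %.4g nm/px, %d/%d foreground (%.1f%%)\n",
              nrow(x), ncol(x), attr(x, "pixel_size_nm"),
              sum(x), length(x), 100 * mean(x)))
  invisible(x)
}

# shape congruence check used by the contact estimators
check_congruent <- function(a, b, what = "image and mask") {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("Shape mismatch: %s must share dimensions (%s vs %s).",
                  what, paste(dim(a), collapse = "x"),
                  paste(dim(b), collapse = "x")),
          class = "axc_error_shape")
  }
  invisible(TRUE)
}
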