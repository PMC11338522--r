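#' Background-corrected mean intensity along a segmented line
#'
#' Resamples the image along a polyline at one-pixel arc steps, averaging
#' bilinear samples across the stated perpendicular width, and subtracts the
#' mean of an explicit background ROI. This mirrors segmented-line
#' quantification of axonal segments: the profile mean is the readout, the
#' background ROI makes the correction explicit rather than implicit.
#'
#' @param image A [pixel_image()].
#' @param trace An [make_axon_trace()] result or a data frame of polyline
#'   vertices (`x_nm`, `y_nm`, world coordinates).
#' @param width_px Perpendicular averaging width in pixels (>= 1; samples at
#'   1 px spacing centered on the line).
#' @param background_roi Background rectangle `c(x, y, w, h)` in 0-based
#'   pixel offsets (x = column, y = row), disjoint from the profile band.
#' @return One-row tibble: `raw_mean`, `background`, `corrected_mean`,
#'   `profile_length_um`, `line_width_px`, `negative_flag` (corrected mean
#'   below zero is retained but flagged, since truncation would bias
#'   downstream percent changes).
#' @examples
#' img <- pixel_image(matrix(5, 20, 40), pixel_size_nm = 100)
#' tr <- tibble::tibble(x_nm = c(500, 3500), y_nm = c(1000, 1000))
#' profile_mean(img, tr, width_px = 3, background_roi = c(0, 16, 40, 4))
#' @export
profile_mean <- function(image, trace, width_px = 1L, background_roi) {
  if (width_px < 1) abort("`width_px` must be >= 1.",
                          class = "axc_error_parameter")
  px <- pixel_size_nm(image)
  or <- attr(image, "origin_nm") %||% c(0, 0)
  xy <- trace_vertices(trace)

  rs <- resample_polyline(xy, step = px)
  # world -> continuous pixel-center coordinates
  ccol <- (rs$points[, 1] - or[1]) / px + 0.5
  crow <- (rs$points[, 2] - or[2]) / px + 0.5
  normal <- cbind(-rs$tangents[, 2], rs$tangents[, 1])
  offsets <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, by = 1)

  mat <- unclass(image)
  vals <- matrix(NA_real_, length(ccol), length(offsets))
  band_px <- matrix(FALSE, nrow(mat), ncol(mat))
  for (j in seq_along(offsets)) {
    rj <- crow + offsets[j] * normal[, 2]
    cj <- ccol + offsets[j] * normal[, 1]
    vals[, j] <- bilinear(mat, rj, cj)
    ri <- pmin(pmax(round(rj), 1L), nrow(mat))
    ci <- pmin(pmax(round(cj), 1L), ncol(mat))
    band_px[cbind(ri, ci)] <- TRUE
  }

  roi <- parse_roi(background_roi, dim(mat))
  if (any(band_px[roi$rows, roi$cols])) {
    abort("Background ROI overlaps the profile band.",
          class = "axc_error_parameter")
  }
  bg <- mean(mat[roi$rows, roi$cols])

  raw <- mean(vals)
  corrected <- raw - bg
  tibble(
    raw_mean = raw,
    background = bg,
    corrected_mean = corrected,
    profile_length_um = rs$total_length / 1000,
    line_width_px = as.integer(width_px),
    negative_flag = corrected < 0
  )
}

# ROI c(x, y, w, h), 0-based offsets, -> 1-based row/col index ranges.
parse_roi <- function(roi, dims) {
  if (!is.numeric(roi) || length(roi) != 4L || roi[3] < 1 || roi[4] < 1) {
    abort("`background_roi` must be c(x, y, w, h) with w, h >= 1.",
          class = "axc_error_parameter")
  }
  rows <- (roi[2] + 1):(roi[2] + roi[4])
  cols <- (roi[1] + 1):(roi[1] + roi[3])
  if (min(rows) < 1 || max(rows) > dims[1] ||
      min(cols) < 1 || max(cols) > dims[2]) {
    abort("`background_roi` exceeds the image bounds.",
          class = "axc_error_parameter")
  }
  list(rows = rows, cols = cols)
}

#' Percent change between condition means
#'
#' `100 * (mean(control) - mean(test)) / mean(control)`; positive values are
#' reductions in the test condition.
#'
#' @param control_values,test_values Non-empty numeric vectors of
#'   background-corrected means.
#' @return Percent change (single number).
#' @examples
#' percent_change(c(2, 4), c(1, 2))   # 50
#' @export
percent_change <- function(control_values, test_values) {
  if (length(control_values) == 0 || length(test_values) == 0) {
    abort("Both value sets must be non-empty.", class = "axc_error_parameter")
  }
  mc <- mean(control_values)
  if (mc <= 0) {
    abort("Non-positive control mean: percent change undefined.",
          class = "axc_error_degenerate")
  }
  100 * (mc - mean(test_values)) / mc
}

#' Dendrite/axon polarity index
#'
#' `PI = (Id - Ia) / (Id + Ia)`, where `Id` is the average mean intensity of
#' exactly three dendrites and `Ia` the axonal mean intensity. `PI = 0`
#' marks a non-polarized distribution, `PI < 0` axonal enrichment and
#' `PI > 0` dendritic enrichment.
#'
#' @param axon_intensity Background-corrected axonal mean (>= 0).
#' @param dendrite_intensities Exactly three background-corrected dendritic
#'   means (>= 0).
#' @return One-row tibble: `pi`, `i_d`, `i_a`.
#' @examples
#' polarity_index(10, c(30, 30, 30))   # pi = 0.5
#' @export
polarity_index <- function(axon_intensity, dendrite_intensities) {
  if (length(dendrite_intensities) != 3L) {
    abort("Exactly three dendrite intensities are required.",
          class = "axc_error_parameter")
  }
  if (length(axon_intensity) != 1L) {
    abort("`axon_intensity` must be a single value.",
          class = "axc_error_parameter")
  }
  if (any(c(axon_intensity, dendrite_intensities) < 0)) {
    abort("Intensities must be non-negative.", class = "axc_error_parameter")
  }
  i_d <- mean(dendrite_intensities)
  i_a <- axon_intensity
  if (i_d + i_a == 0) {
    abort("Id + Ia = 0: polarity index undefined.",
          class = "axc_error_degenerate")
  }
  tibble(pi = (i_d - i_a) / (i_d + i_a), i_d = i_d, i_a = i_a)
}

#' Normalize split-APEX streptavidin intensities
#'
#' Within each experimental batch, streptavidin intensities are divided by
#' that batch's control-condition mean, so the control mean is 1 by
#' construction and batches are comparable. With `correct_expression =
#' TRUE` each cell's streptavidin value is first divided by the product of
#' its V5 and HA intensities (the expression levels of the two split
#' fragments) before batch normalization; cells with a zero expression
#' marker are flagged and excluded.
#'
#' @param measurements Data frame with columns `strep`, `condition`,
#'   `batch_id`, and (for expression correction) `v5`, `ha`.
#' @param control_condition Condition label of the control group.
#' @param correct_expression Divide by `v5 * ha` per cell first?
#' @return Tibble with `batch_id`, `condition`, `strep_raw`,
#'   `expression_corrected` (NA unless requested), `strep_normalized`,
#'   `excluded`.
#' @examples
#' df <- tibble::tibble(strep = c(2, 2, 3), condition = c("ctrl", "ctrl", "kd"),
#'                      batch_id = "A")
#' normalize_apex(df, "ctrl")
#' @export
normalize_apex <- function(measurements, control_condition,
                           correct_expression = FALSE) {
  need <- c("strep", "condition", "batch_id")
  if (correct_expression) need <- c(need, "v5", "ha")
  if (!all(need %in% names(measurements))) {
    abort(sprintf("`measurements` needs columns %s.",
                  paste(need, collapse = ", ")),
          class = "axc_error_parameter")
  }
  m <- as_tibble(measurements)
  m$strep_raw <- m$strep
  if (correct_expression) {
    m$excluded <- m$v5 <= 0 | m$ha <= 0
    m$expression_corrected <- ifelse(m$excluded, NA_real_,
                                     m$strep / (m$v5 * m$ha))
    m$.base <- m$expression_corrected
  } else {
    m$excluded <- FALSE
    m$expression_corrected <- NA_real_
    m$.base <- m$strep
  }
  out <- m |>
    dplyr::group_by(.data$batch_id) |>
    dplyr::group_modify(function(d, key) {
      ctrl <- d$.base[d$condition == control_condition & !d$excluded]
      if (length(ctrl) == 0) {
        abort(sprintf("Batch \"%s\" has no usable control measurements.",
                      key$batch_id[[1]]),
              class = "axc_error_normalization")
      }
      d$strep_normalized <- ifelse(d$excluded, NA_real_,
                                   d$.base / mean(ctrl))
      d
    }) |>
    dplyr::ungroup()
  out[, c("batch_id", "condition", "strep_raw", "expression_corrected",
          "strep_normalized", "excluded")]
}

#' Fold enrichment of branch-point signal over the axon shaft
#'
#' `mean(branch_values) / mean(shaft_values)`.
#'
#' @param branch_values,shaft_values Non-empty numeric vectors of
#'   background-corrected means.
#' @return Fold change (single number).
#' @examples
#' branch_enrichment(c(3.5), c(2))   # 1.75
#' @export
branch_enrichment <- function(branch_values, shaft_values) {
  if (length(branch_values) == 0 || length(shaft_values) == 0) {
    abort("Both value sets must be non-empty.", class = "axc_error_parameter")
  }
  ms <- mean(shaft_values)
  if (ms <= 0) {
    abort("Non-positive shaft mean: fold change undefined.",
          class = "axc_error_degenerate")
  }
  mean(branch_values) / ms
}

#' Branch-window versus shaft intensity for one rendered segment
#'
#' Measures [profile_mean()] over windows centered on the trace's branch
#' points and over the remaining shaft (with a guard gap so PSF-blurred
#' window signal does not leak into the shaft measure), both background
#' corrected with the same ROI.
#'
#' @param image Rendered segment ([pixel_image()]).
#' @param trace The segment's [make_axon_trace()]; must have branch points.
#' @param width_px,background_roi As in [profile_mean()].
#' @param window_um Full width of each branch window (um).
#' @param guard_um Guard gap between windows and shaft measures (um).
#' @return One-row tibble: `branch_mean`, `shaft_mean` (corrected means).
#' @export
measure_branch_shaft <- function(image, trace, width_px, background_roi,
                                 window_um = 2, guard_um = 1) {
  if (!inherits(trace, "axon_trace") || length(trace$branch_points_nm) == 0) {
    abort("`trace` must be an axon_trace with branch points.",
          class = "axc_error_parameter")
  }
  L <- trace$length_nm
  half <- window_um * 1000 / 2
  guard <- guard_um * 1000
  win <- tibble(lo = pmax(trace$branch_points_nm - half, 0),
                hi = pmin(trace$branch_points_nm + half, L))
  win <- merge_intervals(win)
  shaft <- complement_intervals(
    tibble(lo = pmax(win$lo - guard, 0), hi = pmin(win$hi + guard, L)), L)

  mean_over <- function(iv) {
    if (nrow(iv) == 0) return(NA_real_)
    res <- purrr::pmap(iv, function(lo, hi) {
      sub <- tibble(x_nm = c(lo, hi), y_nm = c(0, 0))
      pm <- profile_mean(image, sub, width_px = width_px,
                        background_roi = background_roi)
      c(pm$corrected_mean, hi - lo)
    })
    v <- vapply(res, `[`, numeric(1), 1)
    w <- vapply(res, `[`, numeric(1), 2)
    sum(v * w) / sum(w)
  }
  tibble(branch_mean = mean_over(win), shaft_mean = mean_over(shaft))
}

merge_intervals <- function(iv) {
  iv <- iv[order(iv$lo), , drop = FALSE]
  if (nrow(iv) <= 1) return(iv)
  lo <- iv$lo[1]; hi <- iv$hi[1]
  out_lo <- c(); out_hi <- c()
  for (i in 2:nrow(iv)) {
    if (iv$lo[i] <= hi) {
      hi <- max(hi, iv$hi[i])
    } else {
      out_lo <- c(out_lo, lo); out_hi <- c(out_hi, hi)
      lo <- iv$lo[i]; hi <- iv$hi[i]
    }
  }
  tibble(lo = c(out_lo, lo), hi = c(out_hi, hi))
}

complement_intervals <- function(iv, L) {
  iv <- merge_intervals(iv)
  edges <- c(0, as.vector(rbind(iv$lo, iv$hi)), L)
  lo <- edges[seq(1, length(edges), by = 2)]
  hi <- edges[seq(2, length(edges), by = 2)]
  keep <- hi - lo > 1e-9
  tibble(lo = lo[keep], hi = hi[keep])
}
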