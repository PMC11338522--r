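#' Normalize a photobleaching-recovery trace
#'
#' Three stages, mirroring standard FRAP practice:
#' 1. subtract the per-frame background;
#' 2. correct for bleaching caused by the acquisition itself by dividing by
#'    the unbleached reference trace rescaled to its own pre-bleach mean
#'    (ratio method; disable with `correct_acquisition = FALSE` when no
#'    reference exists);
#' 3. affine-map so that the mean of the three frames preceding the bleach
#'    is exactly 100% and the first post-bleach frame is exactly 0%.
#'
#' The anchors hold exactly for every normalized curve, and the result is
#' invariant under affine rescaling of the raw data (`a * raw + b` with
#' matching background shift).
#'
#' @param series A [frap_series()] (or tibble with `time_s`, `raw`,
#'   `background`, optionally `reference`).
#' @param bleach_index 1-based index of the first post-bleach frame;
#'   defaults to the attribute carried by the series.
#' @param correct_acquisition Apply the reference-ratio correction?
#' @return A `normalized_frap_curve`: tibble (`time_s`, `percent`) with
#'   attribute `bleach_index`.
#' @examples
#' fs <- simulate_frap(100, 0.9, 0.4, 120, noise_sd = 1, seed = 1)
#' nc <- normalize_frap(fs)
#' mean(nc$percent[1:3])   # exactly 100
#' @export
normalize_frap <- function(series, bleach_index = NULL,
                           correct_acquisition = TRUE) {
  bi <- bleach_index %||% attr(series, "bleach_index")
  if (is.null(bi)) {
    abort("Supply `bleach_index` (first post-bleach frame).",
          class = "axc_error_parameter")
  }
  bi <- as.integer(bi)
  if (bi < 4L) {
    abort("At least three pre-bleach frames are required.",
          class = "axc_error_parameter")
  }
  if (bi > nrow(series)) {
    abort("`bleach_index` beyond the end of the series.",
          class = "axc_error_parameter")
  }
  pre_idx <- (bi - 3L):(bi - 1L)

  s <- series$raw - series$background
  if (correct_acquisition) {
    if (!"reference" %in% names(series)) {
      abort(paste0("No reference trace: supply one or set ",
                   "`correct_acquisition = FALSE`."),
            class = "axc_error_parameter")
    }
    ref <- series$reference - series$background
    s <- s / (ref / mean(ref[pre_idx]))
  }
  pre <- mean(s[pre_idx])
  b0 <- s[bi]
  if (isTRUE(all.equal(pre, b0))) {
    abort("Degenerate trace: pre-bleach mean equals the bleach-point value.",
          class = "axc_error_degenerate")
  }
  percent <- 100 * (s - b0) / (pre - b0)
  structure(
    tibble(time_s = series$time_s, percent = percent),
    bleach_index = bi,
    class = c("normalized_frap_curve", class(tibble()))
  )
}

#' Average normalized recovery curves across cells
#'
#' Per-timepoint mean, standard deviation and standard error across curves
#' sharing a common time grid. Grids must match exactly — no resampling is
#' performed, so acquisition mismatches surface as errors rather than being
#' silently interpolated away.
#'
#' @param curves List of [normalize_frap()] outputs.
#' @return A `frap_mean_curve` tibble: `time_s`, `mean_percent`,
#'   `sd_percent`, `sem_percent`, `n`.
#' @export
average_recovery <- function(curves) {
  if (length(curves) == 0) {
    abort("`curves` is empty.", class = "axc_error_parameter")
  }
  grid <- curves[[1]]$time_s
  for (cv in curves) {
    if (length(cv$time_s) != length(grid) ||
        max(abs(cv$time_s - grid)) > 1e-9) {
      abort("Curves do not share a common time grid (no resampling is done).",
            class = "axc_error_alignment")
    }
  }
  mat <- vapply(curves, function(cv) cv$percent,
                numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  n <- length(curves)
  sds <- apply(mat, 1, sd)
  structure(
    tibble(time_s = grid,
           mean_percent = rowMeans(mat),
           sd_percent = sds,
           sem_percent = sds / sqrt(n),
           n = n),
    bleach_index = attr(curves[[1]], "bleach_index"),
    class = c("frap_mean_curve", class(tibble()))
  )
}

#' Recovery level at a stated time
#'
#' Scalar summary for comparisons between conditions: the normalized value
#' at the sampled timepoint nearest to `t_s` (no interpolation; the
#' timepoint actually used is reported).
#'
#' @param curve A [normalize_frap()] or [average_recovery()] result.
#' @param t_s Query time (s), within the curve's span.
#' @return One-row tibble: `t_requested_s`, `time_s`, `percent`.
#' @examples
#' fs <- simulate_frap(100, 1, 0.4, 120, n_frames = 33, seed = 1)
#' recovery_at(normalize_frap(fs), 900)
#' @export
recovery_at <- function(curve, t_s) {
  tv <- curve$time_s
  if (t_s < min(tv) - 1e-9 || t_s > max(tv) + 1e-9) {
    abort("`t_s` lies outside the curve's time span.",
          class = "axc_error_range")
  }
  i <- which.min(abs(tv - t_s))
  val <- if ("percent" %in% names(curve)) curve$percent[i] else
    curve$mean_percent[i]
  tibble(t_requested_s = t_s, time_s = tv[i], percent = val)
}
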