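#' Read and write pixel images as TIFF with a YAML sidecar
#'
#' Images are written as 32-bit float TIFF scaled to `[0, 1]`; the physical
#' pixel size, channel label, origin and intensity scale travel in a YAML
#' sidecar (`<path>.yaml`, key `pixel_size_nm`), since baseline TIFF has no
#' reliable slot for physical calibration.
#'
#' @param image A [pixel_image()].
#' @param path Output TIFF path.
#' @return `write_image_tiff()` returns `path` invisibly;
#'   `read_image_tiff()` returns a [pixel_image()].
#' @export
write_image_tiff <- function(image, path) {
  scale <- max(image, 1e-12)
  tiff::writeTIFF(unclass(image) / scale, path, bits.per.sample = 32L)
  meta <- list(pixel_size_nm = pixel_size_nm(image),
               channel = attr(image, "channel"),
               origin_nm = as.numeric(attr(image, "origin_nm") %||% c(0, 0)),
               intensity_scale = scale)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_image_tiff
#' @param pixel_size_nm Override/supply the pixel size when no sidecar
#'   exists.
#' @export
read_image_tiff <- function(path, pixel_size_nm = NULL) {
  mat <- tiff::readTIFF(path)
  if (length(dim(mat)) == 3L) mat <- mat[, , 1]
  sidecar <- paste0(path, ".yaml")
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()
  ps <- pixel_size_nm %||% meta$pixel_size_nm
  if (is.null(ps)) {
    abort("No pixel size: supply `pixel_size_nm` or a YAML sidecar.",
          class = "axc_error_io")
  }
  pixel_image(mat * (meta$intensity_scale %||% 1), ps,
              channel = meta$channel %||% "",
              origin_nm = unlist(meta$origin_nm %||% c(0, 0)))
}

#' Read and write localization tables
#'
#' CSV with the conventional header `x_nm,y_nm,precision_nm,frame,channel`.
#'
#' @param table Localization tibble.
#' @param path CSV path.
#' @export
write_localizations <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("x_nm", "y_nm", "precision_nm", "frame", "channel")
  if (!all(need %in% names(tb))) {
    abort(sprintf("Localization CSV needs columns %s.",
                  paste(need, collapse = ",")),
          class = "axc_error_io")
  }
  if (any(tb$precision_nm <= 0) || any(tb$frame < 0)) {
    abort("Invalid localization table: precision_nm must be > 0, frame >= 0.",
          class = "axc_error_io")
  }
  tb
}

#' Read a FRAP trace CSV
#'
#' Expected columns: `time_s`, `raw`, `background`, optionally `reference`
#' and `is_prebleach` (logical flag marking pre-bleach frames; the bleach
#' index is inferred as the first frame after the flagged block unless
#' given explicitly).
#'
#' @param path CSV path.
#' @param bleach_index Optional explicit 1-based first post-bleach frame.
#' @return A [frap_series()].
#' @export
read_frap_csv <- function(path, bleach_index = NULL) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  if (is.null(bleach_index)) {
    if (!"is_prebleach" %in% names(tb)) {
      abort("Supply `bleach_index` or an is_prebleach column.",
            class = "axc_error_io")
    }
    bleach_index <- sum(tb$is_prebleach) + 1L
  }
  frap_series(tb[, setdiff(names(tb), "is_prebleach")], bleach_index)
}

#' Write a scene to JSON
#'
#' Serializes the ground truth (trace, tubule intervals, puncta) so a
#' simulated dataset can be archived next to its rendered images.
#'
#' @param scene A [make_scene()] result.
#' @param path Output JSON path.
#' @export
write_scene_json <- function(scene, path) {
  jsonlite::write_json(
    list(trace = list(vertices = scene$trace$vertices,
                      width_nm = scene$trace$width_nm,
                      branch_points_nm = scene$trace$branch_points_nm),
         er_tubule_radius_nm = scene$er_tubule_radius_nm,
         er_intervals = scene$er_intervals,
         bind_distance_nm = scene$bind_distance_nm,
         bound_fraction = scene$bound_fraction,
         puncta = scene$puncta,
         seed = scene$seed),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
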