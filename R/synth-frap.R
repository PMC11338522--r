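#' Raw photobleaching-recovery series
#'
#' Container for one FRAP acquisition: per-frame times, the measured
#' intensity of the bleached region, a background value and (optionally) an
#' unbleached same-cell reference region used for acquisition-bleaching
#' correction. `bleach_index` is the 1-based index of the first post-bleach
#' frame.
#'
#' @param data Data frame with columns `time_s`, `raw`, `background` and
#'   optionally `reference`.
#' @param bleach_index 1-based index of the first post-bleach frame; at
#'   least three pre-bleach frames must precede it.
#' @return A `frap_series` tibble (attribute `bleach_index`).
#' @export
frap_series <- function(data, bleach_index) {
  data <- as_tibble(data)
  need <- c("time_s", "raw", "background")
  if (!all(need %in% names(data))) {
    abort(sprintf("FRAP data needs columns %s.", paste(need, collapse = ", ")),
          class = "axc_error_parameter")
  }
  if (any(diff(data$time_s) <= 0)) {
    abort("`time_s` must be strictly increasing.", class = "axc_error_parameter")
  }
  bi <- as.integer(bleach_index)
  if (bi <= 1L || bi > nrow(data)) {
    abort("`bleach_index` must lie strictly inside the series.",
          class = "axc_error_parameter")
  }
  structure(data, bleach_index = bi,
            class = c("frap_series", class(data)))
}

bleach_index <- function(series) {
  bi <- attr(series, "bleach_index")
  if (is.null(bi)) abort("Series carries no `bleach_index`.",
                         class = "axc_error_parameter")
  bi
}

#' Simulate a FRAP acquisition with acquisition bleaching
#'
#' Generates a bleached-region trace plus a co-emitted unbleached reference
#' trace. The noiseless signal is:
#' * `prebleach_level` for the pre-bleach frames;
#' * a drop to `prebleach_level * (1 - bleach_depth)` at the bleach frame;
#' * mono-exponential recovery towards
#'   `prebleach_level * (1 - bleach_depth + bleach_depth * recovery_fraction)`
#'   with time constant `recovery_tau_s`.
#'
#' Both traces decay by `exp(-acq_bleach_rate * frame)` (frame 0-based) to
#' emulate bleaching by the acquisition itself, a constant background is
#' added, and Gaussian noise is applied last.
#'
#' @param prebleach_level Pre-bleach fluorescence level (> 0).
#' @param bleach_depth Fraction of signal removed by the bleach, `[0, 1]`.
#' @param recovery_fraction Mobile/recovering fraction of the bleached
#'   signal, `[0, 1]`.
#' @param recovery_tau_s Recovery time constant (s, > 0).
#' @param acq_bleach_rate Per-frame acquisition bleaching rate (>= 0).
#' @param n_prebleach Pre-bleach frames (>= 3, as three frames anchor the
#'   normalization).
#' @param n_frames Total frames (> `n_prebleach`).
#' @param frame_interval_s Frame interval (s, > 0).
#' @param noise_sd Gaussian noise sd added to both traces.
#' @param background_level Constant background added to both traces.
#' @param seed Integer seed.
#' @return A [frap_series()] with `bleach_index = n_prebleach + 1`.
#' @examples
#' fs <- simulate_frap(100, 0.9, 0.4, 120, n_prebleach = 3, n_frames = 33,
#'                     frame_interval_s = 30, seed = 1)
#' attr(fs, "bleach_index")
#' @export
simulate_frap <- function(prebleach_level, bleach_depth, recovery_fraction,
                          recovery_tau_s, acq_bleach_rate = 0,
                          n_prebleach = 3L, n_frames = 33L,
                          frame_interval_s = 30, noise_sd = 0,
                          background_level = 0, seed = 1L) {
  if (prebleach_level <= 0) abort("`prebleach_level` must be > 0.",
                                  class = "axc_error_parameter")
  if (bleach_depth < 0 || bleach_depth > 1) {
    abort("`bleach_depth` must lie in [0, 1].", class = "axc_error_parameter")
  }
  if (recovery_fraction < 0 || recovery_fraction > 1) {
    abort("`recovery_fraction` must lie in [0, 1].", class = "axc_error_parameter")
  }
  if (recovery_tau_s <= 0) abort("`recovery_tau_s` must be > 0.",
                                 class = "axc_error_parameter")
  if (acq_bleach_rate < 0) abort("`acq_bleach_rate` must be >= 0.",
                                 class = "axc_error_parameter")
  if (n_prebleach < 3L) {
    abort("Need at least 3 pre-bleach frames to anchor normalization.",
          class = "axc_error_parameter")
  }
  if (n_frames <= n_prebleach) {
    abort("`n_frames` must exceed `n_prebleach`.", class = "axc_error_parameter")
  }
  if (frame_interval_s <= 0) abort("`frame_interval_s` must be > 0.",
                                   class = "axc_error_parameter")

  frames0 <- seq_len(n_frames) - 1L                 # 0-based frame index
  time_s <- frames0 * frame_interval_s
  bi <- n_prebleach + 1L
  t_rec <- pmax(time_s - time_s[bi], 0)

  signal <- ifelse(
    frames0 < n_prebleach,
    prebleach_level,
    prebleach_level * (1 - bleach_depth +
                         bleach_depth * recovery_fraction *
                           (1 - exp(-t_rec / recovery_tau_s)))
  )
  decay <- exp(-acq_bleach_rate * frames0)
  raw <- signal * decay + background_level
  reference <- prebleach_level * decay + background_level

  if (noise_sd > 0) {
    noise <- with_seed(seed_stream(seed, "frap"),
                       matrix(rnorm(2L * n_frames, 0, noise_sd), ncol = 2L))
    raw <- raw + noise[, 1L]
    reference <- reference + noise[, 2L]
  }

  frap_series(
    tibble(frame = frames0, time_s = time_s, raw = raw,
           background = rep(background_level, n_frames),
           reference = reference),
    bleach_index = bi
  )
}
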