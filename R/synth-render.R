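#' Render one channel of a scene through the imaging forward model
#'
#' Projects the ground-truth scene onto a pixel grid, convolves with an
#' isotropic Gaussian PSF (truncated at 4 sigma), scales to photons, and
#' corrupts with Poisson shot noise followed by additive Gaussian read
#' noise, clipping at zero. Only the 2D projection is modeled (experimental
#' stacks are maximum/average projected before quantification).
#'
#' The emitter map per source:
#' * `"puncta"`: each punctum deposits its amplitude into the pixel
#'   containing it (half-open binning).
#' * `"er"`: each tubule stretch deposits, per column, a mass of
#'   `2 * r / pixel_size` (so total mass is proportional to tubule area),
#'   distributed across rows either as the 2D projection of a uniformly
#'   labeled cylinder surface (`er_profile = "surface"`, edge-bright arcsine
#'   profile — the appropriate forward model for a membrane marker) or as a
#'   flat ridge over `|y| <= r` (`er_profile = "solid"`, a volume marker).
#'
#' In a noiseless render total image intensity equals
#' `photon_scale * (total emitter mass)` up to kernel truncation (< 1%).
#'
#' @param scene A [make_scene()] result.
#' @param source `"er"` or `"puncta"`.
#' @param pixel_size_nm Pixel size (nm); must not exceed `psf_fwhm_nm`.
#' @param psf_fwhm_nm Full width at half maximum of the Gaussian PSF (nm).
#' @param photon_scale Photons per unit emitter mass (>= 0).
#' @param read_noise_sd Read noise standard deviation (photons, >= 0).
#' @param seed Integer seed (noise realization).
#' @param background_level Uniform background level (photons/pixel) added
#'   before the noise stages.
#' @param poisson_noise Apply Poisson shot noise? Set `FALSE` (with
#'   `read_noise_sd = 0`) for a noiseless render.
#' @param margin_nm Background margin added on every side of the axon strip;
#'   keeps blurred mass on the canvas and provides background-ROI pixels.
#' @param er_profile Transverse tubule profile, `"surface"` or `"solid"`.
#' @return A [pixel_image()] whose origin is `(-margin_nm,
#'   -width/2 - margin_nm)`.
#' @examples
#' tr <- make_axon_trace(5, width_nm = 400)
#' sc <- make_scene(tr, 50, 0.5, 30, 80, seed = 1)
#' img <- render_channel(sc, "puncta", pixel_size_nm = 20, psf_fwhm_nm = 60,
#'                       photon_scale = 100, seed = 2)
#' @export
render_channel <- function(scene, source = c("er", "puncta"),
                           pixel_size_nm, psf_fwhm_nm,
                           photon_scale, read_noise_sd = 0, seed = 1L,
                           background_level = 0, poisson_noise = TRUE,
                           margin_nm = 0,
                           er_profile = c("surface", "solid")) {
  source <- match.arg(source)
  er_profile <- match.arg(er_profile)
  if (!inherits(scene, "gt_scene")) {
    abort("`scene` must be a gt_scene.", class = "axc_error_parameter")
  }
  if (pixel_size_nm <= 0 || psf_fwhm_nm <= 0) {
    abort("Pixel size and PSF FWHM must be positive.",
          class = "axc_error_parameter")
  }
  if (pixel_size_nm > psf_fwhm_nm) {
    abort("Undersampled render: `pixel_size_nm` must not exceed `psf_fwhm_nm`.",
          class = "axc_error_parameter")
  }
  if (photon_scale < 0 || read_noise_sd < 0 || background_level < 0) {
    abort("`photon_scale`, `read_noise_sd` and `background_level` must be >= 0.",
          class = "axc_error_parameter")
  }
  px <- pixel_size_nm
  half_w <- scene$trace$width_nm / 2
  L <- scene$trace$length_nm
  x0 <- -margin_nm
  y0 <- -half_w - margin_nm
  nx <- max(1L, ceiling((L + 2 * margin_nm) / px))
  ny <- max(1L, ceiling((scene$trace$width_nm + 2 * margin_nm) / px))

  emitter <- matrix(0, ny, nx)
  if (source == "puncta") {
    p <- scene$puncta
    if (nrow(p) > 0) {
      col <- pmin(pmax(floor((p$x_nm - x0) / px) + 1L, 1L), nx)
      row <- pmin(pmax(floor((p$y_nm - y0) / px) + 1L, 1L), ny)
      for (i in seq_len(nrow(p))) {
        emitter[row[i], col[i]] <- emitter[row[i], col[i]] + p$amplitude[i]
      }
    }
  } else {
    emitter <- er_emitter(scene, ny, nx, px, x0, y0, er_profile)
  }

  blurred <- blur_gaussian(emitter, (psf_fwhm_nm / 2.354820045) / px)
  lambda <- blurred * photon_scale + background_level

  img <- with_seed(seed_stream(seed, "render", source), {
    out <- if (poisson_noise) {
      matrix(rpois(length(lambda), pmax(lambda, 0)), ny, nx)
    } else {
      lambda
    }
    if (read_noise_sd > 0) {
      out <- out + matrix(rnorm(length(out), 0, read_noise_sd), ny, nx)
    }
    out
  })
  img <- pmax(img, 0)
  pixel_image(img, px, channel = source, origin_nm = c(x0, y0))
}

# ER emitter map: per-column mass 2r/px over covered columns, distributed
# transversally by the chosen profile. Partial column coverage at stretch
# ends is handled by the covered-length fraction.
er_emitter <- function(scene, ny, nx, px, x0, y0, er_profile) {
  r <- scene$er_tubule_radius_nm
  iv <- scene$er_intervals
  emitter <- matrix(0, ny, nx)
  if (nrow(iv) == 0) return(emitter)

  # fraction of each column's x-range covered by tubule stretches
  col_lo <- x0 + (seq_len(nx) - 1) * px
  col_hi <- col_lo + px
  cover <- rep(0, nx)
  for (i in seq_len(nrow(iv))) {
    ov <- pmin(col_hi, iv$end_nm[i]) - pmax(col_lo, iv$start_nm[i])
    cover <- cover + pmax(ov, 0)
  }
  cover <- pmin(cover / px, 1)

  # transverse row weights, summing to 1 across the tubule
  row_lo <- y0 + (seq_len(ny) - 1) * px
  row_hi <- row_lo + px
  wrow <- if (er_profile == "solid") {
    pmax(pmin(row_hi, r) - pmax(row_lo, -r), 0) / (2 * r)
  } else {
    # projected cylinder-surface density 1/(pi sqrt(r^2 - y^2)) integrated
    # over each pixel row: (asin(hi/r) - asin(lo/r)) / pi
    cl <- function(v) pmin(pmax(v / r, -1), 1)
    (asin(cl(row_hi)) - asin(cl(row_lo))) / pi
  }
  outer(wrow, cover) * (2 * r / px)
}

#' Emit a single-molecule localization table for a scene
#'
#' Forward model for dual-color SMLM after localization fitting: each
#' punctum blinks a Poisson number of times, each blink yielding one
#' localization jittered by the stated precision; the ER channel is sampled
#' along the tubule surface at a fixed linear density. Fitting raw frames is
#' out of scope — this emits the *result* of such fitting.
#'
#' @param scene A [make_scene()] result.
#' @param precision_nm Localization precision (Gaussian sd, nm, > 0).
#' @param mean_blinks Mean localizations per punctum (>= 0).
#' @param seed Integer seed.
#' @param er_density_per_um Expected ER localizations per micrometre of
#'   tubule.
#' @param n_frames Number of acquisition frames localizations are spread
#'   over (frame indices are 0-based).
#' @return Tibble with `x_nm`, `y_nm`, `precision_nm`, `frame`, `channel`
#'   (`"ribo"` for puncta, `"er"` for tubule).
#' @examples
#' tr <- make_axon_trace(5, width_nm = 400)
#' sc <- make_scene(tr, 20, 0.5, 30, 80, seed = 1)
#' locs <- emit_localizations(sc, precision_nm = 10, mean_blinks = 5, seed = 2)
#' table(locs$channel)
#' @export
emit_localizations <- function(scene, precision_nm, mean_blinks, seed = 1L,
                               er_density_per_um = 100, n_frames = 10000L) {
  if (!inherits(scene, "gt_scene")) {
    abort("`scene` must be a gt_scene.", class = "axc_error_parameter")
  }
  if (precision_nm <= 0) {
    abort("`precision_nm` must be > 0.", class = "axc_error_parameter")
  }
  if (mean_blinks < 0) {
    abort("`mean_blinks` must be >= 0.", class = "axc_error_parameter")
  }
  p <- scene$puncta
  ribo <- with_seed(seed_stream(seed, "locs", "ribo"), {
    nb <- if (nrow(p) > 0) rpois(nrow(p), mean_blinks) else integer(0)
    n <- sum(nb)
    tibble(
      x_nm = rep(p$x_nm, nb) + rnorm(n, 0, precision_nm),
      y_nm = rep(p$y_nm, nb) + rnorm(n, 0, precision_nm),
      precision_nm = rep(precision_nm, n),
      frame = sample.int(n_frames, n, replace = TRUE) - 1L,
      channel = rep("ribo", n)
    )
  })
  iv <- scene$er_intervals
  er <- with_seed(seed_stream(seed, "locs", "er"), {
    tot_um <- sum(iv$end_nm - iv$start_nm) / 1000
    n <- rpois(1, er_density_per_um * tot_um)
    x <- sample_x_in_intervals(n, iv, list(breaks = c(0, scene$trace$length_nm),
                                           weights = 1))
    tibble(
      x_nm = x + rnorm(n, 0, precision_nm),
      y_nm = sample(c(-1, 1), n, replace = TRUE) * scene$er_tubule_radius_nm +
        rnorm(n, 0, precision_nm),
      precision_nm = rep(precision_nm, n),
      frame = sample.int(n_frames, n, replace = TRUE) - 1L,
      channel = rep("er", n)
    )
  })
  dplyr::bind_rows(ribo, er)
}
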