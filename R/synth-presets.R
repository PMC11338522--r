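#' Named simulation presets
#'
#' Presets bundle a complete, versioned parameter set for scene generation,
#' rendering and quantification. The shipped presets encode the programmed
#' effect sizes that the recovery suite re-estimates: intensity-pair
#' reductions of 29%, 30% and 37%, a contact geometry with a 45% bound
#' fraction and 30 nm binding shell, and a 1.75-fold branch-point density
#' enrichment.
#'
#' @param file Optional path to a presets YAML; defaults to the file shipped
#'   with the package.
#' @return `simulation_presets()`: a named list of presets.
#' @examples
#' names(simulation_presets())
#' simulation_preset("fig1-kd-puro")$scale_factor
#' @export
simulation_presets <- function(file = NULL) {
  file <- file %||% system.file("extdata", "presets.yaml",
                                package = "axoncontact", mustWork = TRUE)
  cfg <- yaml::read_yaml(file)
  if (is.null(cfg$presets)) {
    abort("Preset file has no `presets` section.", class = "axc_error_config")
  }
  lapply(cfg$presets, function(p) {
    p$version <- cfg$version
    p
  })
}

#' @describeIn simulation_presets Resolve one preset by name (or pass a
#'   preset list through unchanged).
#' @param preset Preset name or an already-resolved preset list.
#' @export
simulation_preset <- function(preset, file = NULL) {
  if (is.list(preset)) return(preset)
  all <- simulation_presets(file)
  if (!preset %in% names(all)) {
    abort(sprintf("Unknown preset \"%s\". Available: %s.", preset,
                  paste(names(all), collapse = ", ")),
          class = "axc_error_config")
  }
  out <- all[[preset]]
  out$name <- preset
  out
}

# Build trace + scene + render arguments from a preset, with an optional
# multiplicative adjustment of one scale target for the test group.
preset_args <- function(preset, scale = 1) {
  g <- preset$geometry
  s <- preset$scene
  r <- preset$render
  if (identical(preset$scale_target, "n_puncta")) {
    s$n_puncta <- as.integer(round_half_up(s$n_puncta * scale))
  } else if (identical(preset$scale_target, "photon_scale") || is.null(preset$scale_target)) {
    r$photon_scale <- r$photon_scale * scale
  } else {
    abort(sprintf("Unsupported scale_target \"%s\".", preset$scale_target),
          class = "axc_error_config")
  }
  list(geometry = g, scene = s, render = r, quantify = preset$quantify)
}

scene_from_args <- function(a, seed) {
  tr <- make_axon_trace(a$geometry$length_um,
                        width_nm = a$geometry$width_nm,
                        n_branches = a$geometry$n_branches %||% 0L,
                        seed = seed)
  sc_args <- a$scene
  do.call(make_scene, c(list(trace = tr, seed = seed), sc_args))
}

render_from_args <- function(a, scene, source, seed, noiseless = FALSE) {
  r <- a$render
  ps <- if (source == "er" && !is.null(r$photon_scale_er)) {
    r$photon_scale_er
  } else {
    r$photon_scale
  }
  render_channel(scene, source,
                 pixel_size_nm = r$pixel_size_nm,
                 psf_fwhm_nm = r$psf_fwhm_nm,
                 photon_scale = ps,
                 read_noise_sd = if (noiseless) 0 else r$read_noise_sd %||% 0,
                 seed = seed,
                 background_level = if (noiseless) 0 else r$background_level %||% 0,
                 poisson_noise = !noiseless,
                 margin_nm = r$margin_nm %||% 0,
                 er_profile = r$er_profile %||% "surface")
}

#' Simulate a control/test condition pair
#'
#' Renders two groups of axon segments whose only systematic difference is
#' the preset's scale factor, applied to the test group's photon budget or
#' punctum density. Per-image seeds are derived deterministically from the
#' master seed via [seed_stream()], so any single image can be regenerated
#' in isolation.
#'
#' @param preset Preset name (see [simulation_presets()]) or preset list;
#'   must define `scale_factor` and `scale_target`.
#' @param n_per_group Segments per group (>= 0).
#' @param seed Master seed.
#' @param noiseless Disable Poisson/read noise and background (used to
#'   verify exact linear scaling of the forward model).
#' @return Tibble with one row per segment: `group` (`"control"`/`"test"`),
#'   `replicate`, `scene` and `image` list-columns. The resolved preset is
#'   attached as attribute `"preset"`.
#' @examples
#' pair <- simulate_condition_pair("fig1-kd-puro", n_per_group = 2, seed = 1)
#' dplyr::count(pair, group)
#' @export
simulate_condition_pair <- function(preset, n_per_group, seed = 1L,
                                    noiseless = FALSE) {
  preset <- simulation_preset(preset)
  if (is.null(preset$scale_factor)) {
    abort("Preset does not define a condition pair (`scale_factor` missing).",
          class = "axc_error_config")
  }
  if (n_per_group < 0) {
    abort("`n_per_group` must be >= 0.", class = "axc_error_parameter")
  }
  if (n_per_group == 0L) {
    out <- tibble(group = factor(character(0),
                                 levels = c("control", "test")),
                  replicate = integer(0),
                  scene = list(), image = list())
    attr(out, "preset") <- preset
    return(out)
  }
  groups <- list(control = 1, test = preset$scale_factor)
  rows <- purrr::imap(groups, function(scale, grp) {
    a <- preset_args(preset, scale)
    purrr::map(seq_len(n_per_group), function(i) {
      s_i <- seed_stream(seed, grp, i)
      scene <- scene_from_args(a, s_i)
      img <- render_from_args(a, scene, "puncta", s_i, noiseless = noiseless)
      tibble(group = grp, replicate = i,
             scene = list(scene), image = list(img))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  rows$group <- factor(rows$group, levels = c("control", "test"))
  attr(rows, "preset") <- preset
  rows
}

#' Simulate a set of two-channel contact segments
#'
#' Generates ER + ribosome channel pairs under a contact-geometry preset,
#' ready for [analyze_segment()].
#'
#' @inheritParams simulate_condition_pair
#' @param n_segments Number of segments.
#' @return Tibble with `replicate`, `scene`, `er_image`, `ribo_image`
#'   list-columns; resolved preset attached as attribute `"preset"`.
#' @examples
#' segs <- simulate_contact_segments("fig2-sted-contact", 2, seed = 5)
#' segs$er_image[[1]]
#' @export
simulate_contact_segments <- function(preset, n_segments, seed = 1L,
                                      noiseless = FALSE) {
  preset <- simulation_preset(preset)
  a <- preset_args(preset, 1)
  purrr::map(seq_len(n_segments), function(i) {
    s_i <- seed_stream(seed, "segment", i)
    sc <- scene_from_args(a, s_i)
    er <- render_from_args(a, sc, "er", seed_stream(s_i, "er"),
                           noiseless = noiseless)
    ribo <- render_from_args(a, sc, "puncta", seed_stream(s_i, "ribo"),
                             noiseless = noiseless)
    tibble(replicate = i, scene = list(sc),
           er_image = list(er), ribo_image = list(ribo))
  }) |> purrr::list_rbind() |>
    structure(preset = preset)
}
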