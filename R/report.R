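#' Two-group and multi-group condition comparisons
#'
#' Plumbing around the standard tests used for imaging quantifications:
#' Mann-Whitney (Wilcoxon rank-sum) for two groups, one-way ANOVA followed
#' by Dunnett comparisons to the control for more.
#'
#' @param data Data frame of per-cell/per-segment measurements.
#' @param value,group Column names (strings) of the measurement and the
#'   condition label.
#' @param test `"mann-whitney"` or `"anova-dunnett"`.
#' @param control Control condition label (required for Dunnett).
#' @return Tidy tibble with one row per comparison: `comparison`,
#'   `statistic`, `p_value`, `method`.
#' @examples
#' df <- data.frame(v = c(rnorm(8), rnorm(8, 2)),
#'                  g = rep(c("a", "b"), each = 8))
#' compare_groups(df, "v", "g")
#' @export
compare_groups <- function(data, value, group,
                           test = c("mann-whitney", "anova-dunnett"),
                           control = NULL) {
  test <- match.arg(test)
  v <- data[[value]]
  g <- factor(data[[group]])
  if (is.null(v) || is.null(g)) {
    abort("`value`/`group` columns not found.", class = "axc_error_parameter")
  }
  if (test == "mann-whitney") {
    if (nlevels(g) != 2L) {
      abort("Mann-Whitney requires exactly two groups.",
            class = "axc_error_parameter")
    }
    wt <- wilcox.test(v ~ g, exact = FALSE)
    tibble(comparison = paste(levels(g), collapse = " vs "),
           statistic = unname(wt$statistic),
           p_value = wt$p.value,
           method = "Mann-Whitney U")
  } else {
    if (is.null(control) || !control %in% levels(g)) {
      abort("Dunnett comparisons need a `control` level present in the data.",
            class = "axc_error_parameter")
    }
    g <- stats::relevel(g, ref = control)
    fit <- aov(v ~ g, data = data.frame(v = v, g = g))
    dn <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    sm <- summary(dn)
    tibble(comparison = names(sm$test$coefficients),
           statistic = unname(sm$test$tstat),
           p_value = unname(sm$test$pvalues),
           method = "one-way ANOVA + Dunnett")
  }
}

#' Quantify a simulated condition pair with the segmented-line readout
#'
#' Applies [profile_mean()] along the axon midline of every rendered
#' segment, using the preset's profile width and a background ROI in the
#' image's margin rows.
#'
#' @param pair Output of [simulate_condition_pair()].
#' @param preset Preset list; defaults to the one attached to `pair`.
#' @return Tibble: `group`, `replicate`, `corrected_mean`, `raw_mean`,
#'   `background`.
#' @export
quantify_pair <- function(pair, preset = NULL) {
  preset <- preset %||% attr(pair, "preset")
  if (is.null(preset)) {
    abort("No preset attached: supply `preset`.", class = "axc_error_config")
  }
  q <- preset$quantify
  if (nrow(pair) == 0L) {
    return(tibble(group = pair$group, replicate = integer(0),
                  raw_mean = numeric(0), background = numeric(0),
                  corrected_mean = numeric(0),
                  profile_length_um = numeric(0),
                  line_width_px = integer(0), negative_flag = logical(0)))
  }
  res <- purrr::map2(pair$image, pair$scene, function(img, scene) {
    measure_segment_profile(img, scene$trace,
                            width_px = q$width_px %||% 1L,
                            background_rows = q$background_rows %||% 2L)
  }) |> purrr::list_rbind()
  dplyr::bind_cols(pair[, c("group", "replicate")], res)
}

# Midline profile of a rendered segment; the background ROI is the top
# margin strip (first `background_rows` rows span the full width).
measure_segment_profile <- function(image, trace, width_px, background_rows) {
  profile_mean(image,
               tibble(x_nm = c(0, trace$length_nm), y_nm = c(0, 0)),
               width_px = width_px,
               background_roi = c(0, 0, ncol(image), background_rows))
}

#' Run a simulate-quantify-compare experiment from a config
#'
#' Executes the full chain deterministically: resolve the preset, simulate
#' the stated number of replicates under the master seed, quantify every
#' segment, compute the preset's effect size (percent change for condition
#' pairs, contact fractions for contact geometry, fold enrichment for
#' branch geometry) and the matching group statistic, and return everything
#' as a report carrying the config fingerprint.
#'
#' @param config Named list (or path to a YAML file) with at least
#'   `preset`, `n` and `seed`; optional `test` overrides the default
#'   group-comparison test.
#' @return A `comparison_report`: list with `config`, `config_hash`,
#'   `measurements`, `summary`, `effect` and `test` tibbles.
#' @examples
#' rpt <- run_experiment(list(preset = "fig1-kd-puro", n = 4, seed = 7))
#' rpt$effect
#' @export
run_experiment <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$preset) || is.null(config$n) ||
      is.null(config$seed)) {
    abort("`config` needs fields preset, n and seed.",
          class = "axc_error_config")
  }
  preset <- simulation_preset(config$preset)
  kind <- preset$kind %||% "pair"
  hash <- hash_config(config[order(names(config))])

  if (kind == "pair") {
    pair <- simulate_condition_pair(preset, config$n, config$seed)
    meas <- quantify_pair(pair, preset)
    summ <- meas |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(n = dplyr::n(),
                       mean = mean(.data$corrected_mean),
                       sd = sd(.data$corrected_mean), .groups = "drop")
    eff <- tibble(
      quantity = "percent_change",
      value = percent_change(meas$corrected_mean[meas$group == "control"],
                             meas$corrected_mean[meas$group == "test"])
    )
    tst <- compare_groups(meas, "corrected_mean", "group",
                          test = config$test %||% "mann-whitney")
  } else if (kind == "contact") {
    segs <- simulate_contact_segments(preset, config$n, config$seed)
    meas <- analyze_segments(segs,
                             dilate_nm = preset$quantify$dilate_nm %||% 5)
    summ <- tibble(
      quantity = c("fraction_in_mask", "fraction_in_enlarged",
                   "fraction_flipped", "mask_area_fraction"),
      mean = c(mean(meas$fraction_in_mask), mean(meas$fraction_in_enlarged),
               mean(meas$fraction_flipped), mean(meas$mask_area_fraction)),
      sd = c(sd(meas$fraction_in_mask), sd(meas$fraction_in_enlarged),
             sd(meas$fraction_flipped), sd(meas$mask_area_fraction)),
      n = nrow(meas)
    )
    eff <- tibble(quantity = "mean_fraction_in_mask",
                  value = mean(meas$fraction_in_mask))
    wt <- wilcox.test(meas$fraction_in_mask, meas$fraction_flipped,
                      paired = TRUE, alternative = "greater", exact = FALSE)
    tst <- tibble(comparison = "in-mask vs flipped (paired, one-sided)",
                  statistic = unname(wt$statistic), p_value = wt$p.value,
                  method = "Wilcoxon signed-rank")
  } else if (kind == "branch") {
    meas <- simulate_branch_measurements(preset, config$n, config$seed)
    summ <- meas |>
      tidyr::pivot_longer(c("branch_mean", "shaft_mean"),
                          names_to = "region", values_to = "value") |>
      dplyr::group_by(.data$region) |>
      dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                       sd = sd(.data$value), .groups = "drop")
    eff <- tibble(quantity = "branch_fold_enrichment",
                  value = branch_enrichment(meas$branch_mean,
                                            meas$shaft_mean))
    wt <- wilcox.test(meas$branch_mean, meas$shaft_mean, paired = TRUE,
                      alternative = "greater", exact = FALSE)
    tst <- tibble(comparison = "branch vs shaft (paired, one-sided)",
                  statistic = unname(wt$statistic), p_value = wt$p.value,
                  method = "Wilcoxon signed-rank")
  } else {
    abort(sprintf("Unknown preset kind \"%s\".", kind),
          class = "axc_error_config")
  }

  structure(list(config = config, config_hash = hash, preset = preset,
                 measurements = meas, summary = summ, effect = eff,
                 test = tst, seed = config$seed),
            class = "comparison_report")
}

#' Simulate and measure branch-versus-shaft segments under a preset
#'
#' @param preset Branch-geometry preset (name or list).
#' @param n_segments Number of segments.
#' @param seed Master seed.
#' @return Tibble: `replicate`, `branch_mean`, `shaft_mean`.
#' @export
simulate_branch_measurements <- function(preset, n_segments, seed = 1L) {
  preset <- simulation_preset(preset)
  a <- preset_args(preset, 1)
  q <- preset$quantify
  purrr::map(seq_len(n_segments), function(i) {
    s_i <- seed_stream(seed, "branchseg", i)
    scene <- scene_from_args(a, s_i)
    img <- render_from_args(a, scene, "puncta", s_i)
    ms <- measure_branch_shaft(
      img, scene$trace,
      width_px = q$width_px %||% 1L,
      background_roi = c(0, 0, ncol(img), q$background_rows %||% 2L),
      window_um = q$branch_window_um %||% 2,
      guard_um = q$guard_um %||% 1)
    dplyr::bind_cols(tibble(replicate = i), ms)
  }) |> purrr::list_rbind()
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> preset \"%s\", n = %s, seed = %s\n",
              x$preset$name %||% "?", x$config$n, x$seed))
  cat(sprintf("  config hash %s\n", x$config_hash))
  cat("  effect:\n")
  print(x$effect)
  cat("  test:\n")
  print(x$test)
  invisible(x)
}

#' @rdname run_experiment
#' @param x A `comparison_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.comparison_report <- function(x, ...) {
  x$summary
}

#' @rdname run_experiment
#' @exportS3Method generics::glance
glance.comparison_report <- function(x, ...) {
  tibble(preset = x$preset$name %||% NA_character_,
         n = x$config$n,
         seed = x$seed,
         effect_quantity = x$effect$quantity[1],
         effect_value = x$effect$value[1],
         p_value = x$test$p_value[1],
         method = x$test$method[1],
         config_hash = x$config_hash)
}

#' Validate an analysis manifest
#'
#' Checks the bookkeeping of a manifest (one row per cell/segment): that
#' referenced files exist, that condition labels come from the declared
#' set, and that every batch contains control rows. An empty result means
#' the manifest is valid.
#'
#' @param manifest Data frame, or path to a CSV with columns such as
#'   `path`, `condition`, `batch_id`.
#' @param conditions Optional character vector of allowed condition labels.
#' @param control_condition Optional control label; batches lacking it are
#'   reported.
#' @param base_dir Directory file paths are resolved against.
#' @return Tibble of issues (`row`, `issue`); zero rows when valid.
#' @examples
#' m <- tibble::tibble(condition = c("ctrl", "kd"), batch_id = "A")
#' validate_manifest(m, conditions = c("ctrl", "kd"),
#'                   control_condition = "ctrl")
#' @export
validate_manifest <- function(manifest, conditions = NULL,
                              control_condition = NULL, base_dir = ".") {
  if (is.character(manifest) && length(manifest) == 1L) {
    if (!file.exists(manifest)) {
      abort(sprintf("Cannot read manifest \"%s\".", manifest),
            class = "axc_error_io")
    }
    manifest <- readr::read_csv(manifest, show_col_types = FALSE)
  }
  issues <- tibble(row = integer(0), issue = character(0))
  add <- function(row, msg) {
    issues <<- dplyr::bind_rows(issues, tibble(row = row, issue = msg))
  }
  if ("path" %in% names(manifest)) {
    for (i in seq_len(nrow(manifest))) {
      p <- file.path(base_dir, manifest$path[i])
      if (!file.exists(p)) add(i, sprintf("missing file: %s", manifest$path[i]))
    }
  }
  if (!is.null(conditions) && "condition" %in% names(manifest)) {
    bad <- which(!manifest$condition %in% conditions)
    for (i in bad) {
      add(i, sprintf("unknown condition label: %s", manifest$condition[i]))
    }
  }
  if (!is.null(control_condition) && all(c("condition", "batch_id") %in%
                                         names(manifest))) {
    for (b in unique(manifest$batch_id)) {
      rows <- manifest$condition[manifest$batch_id == b]
      if (!control_condition %in% rows) {
        add(NA_integer_, sprintf("batch without control rows: %s", b))
      }
    }
  }
  issues
}
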