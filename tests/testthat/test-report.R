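test_that("run_experiment recovers the programmed effect and is deterministic", {
  cfg <- list(preset = "fig1-kd-puro", n = 8, seed = 42)
  rpt <- run_experiment(cfg)
  expect_s3_class(rpt, "comparison_report")
  expect_lt(abs(rpt$effect$value - 29), 3)
  expect_equal(rpt$test$method, "Mann-Whitney U")

  rpt2 <- run_experiment(cfg)
  expect_identical(rpt$effect, rpt2$effect)
  expect_identical(rpt$measurements, rpt2$measurements)
  expect_identical(rpt$config_hash, rpt2$config_hash)

  # different seeds produce a different realization but the same hash scheme
  rpt3 <- run_experiment(list(preset = "fig1-kd-puro", n = 8, seed = 43))
  expect_false(identical(rpt$effect$value, rpt3$effect$value))
  expect_false(identical(rpt$config_hash, rpt3$config_hash))
})

test_that("run_experiment handles contact and branch presets", {
  rc <- run_experiment(list(preset = "fig2-sted-contact", n = 6, seed = 5))
  expect_equal(rc$effect$quantity, "mean_fraction_in_mask")
  expect_true(rc$effect$value > 0 && rc$effect$value < 1)

  rb <- run_experiment(list(preset = "fig3-branch", n = 4, seed = 6))
  expect_equal(rb$effect$quantity, "branch_fold_enrichment")
  expect_gt(rb$effect$value, 1)

  expect_error(run_experiment(list(preset = "fig1-kd-puro")),
               class = "axc_error_config")
})

test_that("tidy and glance summarize reports in broom style", {
  rpt <- run_experiment(list(preset = "fig1-kd-puro", n = 4, seed = 2))
  td <- tidy(rpt)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("group", "n", "mean", "sd") %in% names(td)))
  gl <- glance(rpt)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("effect_value", "p_value", "config_hash") %in% names(gl)))
})

test_that("compare_groups runs both supported tests", {
  set.seed(31)
  df <- data.frame(v = c(rnorm(12, 10), rnorm(12, 13), rnorm(12, 10.2)),
                   g = rep(c("ctrl", "high", "null"), each = 12))
  two <- compare_groups(df[df$g != "null", ], "v", "g")
  expect_lt(two$p_value, 0.01)

  dn <- compare_groups(df, "v", "g", test = "anova-dunnett", control = "ctrl")
  expect_equal(nrow(dn), 2)
  expect_true(any(dn$p_value < 0.01))
  expect_error(compare_groups(df, "v", "g", test = "anova-dunnett"),
               class = "axc_error_parameter")
})

test_that("manifests are validated for files, labels and controls", {
  good <- tibble::tibble(condition = c("ctrl", "kd"), batch_id = "A")
  expect_equal(nrow(validate_manifest(good, conditions = c("ctrl", "kd"),
                                      control_condition = "ctrl")), 0)

  noctrl <- tibble::tibble(condition = c("kd", "kd"),
                           batch_id = c("A", "B"))
  iss <- validate_manifest(noctrl, control_condition = "ctrl")
  expect_equal(nrow(iss), 2)
  expect_true(all(grepl("batch without control", iss$issue)))

  dangling <- tibble::tibble(path = "does/not/exist.tif", condition = "ctrl",
                             batch_id = "A")
  iss2 <- validate_manifest(dangling)
  expect_equal(nrow(iss2), 1)
  expect_match(iss2$issue, "missing file")

  bad_label <- tibble::tibble(condition = "typo", batch_id = "A")
  iss3 <- validate_manifest(bad_label, conditions = c("ctrl", "kd"))
  expect_match(iss3$issue, "unknown condition")
})

test_that("pixel images round-trip through TIFF with their calibration", {
  img <- render_channel(tiny_scene(seed = 2), "puncta", 20, 60,
                        photon_scale = 60, seed = 3)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_tiff(img, path)
  back <- read_image_tiff(path)
  expect_equal(pixel_size_nm(back), 20)
  expect_equal(unclass(back), unclass(img), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("scene JSON serialization captures the ground truth", {
  sc <- tiny_scene(n_puncta = 12, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_scene_json(sc, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(back$puncta), 12)
  expect_equal(back$er_tubule_radius_nm, sc$er_tubule_radius_nm)
})
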