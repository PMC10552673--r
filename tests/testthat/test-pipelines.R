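test_that("EBD pipeline recovers dye-positive counts and conserves totals", {
  tr <- quick_scene(101, n_fibers = 100, marker_fraction = 0.07)
  res <- run_ebd(render_fluorescence(tr, "ebd"))
  expect_equal(res$counts$total_cells, 100L)
  expect_equal(res$counts$ebd_pos_cells, 7L)
  expect_equal(res$percent$pct_ebd_pos, 7.0)
  expect_equal(res$counts$not_ebd_cells + res$counts$ebd_pos_cells,
               res$counts$total_cells)
  # dye-free scene mirrors the healthy-muscle observation
  tr0 <- quick_scene(102, marker_fraction = 0)
  res0 <- run_ebd(render_fluorescence(tr0, "ebd"))
  expect_equal(res0$counts$ebd_pos_cells, 0L)
  # blank image: zero cells, warning, no percentage (the degenerate
  # full-frame "object" fails the fiber-scale diameter filter)
  blank <- multichannel_image(array(0, c(400, 400, 3)),
                              c("red", "green", "blue"))
  resb <- run_ebd(blank)
  expect_equal(resb$counts$total_cells, 0L)
  expect_null(resb$percent$pct_ebd_pos)
  expect_true(length(resb$warnings) > 0L)
})

test_that("more rendered dye-positive fibers never yields fewer detections", {
  counts <- vapply(c(0, 0.04, 0.08, 0.15), function(f) {
    tr <- quick_scene(103, n_fibers = 100, marker_fraction = f)
    run_ebd(render_fluorescence(tr, "ebd"))$counts$ebd_pos_cells
  }, integer(1L))
  expect_true(all(diff(counts) >= 0))
})

test_that("regeneration pipeline counts and sizes marker-positive fibers", {
  tr <- quick_scene(104, n_fibers = 50, marker_fraction = 0.14,
                    marker_size_bias = "small")
  res <- run_emyhc(render_fluorescence(tr, "emyhc"))
  expect_equal(res$counts$total_cells, 50L)
  expect_equal(res$counts$emyhc_pos_cells, 7L)
  expect_equal(res$percent$pct_emyhc_pos, 14.0)
  drawn <- sort(tr$fiber_areas[tr$marker_flags])
  expect_equal(sort(res$sizes), drawn)
  expect_lt(median(drawn), median(tr$fiber_areas[!tr$marker_flags]))
  # no marker signal: zero positives and an empty size list
  tr0 <- quick_scene(105, n_fibers = 50, marker_fraction = 0)
  res0 <- run_emyhc(render_fluorescence(tr0, "emyhc"))
  expect_equal(res0$counts$emyhc_pos_cells, 0L)
  expect_length(res0$sizes, 0L)
})

test_that("CD68 pipeline reports percent area of aggregate coverage", {
  tr <- quick_scene(106, aggregate_count = 6, aggregate_radius = 15)
  res <- run_cd68(render_fluorescence(tr, "cd68"))
  expect_lt(abs(res$percent$pct_area - tr$summary$pct_aggregate_area), 0.3)
  # zero-signal and full-signal extremes
  zero <- multichannel_image(array(0, c(64, 64, 3)), c("red", "green", "blue"))
  expect_equal(run_cd68(zero)$percent$pct_area, 0)
  fullpx <- array(0, c(64, 64, 3)); fullpx[, , 2L] <- 1
  full <- multichannel_image(fullpx, c("red", "green", "blue"))
  cfg <- default_pipeline_config("cd68")
  cfg$marker_params <- segmentation_params(
    min_diameter = 1, max_diameter = 1000,
    threshold = cfg$marker_params$threshold, declump = FALSE)
  expect_equal(run_cd68(full, cfg)$percent$pct_area, 100)
})

test_that("collagen pipeline measures interstitial coverage from brightfield", {
  tr <- quick_scene(107, collagen_fraction = 0.10)
  res <- run_collagen(render_brightfield_collagen(tr))
  expect_lt(abs(res$percent$pct_area - 10), 1.0)
  # collagen-free scene stays near zero
  tr0 <- quick_scene(108, collagen_fraction = 0)
  expect_lte(run_collagen(render_brightfield_collagen(tr0))$percent$pct_area,
             0.5)
  # uniform mid-gray frame: nothing survives the diameter filter
  u <- multichannel_image(array(0.5, c(400, 400, 3)),
                          c("red", "green", "blue"))
  expect_equal(run_collagen(u)$percent$pct_area, 0)
})

test_that("missing channel roles raise a config error", {
  gray_only <- multichannel_image(array(0.3, c(16, 16, 1)), "red")
  expect_error(run_ebd(gray_only), "config error")
  cfg <- default_pipeline_config("cd68")
  cfg$channel_roles$marker <- "blue"
  ok <- multichannel_image(array(0.2, c(16, 16, 2)), c("red", "green"))
  expect_error(run_cd68(ok, cfg), "config error")
})

test_that("batch runs export CSV rows and tolerate corrupt files", {
  dir <- withr::local_tempdir()
  paths <- character(0L)
  for (s in 1:2) {
    tr <- quick_scene(110 + s, n_fibers = 50, marker_fraction = 0.1)
    p <- file.path(dir, sprintf("scene%d.tif", s))
    write_image(render_fluorescence(tr, "emyhc"), p)
    paths <- c(paths, p)
  }
  bad <- file.path(dir, "corrupt.tif")
  writeLines("this is not a TIFF", bad)
  out <- file.path(dir, "res.csv")
  res <- run_batch(c(paths, bad), default_pipeline_config("emyhc"), out)
  expect_equal(attr(res, "n_failed"), 1L)
  lines <- readLines(out)
  expect_length(lines, 4L)           # header + 2 data + 1 warning row
  expect_match(lines[4L], "failed")
  # per-object size file accompanies the regeneration assay
  obj <- read.csv(file.path(dir, "res_objects.csv"))
  expect_named(obj, c("image_id", "label", "area_px"))
  expect_gt(nrow(obj), 0L)
  # an all-corrupt batch is an error
  expect_error(run_batch(bad, default_pipeline_config("emyhc"),
                         file.path(dir, "x.csv")), "no valid images")
})

test_that("YAML configuration overrides merge onto assay defaults", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "cfg.yaml")
  writeLines(c("assay: emyhc",
               "cell_params:",
               "  min_diameter: 17",
               "marker_params:",
               "  threshold:",
               "    lower_bound: 0.3"), p)
  cfg <- read_pipeline_config(p)
  expect_equal(cfg$assay, "emyhc")
  expect_equal(cfg$cell_params$min_diameter, 17)
  expect_equal(cfg$cell_params$max_diameter, 150)    # default retained
  expect_equal(cfg$marker_params$threshold$lower_bound, 0.3)
  expect_equal(cfg$marker_params$threshold$method, "min_cross_entropy")
  # the shipped annotated config parses
  shipped <- system.file("extdata", "default_config.yaml",
                         package = "musclehisto")
  expect_equal(read_pipeline_config(shipped)$assay, "ebd")
})
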