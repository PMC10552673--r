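test_that("disjoint bright disks are found with near-circular areas", {
  params <- segmentation_params(min_diameter = 10, max_diameter = 40)
  res <- identify_primary_objects(two_disjoint_disks(), params)
  expect_equal(res$labels$n_objects, 2L)
  expect_true(all(abs(res$table$area - pi * 100) / (pi * 100) < 0.05))
  # blank image: zero objects, not an error
  blank <- identify_primary_objects(matrix(0, 50, 50), params)
  expect_equal(blank$labels$n_objects, 0L)
  expect_equal(nrow(blank$table), 0L)
})

test_that("declumping splits touching disks and never merges", {
  img <- two_overlapping_disks()
  n_de <- identify_primary_objects(
    img, segmentation_params(10, 40, declump = TRUE))$labels$n_objects
  n_plain <- identify_primary_objects(
    img, segmentation_params(10, 40, declump = FALSE))$labels$n_objects
  expect_equal(n_de, 2L)
  expect_equal(n_plain, 1L)
  # property: declump counts >= plain counts on random blob scenes
  set.seed(41)
  for (i in 1:5) {
    m <- disk_image(80, 80, centers = cbind(runif(4, 15, 65), runif(4, 15, 65)),
                    radius = runif(4, 6, 12))
    a <- identify_primary_objects(m, segmentation_params(5, 60))$labels$n_objects
    b <- identify_primary_objects(
      m, segmentation_params(5, 60, declump = FALSE))$labels$n_objects
    expect_gte(a, b)
  }
})

test_that("increasing the declumping smoothing never increases the count", {
  img <- two_overlapping_disks()
  counts <- vapply(c(0.5, 1, 2, 2.5, 4, 8, 12), function(s) {
    identify_primary_objects(
      img, segmentation_params(10, 40, smoothing_sigma = s))$labels$n_objects
  }, integer(1L))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1L], 2L)                 # split at small smoothing
  expect_equal(counts[length(counts)], 1L)     # merged at heavy smoothing
})

test_that("labels are consecutive and object areas conserve foreground", {
  set.seed(42)
  for (i in 1:5) {
    m <- disk_image(60, 60, centers = cbind(runif(3, 10, 50), runif(3, 10, 50)),
                    radius = runif(3, 5, 10))
    res <- identify_primary_objects(m, segmentation_params(3, 100))
    lab <- res$labels$labels
    present <- sort(unique(lab[lab > 0L]))
    expect_identical(present, seq_len(res$labels$n_objects))
    expect_equal(sum(res$table$area), sum(lab > 0L))
    expect_equal(sum(objects_to_binary(res$labels)), sum(res$table$area))
  }
})

test_that("diameter filtering uses the area-equivalent diameter inclusively", {
  lab <- matrix(0L, 20, 20)
  lab[3:12, 3:12] <- 1L              # area 100, eq diameter 11.28
  lm <- label_map(lab)
  kept <- filter_by_diameter(lm, min_d = 5, max_d = 50)
  expect_equal(kept$labels$n_objects, 1L)
  gone <- filter_by_diameter(lm, min_d = 12, max_d = 50)
  expect_equal(gone$labels$n_objects, 0L)
  ident <- filter_by_diameter(lm, min_d = 0, max_d = Inf)
  expect_equal(ident$labels$labels, lab)
  expect_error(filter_by_diameter(lm, min_d = 9, max_d = 3), "<=")
  # survivors are relabeled consecutively preserving order
  lab2 <- matrix(0L, 30, 30)
  lab2[2:3, 2:3] <- 1L               # area 4, eq diam 2.26
  lab2[10:19, 10:19] <- 2L           # area 100
  lab2[25:28, 25:28] <- 3L           # area 16, eq diam 4.51
  out <- filter_by_diameter(label_map(lab2), min_d = 3, max_d = 50)
  expect_equal(out$labels$n_objects, 2L)
  expect_equal(unique(out$labels$labels[lab2 == 2L]), 1L)
  expect_equal(unique(out$labels$labels[lab2 == 3L]), 2L)
})

test_that("objects_to_binary maps any labeled pixel to 1", {
  empty <- label_map(matrix(0L, 4, 4))
  expect_equal(objects_to_binary(empty), matrix(0, 4, 4))
  full <- label_map(matrix(1L, 4, 4))
  expect_equal(objects_to_binary(full), matrix(1, 4, 4))
})

test_that("discard_border removes only edge-touching objects", {
  m <- matrix(0.05, 40, 40)
  m[1:8, 1:8] <- 0.9          # touches two edges
  m[20:28, 20:28] <- 0.9      # interior
  res <- identify_primary_objects(
    m, segmentation_params(3, 30, discard_border = TRUE, declump = FALSE))
  expect_equal(res$labels$n_objects, 1L)
  res2 <- identify_primary_objects(
    m, segmentation_params(3, 30, discard_border = FALSE, declump = FALSE))
  expect_equal(res2$labels$n_objects, 2L)
})

test_that("noiseless synthetic scenes are recovered fiber for fiber", {
  tr <- quick_scene(seed = 5)
  img <- render_fluorescence(tr, "emyhc")
  lam_inv <- invert(split_channels(img)$red)
  res <- identify_primary_objects(lam_inv,
                                  default_pipeline_config("emyhc")$cell_params)
  expect_equal(res$labels$n_objects, tr$summary$n_fibers)
})
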