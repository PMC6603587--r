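test_that("find_lesions measures a single block correctly", {
  m <- matrix(0L, 10, 12)
  m[3:5, 6:8] <- 3L
  rec <- find_lesions(label_map(m), pixel_spacing_mm = 0.5)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$centroid_row, 4)
  expect_equal(rec$centroid_col, 7)
  expect_equal(c(rec$row_min, rec$col_min, rec$row_max, rec$col_max),
               c(3, 6, 5, 8))
  expect_equal(rec$area_px, 9L)
  expect_equal(rec$area_mm2, 2.25)
  expect_equal(rec$max_diameter_mm, 2 * sqrt(2) * 0.5, tolerance = 1e-12)
  expect_true(rec$small_vessel_flag)
  expect_equal(nrow(find_lesions(label_map(matrix(0L, 5, 5)))), 0L)
  expect_error(find_lesions(label_map(m), pixel_spacing_mm = 0),
               class = "csvd_config_error")
})

test_that("lesion records partition class-3 pixels like the flood oracle", {
  set.seed(40)
  for (i in 1:15) {
    cls <- matrix(0L, 15, 15)
    cls[random_mask(15, 15, 0.25) == 1L] <- 3L
    map <- label_map(cls)
    rec <- find_lesions(map)
    ora <- oracle_label_2d((cls == 3L) * 1L, 8L)
    expect_equal(nrow(rec), max(ora))
    # area conservation
    expect_equal(sum(rec$area_px), sum(cls == 3L))
    # per-component areas agree as multisets
    expect_equal(sort(rec$area_px),
                 sort(as.vector(table(ora[ora > 0L]))),
                 ignore_attr = TRUE)
    # ordering: by area descending
    expect_true(all(diff(rec$area_px) <= 0))
  }
})

test_that("stacking merges overlapping lesions across adjacent slices", {
  m <- matrix(0L, 10, 10); m[3:5, 3:5] <- 3L
  blank <- label_map(matrix(0L, 10, 10))
  two <- stack_slices(list(label_map(m), label_map(m)),
                      pixel_spacing_mm = 0.5, inter_slice_spacing_mm = 4.4)
  expect_equal(length(two$lesions_3d), 1L)
  expect_equal(two$lesions_3d[[1]]$volume_mm3, 2 * 2.25 * 4.4)
  expect_equal(two$lesions_3d[[1]]$slices, c(1L, 2L))
  # same lesion in slices 1 and 3 only -> two 3D groups
  gap <- stack_slices(list(label_map(m), blank, label_map(m)))
  expect_equal(length(gap$lesions_3d), 2L)
  expect_error(stack_slices(list(label_map(m), label_map(matrix(0L, 5, 5)))),
               class = "csvd_shape_error")
})

test_that("3D grouping matches a brute-force 3D flood fill", {
  set.seed(41)
  for (i in 1:8) {
    ns <- sample(2:4, 1)
    maps <- lapply(seq_len(ns), function(s) {
      cls <- matrix(0L, 12, 12)
      cls[random_mask(12, 12, 0.12) == 1L] <- 3L
      label_map(cls)
    })
    vr <- stack_slices(maps)
    vox <- array(0L, c(12, 12, ns))
    for (s in seq_len(ns)) vox[, , s] <- (maps[[s]]$classes == 3L) * 1L
    ora <- oracle_label_3d(vox)
    expect_equal(length(vr$lesions_3d), max(ora))
    # every 2D record belongs to exactly one group, and group voxel
    # sets match the oracle partition as multisets of sizes
    sizes_ora <- sort(as.vector(table(ora[ora > 0L])))
    sizes_got <- sort(vapply(vr$lesions_3d, function(g)
      sum(vr$records$area_px[vr$records$group_id == g$group_id]),
      numeric(1)))
    expect_equal(sizes_got, sizes_ora, ignore_attr = TRUE)
    # volume identity
    for (g in vr$lesions_3d) {
      members <- vr$records[vr$records$group_id == g$group_id, ]
      expect_equal(g$volume_mm3,
                   sum(members$area_mm2) * vr$inter_slice_spacing_mm)
    }
  }
})

test_that("reports serialize to JSON and back, with overlays per slice", {
  m <- matrix(0L, 10, 10); m[3:5, 3:5] <- 3L
  maps <- list(label_map(m), label_map(m))
  slices <- list(grayscale_slice(matrix(80, 10, 10)),
                 grayscale_slice(matrix(90, 10, 10)))
  vr <- stack_slices(maps, pixel_spacing_mm = 0.5)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "report.json")
  write_lesion_report(vr, path, slices = slices, maps = maps,
                      overlays_dir = file.path(dir, "ov"))
  back <- read_lesion_report(path)
  expect_equal(back$kind, "volume_report")
  expect_equal(back$records$area_px, vr$records$area_px)
  expect_equal(back$lesions_3d$volume_mm3[1],
               vr$lesions_3d[[1]]$volume_mm3)
  expect_equal(length(list.files(file.path(dir, "ov"))), length(slices))
  # empty record list still yields valid JSON
  p2 <- file.path(dir, "empty.json")
  write_lesion_report(find_lesions(label_map(matrix(0L, 4, 4))), p2)
  expect_equal(length(read_lesion_report(p2)$records), 0L)
  expect_error(read_lesion_report(file.path(dir, "nope.json")),
               class = "csvd_io_error")
})

test_that("diameter is monotone under growing a lesion", {
  base <- matrix(0L, 20, 20); base[8:10, 8:10] <- 3L
  grown <- base; grown[8:14, 8:10] <- 3L
  d1 <- find_lesions(label_map(base))$max_diameter_mm
  d2 <- find_lesions(label_map(grown))$max_diameter_mm
  expect_gt(d2, d1)
})
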