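test_that("binarize honors fixed and Otsu threshold policies", {
  sl <- grayscale_slice(matrix(c(0, 200, 10, 255), 2, 2))
  m <- binarize(sl, threshold = 100)
  expect_identical(m$cells, matrix(c(0L, 1L, 0L, 1L), 2, 2))
  expect_equal(attr(m, "threshold"), 100)
  # bimodal image: Otsu must land between the two modes
  set.seed(4)
  px <- matrix(sample(c(0, 200), 400, TRUE), 20, 20)
  expect_identical(binarize(grayscale_slice(px), "otsu")$cells,
                   binarize(grayscale_slice(px), 100)$cells)
  expect_error(binarize(grayscale_slice(matrix(0, 8, 8)), "otsu"),
               class = "csvd_degenerate_image_error")
  expect_error(binarize(sl, threshold = "bogus"),
               class = "csvd_config_error")
})

test_that("binarize and inverse_binarize partition the grid", {
  sl <- grayscale_slice(matrix(c(0, 255), 1, 2))
  expect_identical(inverse_binarize(sl, 100)$cells, matrix(c(1L, 0L), 1, 2))
  set.seed(5)
  for (i in 1:10) {
    px <- matrix(sample(0:255, 64, TRUE), 8, 8)
    s <- grayscale_slice(px)
    t <- sample(1:254, 1)
    expect_true(all(binarize(s, t)$cells + inverse_binarize(s, t)$cells == 1L))
  }
})

test_that("connected components match the flood-fill oracle", {
  diag2 <- binary_mask(matrix(c(1L, 0L, 0L, 1L), 2, 2))
  expect_equal(label_components(diag2, 4L)$count, 2L)
  expect_equal(label_components(diag2, 8L)$count, 1L)
  set.seed(6)
  for (i in 1:40) {
    m <- random_mask(sample(2:32, 1), sample(2:32, 1))
    for (conn in c(4L, 8L)) {
      cs <- label_components(binary_mask(m), conn)
      ora <- oracle_label_2d(m, conn)
      expect_true(same_partition(cs$labels, ora))
      expect_equal(sum(cs$areas), sum(m))
      if (cs$count > 0)
        expect_equal(as.vector(table(cs$labels[cs$labels > 0])),
                     as.vector(cs$areas))
    }
  }
})

test_that("remove_largest removes exactly the maximum-area component", {
  m <- matrix(0L, 20, 20)
  m[2:11, 2:11] <- 1L      # area 100
  m[15, 14:20] <- 1L       # area 7
  out <- remove_largest(binary_mask(m))
  expect_equal(sum(out$cells), 7L)
  expect_equal(attr(out, "removed_area"), 100L)
  expect_equal(unname(attr(out, "removed_bbox")), c(2, 2, 11, 11))
  # single component -> empty mask
  solo <- binary_mask(matrix(c(0L, 1L, 1L, 0L), 2, 2))
  expect_equal(sum(remove_largest(solo)$cells), 0L)
  expect_error(remove_largest(binary_mask(matrix(0L, 3, 3))),
               class = "csvd_empty_mask_error")
  # tie: the component first encountered in row-major order goes
  tie <- matrix(0L, 5, 5); tie[1, 1:2] <- 1L; tie[5, 4:5] <- 1L
  kept <- remove_largest(binary_mask(tie))
  expect_true(attr(kept, "removed_tie"))
  expect_equal(which(kept$cells == 1L, arr.ind = TRUE)[, "row"], c(5, 5),
               ignore_attr = TRUE)
  # strictly decreasing foreground when >= 2 components exist
  set.seed(61)
  for (i in 1:10) {
    m <- random_mask(12, 12, 0.3)
    if (label_components(binary_mask(m))$count >= 2)
      expect_lt(sum(remove_largest(binary_mask(m))$cells), sum(m))
  }
})

test_that("median filtering equals the per-pixel neighborhood oracle", {
  lone <- matrix(0L, 7, 7); lone[4, 4] <- 1L
  expect_equal(sum(median_filter_mask(binary_mask(lone))$cells), 0L)
  # a solid block keeps its interior and edges; only the four corner
  # pixels (4 of 9 ones) erode under a strict 3x3 median
  solid <- matrix(0L, 12, 12); solid[2:11, 2:11] <- 1L
  filt <- median_filter_mask(binary_mask(solid))$cells
  expect_identical(filt[3:10, 3:10], solid[3:10, 3:10])
  expect_equal(sum(solid) - sum(filt), 4L)
  # a full-frame foreground is unchanged (edge replication)
  full <- matrix(1L, 8, 8)
  expect_identical(median_filter_mask(binary_mask(full))$cells, full)
  expect_error(median_filter_mask(binary_mask(lone), 4L),
               class = "csvd_config_error")
  set.seed(7)
  for (i in 1:15) {
    m <- random_mask(16, 16)
    for (k in c(3L, 5L))
      expect_identical(median_filter_mask(binary_mask(m), k)$cells,
                       oracle_median(m, k))
  }
})

test_that("brain geometry reports tight boxes, centroids and areas", {
  one <- matrix(0L, 10, 10); one[5, 7] <- 1L
  g <- brain_geometry(binary_mask(one))
  expect_equal(unname(g$bbox), c(5, 7, 5, 7))
  expect_equal(unname(g$centroid), c(5, 7))
  expect_equal(g$area_px, 1L)
  blk <- matrix(0L, 10, 10); blk[3:5, 3:5] <- 1L
  g <- brain_geometry(binary_mask(blk), pixel_spacing_mm = 0.5)
  expect_equal(g$area_px, 9L)
  expect_equal(g$area_mm2, 2.25)
  expect_error(brain_geometry(binary_mask(matrix(0L, 2, 2))),
               class = "csvd_empty_mask_error")
  # rasterized disk area approaches pi r^2
  r <- 20
  d <- sqrt(outer((1:64 - 32.5)^2, (1:64 - 32.5)^2, "+"))
  disk <- binary_mask((d <= r) * 1L)
  expect_lt(abs(brain_geometry(disk)$area_px - pi * r^2) / (pi * r^2), 0.05)
})

test_that("combine_regions unions masks and drops extracranial components", {
  a <- binary_mask(matrix(0L, 6, 6))
  b <- random_mask(6, 6); bm <- binary_mask(b)
  expect_identical(combine_regions(a, bm)$cells, b)
  expect_identical(combine_regions(bm, bm)$cells, b)
  expect_error(combine_regions(a, binary_mask(matrix(0L, 3, 3))),
               class = "csvd_shape_error")
  # a component reaching outside the cranium bbox is dropped
  u <- matrix(0L, 10, 10)
  u[1, ] <- 1L            # exterior band touching the border
  u[5:6, 5:6] <- 1L       # intracranial blob
  got <- combine_regions(binary_mask(u), binary_mask(matrix(0L, 10, 10)),
                         cranium_bbox = c(2, 2, 9, 9))
  expect_equal(sum(got$cells), 4L)
  expect_equal(sum(got$cells[5:6, 5:6]), 4L)
})

test_that("extract_brain recovers the phantom brain and no cranium", {
  spec <- tiny_spec(96)
  thr <- phantom_extraction_threshold(spec)
  ring <- ring_mask_of(spec)
  for (seed in 1:3) {
    g <- generate_slice(spec, seed)
    ex <- extract_brain(g$slice, threshold = thr)
    m <- ex$region$mask$cells
    brain_px <- matrix(g$truth$classes %in% 1:3, spec$image_size)
    expect_gte(sum(m[brain_px]) / sum(brain_px), 0.99)
    expect_equal(sum(m[ring]), 0L)
    # the largest binarized component is excluded entirely
    expect_equal(sum(m[ex$steps$binary$cells == 1L & ring]), 0L)
    expect_identical(ex$masked$pixels, g$slice$pixels * m)
  }
  expect_error(extract_brain(grayscale_slice(matrix(0, 48, 48))),
               class = "csvd_degenerate_image_error")
})
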