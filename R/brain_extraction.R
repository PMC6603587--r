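# Rule-based brain extraction: threshold the slice, remove the cranium
# as the largest connected component, recover the intracranial region
# from the union of the residual bright structures and the
# inverse-thresholded interior, then clean the mask with a median
# filter and measure the result.

#' Construct a binary mask
#'
#' @param cells matrix of 0/1 values (logical accepted).
#' @return object of class `binary_mask` with fields `cells`, `height`,
#'   `width`.
#' @export
binary_mask <- function(cells) {
  if (!is.matrix(cells)) abort_shape("cells must be a matrix")
  if (is.logical(cells)) cells <- cells * 1L
  storage.mode(cells) <- "integer"
  if (anyNA(cells) || any(cells != 0L & cells != 1L))
    abort_format("mask cells must be 0 or 1")
  structure(list(cells = cells, height = nrow(cells), width = ncol(cells)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %dx%d, %d foreground px>\n",
              x$height, x$width, sum(x$cells)))
  invisible(x)
}

#' Otsu's threshold
#'
#' Exhaustive search over the integer intensity histogram for the
#' threshold maximizing between-class variance, with foreground
#' defined as `intensity >= t`. Ties resolve to the lowest threshold.
#'
#' @param pixels intensity matrix (values are rounded to integers for
#'   the histogram).
#' @return the scalar threshold.
#' @export
otsu_threshold <- function(pixels) {
  v <- as.vector(round(pixels))
  if (length(unique(v)) < 2L)
    abort_degenerate_image("constant image: Otsu threshold undefined")
  lo <- min(v); hi <- max(v)
  counts <- tabulate(v - lo + 1L, nbins = hi - lo + 1L)
  levels <- lo:hi
  n <- length(v)
  cum_n <- cumsum(counts)
  cum_s <- cumsum(counts * levels)
  total_s <- cum_s[length(cum_s)]
  # class 0 = {x < t} corresponds to cutting after bin t-1
  w0 <- cum_n[-length(cum_n)] / n
  s0 <- cum_s[-length(cum_s)]
  w1 <- 1 - w0
  mu0 <- ifelse(w0 > 0, s0 / (n * w0), 0)
  mu1 <- ifelse(w1 > 0, (total_s - s0) / (n * w1), 0)
  sigma_b <- w0 * w1 * (mu0 - mu1)^2
  levels[which.max(sigma_b) + 1L]
}

resolve_threshold <- function(slice, threshold) {
  if (is.numeric(threshold)) return(threshold)
  if (identical(threshold, "otsu")) return(otsu_threshold(slice$pixels))
  abort_config(sprintf("unknown threshold policy '%s'", threshold))
}

#' Binarize a slice
#'
#' Step 1 of brain extraction: foreground where
#' `intensity >= threshold`. On typical T1 slices the threshold
#' separates the bright cranium shell (and small hyperintense lesions)
#' from tissue, making the cranium the largest foreground component.
#'
#' @param slice a [grayscale_slice()].
#' @param threshold `"otsu"` or a fixed numeric threshold.
#' @return a [binary_mask()] with the applied threshold recorded in
#'   attribute `"threshold"`.
#' @export
binarize <- function(slice, threshold = "otsu") {
  stopifnot(inherits(slice, "grayscale_slice"))
  t <- resolve_threshold(slice, threshold)
  m <- binary_mask((slice$pixels >= t) * 1L)
  attr(m, "threshold") <- t
  m
}

#' Inverse-binarize a slice
#'
#' Step 3: the elementwise complement of [binarize()] at the same
#' threshold, capturing the sub-threshold interior (brain tissue,
#' central structures) plus the exterior background.
#'
#' @inheritParams binarize
#' @return a [binary_mask()] with attribute `"threshold"`.
#' @export
inverse_binarize <- function(slice, threshold = "otsu") {
  m <- binarize(slice, threshold)
  out <- binary_mask(1L - m$cells)
  attr(out, "threshold") <- attr(m, "threshold")
  out
}

#' Label connected components
#'
#' Components are numbered 1..count in row-major first-encounter
#' order; 0 is background.
#'
#' @param mask a [binary_mask()].
#' @param connectivity 4 or 8 (default 8: avoids splitting thin
#'   diagonal structures such as the skull ring).
#' @return object of class `component_set`: `labels` (integer matrix),
#'   `areas` (pixel counts, indexed by component id), `count`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!connectivity %in% c(4L, 8L))
    abort_config("connectivity must be 4 or 8")
  lab <- cc_label_2d(mask$cells, as.integer(connectivity))
  count <- max(lab)
  areas <- if (count > 0) tabulate(lab[lab > 0L], nbins = count) else integer(0)
  structure(list(labels = lab, areas = areas, count = count,
                 connectivity = as.integer(connectivity)),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set: %d components, areas [%s]>\n", x$count,
              paste(utils::head(sort(x$areas, decreasing = TRUE), 5),
                    collapse = ", ")))
  invisible(x)
}

mask_bbox <- function(cells) {
  idx <- which(cells != 0L, arr.ind = TRUE)
  c(row_min = min(idx[, 1]), col_min = min(idx[, 2]),
    row_max = max(idx[, 1]), col_max = max(idx[, 2]))
}

#' Remove the largest connected component
#'
#' Step 2: delete the maximum-area component (the cranium on a head
#' slice). A tie for the maximum is broken toward the lowest component
#' id, i.e. the component first encountered in a row-major scan.
#'
#' @inheritParams label_components
#' @return the reduced [binary_mask()], with attributes
#'   `"removed_bbox"` (1-based closed box of the removed component),
#'   `"removed_area"` and `"removed_tie"` (TRUE when the maximum was
#'   tied).
#' @export
remove_largest <- function(mask, connectivity = 8L) {
  cs <- label_components(mask, connectivity)
  if (cs$count == 0L) abort_empty_mask("mask has no foreground component")
  biggest <- which.max(cs$areas)           # first index ties to lowest id
  sel <- cs$labels == biggest
  out <- mask$cells
  out[sel] <- 0L
  res <- binary_mask(out)
  attr(res, "removed_bbox") <- mask_bbox(sel * 1L)
  attr(res, "removed_area") <- cs$areas[biggest]
  attr(res, "removed_tie") <- sum(cs$areas == cs$areas[biggest]) > 1L
  res
}

#' Union of two regions, restricted to the intracranial interior
#'
#' Step 4: elementwise OR of the residual bright structures (step 2)
#' and the inverse-binarized interior (step 3). The raw OR also
#' contains the exterior background (equally sub-threshold), so when a
#' cranium bounding box is supplied the result keeps only components
#' lying entirely in the strict interior of that box; the exterior
#' component always reaches the image border or spills outside the box
#' and is dropped.
#'
#' @param a,b [binary_mask()]s of equal dimensions.
#' @param cranium_bbox optional `(row_min, col_min, row_max, col_max)`
#'   closed box of the removed cranium (attribute `"removed_bbox"` of
#'   [remove_largest()]'s result).
#' @param connectivity used for the restriction components.
#' @return a [binary_mask()].
#' @export
combine_regions <- function(a, b, cranium_bbox = NULL, connectivity = 8L) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (a$height != b$height || a$width != b$width)
    abort_shape("mask dimensions differ")
  u <- binary_mask(pmax(a$cells, b$cells))
  if (is.null(cranium_bbox)) return(u)
  cs <- label_components(u, connectivity)
  if (cs$count == 0L) return(u)
  keep <- logical(cs$count)
  for (k in seq_len(cs$count)) {
    idx <- which(cs$labels == k, arr.ind = TRUE)
    keep[k] <- min(idx[, 1]) > cranium_bbox[1] &&
      min(idx[, 2]) > cranium_bbox[2] &&
      max(idx[, 1]) < cranium_bbox[3] &&
      max(idx[, 2]) < cranium_bbox[4]
  }
  out <- u$cells
  out[!(cs$labels %in% which(keep)) ] <- 0L
  binary_mask(out)
}

#' Median-filter a binary mask
#'
#' Step 5: each output cell is the median of its kernel x kernel
#' neighborhood with edge replication (out-of-bounds samples take the
#' nearest edge value, counted with multiplicity). For a binary mask
#' this is a majority vote; the output is still binary.
#'
#' @param mask a [binary_mask()].
#' @param kernel odd width >= 3 (default 3, the smallest
#'   noise-removing kernel).
#' @return a [binary_mask()].
#' @export
median_filter_mask <- function(mask, kernel = 3L) {
  stopifnot(inherits(mask, "binary_mask"))
  kernel <- as.integer(kernel)
  if (kernel < 3L || kernel %% 2L == 0L)
    abort_config("median kernel must be odd and >= 3")
  binary_mask(median_filter_bin(mask$cells, kernel))
}

#' Measure a brain mask
#'
#' Step 6: tight bounding box, centroid and areas of the extracted
#' region. Coordinates are 1-based `(row, col)`; the bounding box is
#' closed on both ends.
#'
#' @param mask a non-empty [binary_mask()].
#' @param pixel_spacing_mm in-plane pixel size; `NA` leaves `area_mm2`
#'   as `NA`.
#' @return object of class `brain_region`: `mask`, `bbox`, `centroid`,
#'   `area_px`, `area_mm2`.
#' @export
brain_geometry <- function(mask, pixel_spacing_mm = NA_real_) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$cells != 0L)) abort_empty_mask("empty mask has no geometry")
  idx <- which(mask$cells != 0L, arr.ind = TRUE)
  structure(
    list(mask = mask,
         bbox = mask_bbox(mask$cells),
         centroid = c(row = mean(idx[, 1]), col = mean(idx[, 2])),
         area_px = nrow(idx),
         area_mm2 = nrow(idx) * pixel_spacing_mm^2),
    class = "brain_region")
}

#' @export
print.brain_region <- function(x, ...) {
  cat(sprintf("<brain_region: %d px (%s mm^2), bbox [%d:%d, %d:%d], centroid (%.1f, %.1f)>\n",
              x$area_px,
              ifelse(is.na(x$area_mm2), "?", format(x$area_mm2)),
              x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4],
              x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Extract the brain from a head slice
#'
#' Runs the six-step rule-based procedure: binarize, remove the
#' cranium (largest component), inverse-binarize, union restricted to
#' the intracranial interior, median filter, measure. The masked slice
#' keeps original intensities where the final mask is 1 and is 0
#' elsewhere.
#'
#' @param slice a [grayscale_slice()].
#' @param threshold `"otsu"` or a fixed numeric value. Otsu assumes a
#'   histogram whose dominant split is tissue vs cranium; for images
#'   with a large dark background (such as the bundled phantom) a
#'   fixed threshold between tissue and skull intensities is the
#'   reliable choice (see [phantom_extraction_threshold()]).
#' @param connectivity component connectivity (default 8).
#' @param median_kernel odd kernel width for step 5.
#' @return object of class `brain_extraction`: `region` (a
#'   `brain_region`), `masked` (a [grayscale_slice()]), `threshold`,
#'   and `steps` — the per-step intermediate masks (`binary`,
#'   `decranial`, `inverse`, `union`, `filtered`) for debugging.
#' @export
extract_brain <- function(slice, threshold = "otsu", connectivity = 8L,
                          median_kernel = 3L) {
  stopifnot(inherits(slice, "grayscale_slice"))
  m1 <- binarize(slice, threshold)
  t <- attr(m1, "threshold")
  m2 <- remove_largest(m1, connectivity)
  m3 <- binary_mask(1L - m1$cells)
  m4 <- combine_regions(m2, m3, cranium_bbox = attr(m2, "removed_bbox"),
                        connectivity = connectivity)
  m5 <- median_filter_mask(m4, median_kernel)
  if (!any(m5$cells != 0L))
    abort_no_brain("no brain region survived extraction")
  region <- brain_geometry(m5, slice$pixel_spacing_mm)
  masked <- grayscale_slice(slice$pixels * m5$cells,
                            pixel_spacing_mm = slice$pixel_spacing_mm,
                            slice_index = slice$slice_index)
  structure(list(region = region, masked = masked, threshold = t,
                 steps = list(binary = m1, decranial = m2, inverse = m3,
                              union = m4, filtered = m5)),
            class = "brain_extraction")
}
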