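# Tiling slices into small square patches and reassembling patch-level
# class decisions into a full-resolution label map. The default 7x7
# non-overlapping tiling partitions the (zero-padded) image, so patch
# decisions recombine into exactly the original frame.

#' Define a patch tiling
#'
#' Padding (bottom/right only, keeping the top-left origin stable) is
#' computed so that patches tile the padded image exactly:
#' `grid_rows = ceiling(height / stride)` and likewise for columns.
#'
#' @param height,width original image size in pixels.
#' @param patch_size square patch width (default 7).
#' @param stride step between patch origins; default `patch_size`,
#'   i.e. non-overlapping.
#' @param pad_value intensity used for padded cells (class 0 when
#'   tiling label maps).
#' @return object of class `patch_grid`.
#' @export
patch_grid <- function(height, width, patch_size = 7L, stride = patch_size,
                       pad_value = 0) {
  patch_size <- as.integer(patch_size); stride <- as.integer(stride)
  height <- as.integer(height); width <- as.integer(width)
  if (patch_size < 1L || stride < 1L || height < 1L || width < 1L)
    abort_config("patch_size, stride and image dims must be >= 1")
  rows <- as.integer(ceiling(height / stride))
  cols <- as.integer(ceiling(width / stride))
  structure(
    list(patch_size = patch_size, stride = stride,
         original_height = height, original_width = width,
         padded_height = as.integer(max((rows - 1L) * stride + patch_size,
                                        rows * stride)),
         padded_width = as.integer(max((cols - 1L) * stride + patch_size,
                                       cols * stride)),
         grid_rows = rows, grid_cols = cols, pad_value = pad_value),
    class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid %dx%d px -> %dx%d patches of %d (stride %d), padded %dx%d>\n",
              x$original_height, x$original_width, x$grid_rows, x$grid_cols,
              x$patch_size, x$stride, x$padded_height, x$padded_width))
  invisible(x)
}

pad_matrix <- function(m, grid, value) {
  out <- matrix(value, grid$padded_height, grid$padded_width)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

#' Extract patches from a slice or label map
#'
#' Patches are enumerated row-major over the grid (grid row 1
#' left-to-right first). Each patch is flattened row-major
#' (within-patch row 1 first) into one row of the `patches` matrix.
#'
#' @param x a [grayscale_slice()], [label_map()] or plain matrix whose
#'   dimensions equal the grid's original dimensions.
#' @param grid a [patch_grid()].
#' @return object of class `patch_set`: `patches` (n x patch_size^2
#'   matrix), `positions` (data frame of 1-based `grid_row`,
#'   `grid_col`), `labels` (NULL until assigned), and the `grid`.
#' @export
extract_patches <- function(x, grid) {
  stopifnot(inherits(grid, "patch_grid"))
  m <- if (inherits(x, "grayscale_slice")) x$pixels
       else if (inherits(x, "label_map")) x$classes
       else if (is.matrix(x)) x
       else abort_shape("cannot tile this object")
  if (nrow(m) != grid$original_height || ncol(m) != grid$original_width)
    abort_shape(sprintf("image is %dx%d but grid expects %dx%d",
                        nrow(m), ncol(m),
                        grid$original_height, grid$original_width))
  pv <- if (inherits(x, "label_map")) 0L else grid$pad_value
  pm <- pad_matrix(m, grid, pv)
  ps <- grid$patch_size
  n <- grid$grid_rows * grid$grid_cols
  patches <- matrix(0, n, ps * ps)
  positions <- data.frame(grid_row = integer(n), grid_col = integer(n))
  i <- 0L
  for (gr in seq_len(grid$grid_rows)) {
    r0 <- (gr - 1L) * grid$stride
    for (gc in seq_len(grid$grid_cols)) {
      c0 <- (gc - 1L) * grid$stride
      i <- i + 1L
      block <- pm[r0 + seq_len(ps), c0 + seq_len(ps), drop = FALSE]
      patches[i, ] <- as.vector(t(block))   # row-major flatten
      positions$grid_row[i] <- gr
      positions$grid_col[i] <- gc
    }
  }
  structure(list(patches = patches, positions = positions, labels = NULL,
                 grid = grid),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set: %d patches of %dx%d%s>\n", nrow(x$patches),
              x$grid$patch_size, x$grid$patch_size,
              if (is.null(x$labels)) "" else ", labeled"))
  invisible(x)
}

#' Assign ground-truth labels to patches
#'
#' Two rules:
#' \describe{
#'   \item{`majority_priority`}{most frequent class in the patch
#'     footprint, ties broken by priority 3 > 2 > 1 > 0;}
#'   \item{`any_lesion` (default)}{class 3 as soon as one lesion pixel
#'     is present, else `majority_priority`. Lesions are rare and
#'     small, so a plain majority vote would erase sub-patch lesions.}
#' }
#' Padded cells count as class 0.
#'
#' @param truth a [label_map()] matching the grid's original size.
#' @param grid a [patch_grid()].
#' @param rule `"any_lesion"` or `"majority_priority"`.
#' @return integer vector of class ids, one per patch, in patch-set
#'   order.
#' @export
assign_patch_labels <- function(truth, grid,
                                rule = c("any_lesion", "majority_priority")) {
  if (is.character(rule) && length(rule) == 1L &&
      !rule %in% c("any_lesion", "majority_priority"))
    abort_config(sprintf("unknown labeling rule '%s'", rule))
  rule <- match.arg(rule)
  stopifnot(inherits(truth, "label_map"))
  ps <- extract_patches(truth, grid)
  apply_label_rule(ps$patches, rule)
}

apply_label_rule <- function(patch_mat, rule) {
  n <- nrow(patch_mat)
  labels <- integer(n)
  for (i in seq_len(n)) {
    counts <- tabulate(patch_mat[i, ] + 1L, nbins = 4L)
    if (rule == "any_lesion" && counts[4L] > 0L) {
      labels[i] <- 3L
    } else {
      best <- which(counts == max(counts))   # class ids + 1
      labels[i] <- max(best) - 1L            # priority 3 > 2 > 1 > 0
    }
  }
  labels
}

#' Reassemble patch labels into a label map
#'
#' Each patch footprint is filled with its class; padded rows/columns
#' are cropped so the output has the grid's original dimensions. With
#' the default stride = patch_size the footprints partition the image.
#'
#' @param labels integer class ids, one per grid cell, in patch-set
#'   (row-major) order.
#' @param grid a [patch_grid()].
#' @return a [label_map()].
#' @export
reassemble <- function(labels, grid) {
  stopifnot(inherits(grid, "patch_grid"))
  n <- grid$grid_rows * grid$grid_cols
  if (length(labels) != n)
    abort_shape(sprintf("got %d labels for a %d-cell grid",
                        length(labels), n))
  out <- matrix(0L, grid$padded_height, grid$padded_width)
  ps <- grid$patch_size
  i <- 0L
  for (gr in seq_len(grid$grid_rows)) {
    r0 <- (gr - 1L) * grid$stride
    for (gc in seq_len(grid$grid_cols)) {
      c0 <- (gc - 1L) * grid$stride
      i <- i + 1L
      out[r0 + seq_len(ps), c0 + seq_len(ps)] <- as.integer(labels[i])
    }
  }
  label_map(out[seq_len(grid$original_height),
                seq_len(grid$original_width), drop = FALSE])
}
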