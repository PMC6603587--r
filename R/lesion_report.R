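# Clinical outputs: per-slice lesion descriptors (position, bounding
# box, area, diameter, small-vessel flag) and the stacked 3D summary.
#
# Connectivity: 8-connected in-plane, 26-connected across the stack
# (lesions are blob-like; stricter connectivity would fragment them).
# The < 15 mm small-vessel criterion is reported as a flag and never
# used to suppress detections — that decision belongs to the
# clinician.

max_pairwise_dist <- function(coords) {
  n <- nrow(coords)
  if (n == 1L) return(0)
  if (n > 3L) {
    hull <- grDevices::chull(coords[, 2], coords[, 1])
    coords <- coords[hull, , drop = FALSE]
    n <- nrow(coords)
  }
  best <- 0
  for (i in seq_len(n - 1L)) {
    d2 <- (coords[(i + 1L):n, 1] - coords[i, 1])^2 +
      (coords[(i + 1L):n, 2] - coords[i, 2])^2
    best <- max(best, max(d2))
  }
  sqrt(best)
}

#' Locate lesions in a label map
#'
#' One record per 8-connected component of lesion-class pixels,
#' ordered by area descending, then by centroid in row-major order.
#' Coordinates are 1-based `(row, col)`; bounding boxes are closed.
#' `max_diameter_mm` is the longest pairwise distance between member
#' pixel centres (computed exactly via the convex hull) times the
#' pixel spacing; `small_vessel_flag` is true iff it is below 15 mm.
#'
#' @param map a [label_map()].
#' @param pixel_spacing_mm in-plane pixel size (mm). The acquisition
#'   never states it, so it must be supplied; 0.5 mm/px is the
#'   documented default assumption.
#' @param slice_index ordinal slice position recorded in each record.
#' @param lesion_class class id counted as lesion (default 3).
#' @return data frame of class `lesion_records` with columns
#'   `slice_index`, `component_id`, `centroid_row`, `centroid_col`,
#'   `row_min`, `col_min`, `row_max`, `col_max`, `area_px`,
#'   `area_mm2`, `max_diameter_mm`, `small_vessel_flag`; zero rows
#'   when the map holds no lesions.
#' @export
find_lesions <- function(map, pixel_spacing_mm = 0.5,
                         slice_index = NA_integer_, lesion_class = 3L) {
  stopifnot(inherits(map, "label_map"))
  if (!is.na(pixel_spacing_mm) && pixel_spacing_mm <= 0)
    abort_config("pixel spacing must be > 0")
  lab <- cc_label_2d((map$classes == lesion_class) * 1L, 8L)
  k <- max(lab)
  rows <- lapply(seq_len(k), function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    data.frame(
      slice_index = slice_index, component_id = id,
      centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2]),
      row_min = min(idx[, 1]), col_min = min(idx[, 2]),
      row_max = max(idx[, 1]), col_max = max(idx[, 2]),
      area_px = nrow(idx),
      area_mm2 = nrow(idx) * pixel_spacing_mm^2,
      max_diameter_mm = max_pairwise_dist(idx) * pixel_spacing_mm)
  })
  df <- if (k > 0) do.call(rbind, rows) else
    data.frame(slice_index = integer(0), component_id = integer(0),
               centroid_row = numeric(0), centroid_col = numeric(0),
               row_min = integer(0), col_min = integer(0),
               row_max = integer(0), col_max = integer(0),
               area_px = integer(0), area_mm2 = numeric(0),
               max_diameter_mm = numeric(0))
  orig_ids <- df$component_id
  if (nrow(df) > 0) {
    ord <- order(-df$area_px, df$centroid_row, df$centroid_col)
    df <- df[ord, , drop = FALSE]
    orig_ids <- df$component_id
    df$component_id <- seq_len(nrow(df))
    rownames(df) <- NULL
  }
  df$small_vessel_flag <- df$max_diameter_mm < 15
  class(df) <- c("lesion_records", "data.frame")
  # internal bookkeeping for stack_slices(): the raw component label
  # matrix and the per-row original label id
  attr(df, "label_matrix") <- lab
  attr(df, "orig_ids") <- orig_ids
  df
}

#' Stack per-slice label maps into a 3D lesion report
#'
#' Lesion components in adjacent slices are merged into one 3D group
#' under 26-connectivity on the stacked voxel grid (footprints
#' touching by at least one pixel, including diagonally). Group volume
#' is the sum of member areas times the inter-slice spacing.
#'
#' @param maps ordered list of [label_map()]s of equal dimensions
#'   (slice 1 first).
#' @param pixel_spacing_mm in-plane pixel size.
#' @param inter_slice_spacing_mm slice-to-slice distance; the default
#'   4.4 mm is slice thickness (3.4 mm) plus gap (1.0 mm).
#' @param lesion_class class id counted as lesion.
#' @return object of class `volume_report`: spacings, `records` (all
#'   2D lesion records with a `group_id` column) and `lesions_3d`, a
#'   list with per-group `group_id`, `slices`, `n_components`,
#'   `volume_mm3` and `centroid` (row, col, slice).
#' @export
stack_slices <- function(maps, pixel_spacing_mm = 0.5,
                         inter_slice_spacing_mm = 4.4, lesion_class = 3L) {
  if (length(maps) < 1L) abort_shape("need at least one label map")
  for (m in maps) stopifnot(inherits(m, "label_map"))
  h <- maps[[1]]$height; w <- maps[[1]]$width
  ok <- vapply(maps, function(m) m$height == h && m$width == w, logical(1))
  if (!all(ok)) abort_shape("label maps have inconsistent dimensions")
  ns <- length(maps)
  vox <- array(0L, c(h, w, ns))
  for (s in seq_len(ns)) vox[, , s] <- (maps[[s]]$classes == lesion_class) * 1L
  lab3 <- cc_label_3d(as.integer(vox), h, w, ns)
  dim(lab3) <- c(h, w, ns)

  records <- list()
  for (s in seq_len(ns)) {
    rec <- find_lesions(maps[[s]], pixel_spacing_mm, slice_index = s,
                        lesion_class = lesion_class)
    if (nrow(rec) == 0) next
    lab2 <- attr(rec, "label_matrix")
    orig <- attr(rec, "orig_ids")
    rec$group_id <- vapply(seq_len(nrow(rec)), function(i) {
      px <- which(lab2 == orig[i])[1]      # any member pixel
      lab3[px + (s - 1L) * h * w]
    }, integer(1))
    attr(rec, "label_matrix") <- NULL
    attr(rec, "orig_ids") <- NULL
    records[[s]] <- rec
  }
  records <- if (length(records)) do.call(rbind, records) else
    cbind(find_lesions(maps[[1]], pixel_spacing_mm), group_id = integer(0))

  groups <- list()
  for (g in sort(unique(records$group_id))) {
    sel <- records[records$group_id == g, , drop = FALSE]
    idx <- which(lab3 == g, arr.ind = TRUE)
    groups[[length(groups) + 1L]] <- list(
      group_id = g,
      slices = sort(unique(sel$slice_index)),
      n_components = nrow(sel),
      volume_mm3 = sum(sel$area_mm2) * inter_slice_spacing_mm,
      centroid = c(row = mean(idx[, 1]), col = mean(idx[, 2]),
                   slice = mean(idx[, 3])))
  }
  structure(list(pixel_spacing_mm = pixel_spacing_mm,
                 inter_slice_spacing_mm = inter_slice_spacing_mm,
                 n_slices = ns, records = records, lesions_3d = groups),
            class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf("<volume_report: %d slices, %d 3D lesion group(s), total %.2f mm^3>\n",
              x$n_slices, length(x$lesions_3d),
              sum(vapply(x$lesions_3d, `[[`, numeric(1), "volume_mm3"))))
  invisible(x)
}

#' Write a lesion report to JSON (with optional overlays)
#'
#' @param x a `lesion_records` data frame or a `volume_report`.
#' @param path output JSON path.
#' @param slices optional list of [grayscale_slice()]s; with `maps`
#'   and `overlays_dir`, one overlay PNG is written per slice.
#' @param maps optional list of [label_map()]s matching `slices`.
#' @param overlays_dir directory for overlay PNGs.
#' @param style overlay style, see [render_overlay()].
#' @return `path`, invisibly.
#' @export
write_lesion_report <- function(x, path, slices = NULL, maps = NULL,
                                overlays_dir = NULL, style = "fill") {
  payload <- if (inherits(x, "volume_report")) {
    list(kind = "volume_report",
         pixel_spacing_mm = x$pixel_spacing_mm,
         inter_slice_spacing_mm = x$inter_slice_spacing_mm,
         n_slices = x$n_slices,
         records = x$records,
         lesions_3d = lapply(x$lesions_3d, function(g)
           list(group_id = g$group_id, slices = g$slices,
                n_components = g$n_components,
                volume_mm3 = g$volume_mm3,
                centroid = as.list(g$centroid))))
  } else if (inherits(x, "lesion_records") || is.data.frame(x)) {
    list(kind = "lesion_records", records = x)
  } else abort_shape("cannot serialize this object as a lesion report")
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    TRUE
  }, error = function(e) abort_io(conditionMessage(e)))
  if (!is.null(overlays_dir) && !is.null(slices) && !is.null(maps)) {
    if (length(slices) != length(maps))
      abort_shape(sprintf("%d slices but %d label maps for overlays",
                          length(slices), length(maps)))
    dir.create(overlays_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(slices)) {
      ov <- render_overlay(slices[[i]], maps[[i]], style = style)
      png::writePNG(ov / 255,
                    file.path(overlays_dir, sprintf("overlay_%03d.png", i)))
    }
  }
  invisible(path)
}

#' Read back a JSON lesion report
#'
#' @param path JSON written by [write_lesion_report()].
#' @return the parsed report (records as a data frame).
#' @export
read_lesion_report <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}
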