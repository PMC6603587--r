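# Image containers and I/O.
#
# Raster conventions used package-wide: matrices are indexed
# [row, col], 1-based, row 1 = image top. Intensities are kept in
# their native integer range (no silent normalization); the classifier
# applies its own explicit rescale to [0, 1].

#' Construct a grayscale MRI slice
#'
#' The pipeline's raw input: a 2D grid of non-negative intensities
#' with optional physical pixel spacing and position in the
#' acquisition stack. The nominal acquisition size is 512x512 but any
#' size of at least 32x32 is accepted; smaller grids are allowed for
#' unit tests via `strict = FALSE`.
#'
#' @param pixels numeric or integer matrix of finite, non-negative
#'   intensities; row 1 is the image top.
#' @param pixel_spacing_mm in-plane size of one pixel in millimetres,
#'   or `NA` when unknown.
#' @param slice_index 1-based ordinal position in the acquisition
#'   stack, or `NA`.
#' @param strict enforce the 32x32 minimum acquisition size.
#' @return an object of class `grayscale_slice` with fields `pixels`,
#'   `height`, `width`, `pixel_spacing_mm`, `slice_index`.
#' @export
grayscale_slice <- function(pixels, pixel_spacing_mm = NA_real_,
                            slice_index = NA_integer_, strict = FALSE) {
  if (!is.matrix(pixels)) abort_shape("pixels must be a matrix")
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels)) || any(pixels < 0))
    abort_format("intensities must be finite and >= 0")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    abort_shape("empty image")
  if (strict && (nrow(pixels) < 32L || ncol(pixels) < 32L))
    abort_shape("slices smaller than 32x32 are not accepted")
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         slice_index = as.integer(slice_index)),
    class = "grayscale_slice"
  )
}

#' @export
print.grayscale_slice <- function(x, ...) {
  cat(sprintf("<grayscale_slice %dx%d, range [%g, %g], spacing %s mm, slice %s>\n",
              x$height, x$width, min(x$pixels), max(x$pixels),
              ifelse(is.na(x$pixel_spacing_mm), "?", format(x$pixel_spacing_mm)),
              ifelse(is.na(x$slice_index), "?", x$slice_index)))
  invisible(x)
}

#' Construct a label map
#'
#' Per-pixel class assignment with the 4-class scheme:
#' 0 = non-brain, 1 = normal brain, 2 = central brain, 3 = lesion.
#'
#' @param classes integer matrix with every cell in `{0, 1, 2, 3}`.
#' @return object of class `label_map` with fields `classes`,
#'   `height`, `width`.
#' @export
label_map <- function(classes) {
  if (!is.matrix(classes)) abort_shape("classes must be a matrix")
  storage.mode(classes) <- "integer"
  if (anyNA(classes) || any(classes < 0L | classes > 3L))
    abort_format("label map cells must be class ids in {0, 1, 2, 3}")
  structure(list(classes = classes, height = nrow(classes),
                 width = ncol(classes)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  tab <- tabulate(as.vector(x$classes) + 1L, nbins = 4L)
  cat(sprintf("<label_map %dx%d: non-brain %d, brain %d, central %d, lesion %d>\n",
              x$height, x$width, tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

#' Ground-truth color code
#'
#' The 4-color annotation convention for label maps: black = non-brain,
#' green = normal brain, blue = central brain, red = lesion. The
#' mapping is bijective over the four classes.
#'
#' @return a 4x3 integer matrix of RGB triples (0-255); row `i`
#'   corresponds to class id `i - 1`.
#' @export
csvd_palette <- function() {
  m <- rbind(c(0L, 0L, 0L),      # 0 non-brain
             c(0L, 255L, 0L),    # 1 normal brain
             c(0L, 0L, 255L),    # 2 central brain
             c(255L, 0L, 0L))    # 3 lesion
  dimnames(m) <- list(class = as.character(0:3), c("r", "g", "b"))
  m
}

## ---- NetPBM (PGM / PPM) ------------------------------------------------
## Minimal hand-written reader/writer for the plain-text NetPBM formats
## (plus the binary variants on read). No installed R package writes
## P2/P3, and text-format fixtures are required, so this tiny parser is
## kept in-tree.

pnm_header <- function(raw) {
  n <- length(raw)
  toks <- character(0); i <- 1L
  while (length(toks) < 4L && i <= n) {
    ch <- rawToChar(raw[i])
    if (ch == "#") {                       # comment to end of line
      while (i <= n && rawToChar(raw[i]) != "\n") i <- i + 1L
    } else if (grepl("[[:space:]]", ch)) {
      i <- i + 1L
    } else {
      tok <- ""
      while (i <= n && !grepl("[[:space:]]", rawToChar(raw[i]))) {
        tok <- paste0(tok, rawToChar(raw[i])); i <- i + 1L
      }
      toks <- c(toks, tok)
      if (length(toks) == 1L && toks[1] %in% c("P1", "P4"))
        abort_unsupported("bitmap PBM files are not supported")
    }
  }
  if (length(toks) < 4L) abort_format("truncated PNM header")
  list(magic = toks[1], width = as.integer(toks[2]),
       height = as.integer(toks[3]), maxval = as.integer(toks[4]),
       data_at = i + 1L)   # single whitespace byte after maxval
}

read_pnm <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  h <- pnm_header(raw)
  if (is.na(h$width) || is.na(h$height) || is.na(h$maxval))
    abort_format(sprintf("bad PNM header in %s", path))
  channels <- if (h$magic %in% c("P2", "P5")) 1L
              else if (h$magic %in% c("P3", "P6")) 3L
              else abort_format(sprintf("unknown PNM magic '%s'", h$magic))
  nval <- h$width * h$height * channels
  vals <- if (h$magic %in% c("P2", "P3")) {
    txt <- rawToChar(raw[h$data_at:length(raw)])
    v <- suppressWarnings(as.numeric(scan(text = txt, quiet = TRUE)))
    if (length(v) < nval) abort_format("truncated PNM pixel data")
    v[seq_len(nval)]
  } else {
    bytes <- raw[h$data_at:length(raw)]
    if (h$maxval < 256L) {
      if (length(bytes) < nval) abort_format("truncated PNM pixel data")
      as.integer(bytes[seq_len(nval)])
    } else {
      if (length(bytes) < 2L * nval) abort_format("truncated PNM pixel data")
      hi <- as.integer(bytes[seq(1L, 2L * nval, 2L)])
      lo <- as.integer(bytes[seq(2L, 2L * nval, 2L)])
      hi * 256L + lo
    }
  }
  if (channels == 1L) {
    matrix(vals, nrow = h$height, ncol = h$width, byrow = TRUE)
  } else {
    arr <- array(0, c(h$height, h$width, 3L))
    for (k in 1:3)
      arr[, , k] <- matrix(vals[seq(k, nval, 3L)], h$height, h$width,
                           byrow = TRUE)
    arr
  }
}

write_pnm <- function(x, path, maxval = NULL) {
  if (is.matrix(x)) {
    vals <- as.integer(round(t(x)))
    magic <- "P2"; w <- ncol(x); hgt <- nrow(x)
  } else if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L) {
    hgt <- dim(x)[1]; w <- dim(x)[2]
    vals <- integer(hgt * w * 3L)
    flat <- round(x)
    for (k in 1:3) vals[seq(k, length(vals), 3L)] <- as.integer(t(flat[, , k]))
    magic <- "P3"
  } else abort_shape("write_pnm needs a matrix or HxWx3 array")
  if (is.null(maxval)) maxval <- max(255L, max(vals))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(magic, paste(w, hgt), as.character(maxval)), con)
  writeLines(paste(vals, collapse = " "), con)
  invisible(path)
}

## ---- slice read/write --------------------------------------------------

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = "png", pgm = "pnm", ppm = "pnm", pnm = "pnm",
         dcm = "dicom", dicom = "dicom", tif = "tiff", tiff = "tiff",
         abort_format(sprintf("cannot infer image format from '%s'", path)))
}

#' Read a grayscale slice from disk
#'
#' Supported formats: PNG (8-bit grayscale) and NetPBM PGM (ASCII or
#' binary). Integer intensities round-trip losslessly. DICOM and TIFF
#' are recognised but unsupported in this build (no reader available
#' in the dependency footprint) and raise a typed error.
#'
#' @param path file path.
#' @param format `"auto"` (from the extension), `"png"` or `"pnm"`.
#' @param pixel_spacing_mm,slice_index optional metadata to attach.
#' @return a [grayscale_slice()].
#' @export
read_slice <- function(path, format = "auto", pixel_spacing_mm = NA_real_,
                       slice_index = NA_integer_) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  if (identical(format, "auto")) format <- guess_format(path)
  px <- switch(format,
    png = {
      img <- tryCatch(png::readPNG(path),
                      error = function(e) abort_format(conditionMessage(e)))
      if (length(dim(img)) == 3L) {
        if (dim(img)[3] >= 3L &&
            !(all(img[, , 1] == img[, , 2]) && all(img[, , 2] == img[, , 3])))
          abort_unsupported("RGB PNG given where a grayscale slice was expected")
        img <- img[, , 1]
      }
      round(img * 255)
    },
    pnm = {
      m <- read_pnm(path)
      if (!is.matrix(m))
        abort_unsupported("color PPM given where a grayscale slice was expected")
      m
    },
    dicom = abort_unsupported(
      "DICOM reading is not available in this build; convert to PNG/PGM first"),
    tiff = abort_unsupported(
      "TIFF reading is not available in this build; convert to PNG/PGM first"),
    abort_format(sprintf("unknown format '%s'", format))
  )
  grayscale_slice(px, pixel_spacing_mm = pixel_spacing_mm,
                  slice_index = slice_index)
}

#' Write a grayscale slice to disk
#'
#' @param slice a [grayscale_slice()].
#' @param path destination; format inferred from the extension unless
#'   given (`.png`, `.pgm`).
#' @param format `"auto"`, `"png"` or `"pnm"`.
#' @export
write_slice <- function(slice, path, format = "auto") {
  stopifnot(inherits(slice, "grayscale_slice"))
  if (identical(format, "auto")) format <- guess_format(path)
  if (format == "png") {
    if (max(slice$pixels) > 255)
      abort_format("PNG output supports 8-bit intensities only; use PGM")
    png::writePNG(slice$pixels / 255, path)
  } else if (format == "pnm") {
    write_pnm(slice$pixels, path)
  } else abort_format(sprintf("unsupported output format '%s'", format))
  invisible(path)
}

## ---- label-map encode/decode -------------------------------------------

#' Decode an RGB ground-truth image into a label map
#'
#' Each pixel is assigned the class of the nearest palette color
#' (black/green/blue/red, see [csvd_palette()]) by Euclidean distance
#' in RGB space. Hand-drawn annotations have lossy edges, hence the
#' default tolerance of 16 gray levels; pass `tolerance = 0` for an
#' exact-match mode.
#'
#' @param rgb HxWx3 array of 0-255 values (or a file path read with
#'   [read_labelmap()]).
#' @param tolerance maximum accepted RGB distance to the nearest
#'   palette color; farther pixels raise a decode error reporting the
#'   first offending coordinate.
#' @return a [label_map()].
#' @export
decode_labelmap <- function(rgb, tolerance = 16) {
  if (!(is.array(rgb) && length(dim(rgb)) == 3L && dim(rgb)[3] == 3L))
    abort_shape("decode_labelmap needs an HxWx3 RGB array")
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  flat <- cbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]),
                as.vector(rgb[, , 3]))
  pal <- csvd_palette()
  d2 <- sapply(1:4, function(k) {
    (flat[, 1] - pal[k, 1])^2 + (flat[, 2] - pal[k, 2])^2 +
      (flat[, 3] - pal[k, 3])^2
  })
  d2 <- matrix(d2, nrow = nrow(flat))
  best <- max.col(-d2, ties.method = "first")
  mind <- sqrt(d2[cbind(seq_len(nrow(d2)), best)])
  bad <- which(mind > tolerance)
  if (length(bad)) {
    r <- ((bad[1] - 1L) %% h) + 1L
    c <- ((bad[1] - 1L) %/% h) + 1L
    abort_label_decode(sprintf(
      "pixel (%d, %d) with RGB (%g, %g, %g) is %.1f from the nearest palette color (tolerance %g); %d offending pixel(s)",
      r, c, rgb[r, c, 1], rgb[r, c, 2], rgb[r, c, 3], mind[bad[1]],
      tolerance, length(bad)))
  }
  label_map(matrix(best - 1L, h, w))
}

#' Encode a label map as an RGB image
#'
#' Inverse of [decode_labelmap()]: `decode_labelmap(encode_labelmap(m))`
#' is the identity for every valid map.
#'
#' @param map a [label_map()].
#' @return HxWx3 array of 0-255 values.
#' @export
encode_labelmap <- function(map) {
  stopifnot(inherits(map, "label_map"))
  pal <- csvd_palette()
  idx <- as.vector(map$classes) + 1L
  arr <- array(0, c(map$height, map$width, 3L))
  for (k in 1:3) arr[, , k] <- matrix(pal[idx, k], map$height, map$width)
  arr
}

#' Read / write label maps as RGB images
#'
#' @param path PNG or PPM file.
#' @param tolerance passed to [decode_labelmap()].
#' @return `read_labelmap()`: a [label_map()].
#' @export
read_labelmap <- function(path, tolerance = 16) {
  fmt <- guess_format(path)
  rgb <- if (fmt == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) != 3L || dim(img)[3] < 3L)
      abort_format("label-map PNG must be RGB")
    round(img[, , 1:3] * 255)
  } else if (fmt == "pnm") {
    a <- read_pnm(path)
    if (!is.array(a) || length(dim(a)) != 3L)
      abort_format("label-map PNM must be a color PPM")
    a
  } else abort_unsupported(sprintf("unsupported label-map format '%s'", fmt))
  decode_labelmap(rgb, tolerance = tolerance)
}

#' @param map a [label_map()].
#' @rdname read_labelmap
#' @export
write_labelmap <- function(map, path) {
  rgb <- encode_labelmap(map)
  fmt <- guess_format(path)
  if (fmt == "png") png::writePNG(rgb / 255, path)
  else if (fmt == "pnm") write_pnm(rgb, path, maxval = 255L)
  else abort_unsupported(sprintf("unsupported label-map format '%s'", fmt))
  invisible(path)
}

#' Render a diagnostic overlay
#'
#' Draws lesion-class pixels (style `"fill"`) or their 4-connected
#' boundary (style `"outline"`) in red over the grayscale background;
#' optionally tints normal-brain and central-brain classes.
#'
#' @param slice a [grayscale_slice()].
#' @param map a [label_map()] of the same dimensions.
#' @param style `"fill"` or `"outline"`.
#' @param tint also tint classes 1 (green) and 2 (blue) at 25% opacity.
#' @return HxWx3 array of 0-255 values, same spatial dimensions.
#' @export
render_overlay <- function(slice, map, style = c("fill", "outline"),
                           tint = FALSE) {
  style <- match.arg(style)
  stopifnot(inherits(slice, "grayscale_slice"), inherits(map, "label_map"))
  if (slice$height != map$height || slice$width != map$width)
    abort_shape("slice and label map dimensions differ")
  base <- pmin(slice$pixels, 255)
  out <- array(0, c(slice$height, slice$width, 3L))
  for (k in 1:3) out[, , k] <- base
  if (tint) {
    for (cls in c(1L, 2L)) {
      sel <- map$classes == cls
      if (!any(sel)) next
      col <- csvd_palette()[cls + 1L, ]
      for (k in 1:3)
        out[, , k][sel] <- 0.75 * base[sel] + 0.25 * col[k]
    }
  }
  les <- map$classes == 3L
  if (style == "outline" && any(les)) {
    pad <- rbind(FALSE, cbind(FALSE, les, FALSE), FALSE)
    i <- 2:(nrow(pad) - 1); j <- 2:(ncol(pad) - 1)
    interior <- pad[i - 1, j] & pad[i + 1, j] & pad[i, j - 1] & pad[i, j + 1]
    les <- les & !interior
  }
  if (any(les)) {
    out[, , 1][les] <- 255
    out[, , 2][les] <- 0
    out[, , 3][les] <- 0
  }
  out
}
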