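# Synthetic head phantom: a bright cranium ring around textured brain
# tissue with a dark central (ventricle-like) structure and a small
# number of hyperintense lesions, plus additive Gaussian noise. Every
# stage of the pipeline is testable against the phantom's exact
# ground truth. This is a pipeline-testing phantom, not an anatomical
# simulation: intensities are T1-like class means, noise is Gaussian
# (not Rician), and structures are discs/ellipses.

#' Phantom specification
#'
#' Default intensities follow the T1-like ordering skull > lesion >
#' brain > central > background. The pixel spacing defaults to a fixed
#' 256 mm field of view (`256 / image_size` mm per pixel: 0.5 mm at
#' the nominal 512), so lesion sizes stated in millimetres keep their
#' physical meaning when the raster is scaled down for fast tests.
#' Default lesion diameters are 2-14 mm, honoring the < 15 mm
#' small-vessel definition.
#'
#' @param image_size square image width in pixels (default 512).
#' @param skull_outer_radius_frac outer cranium radius as a fraction
#'   of `image_size`.
#' @param skull_thickness_px ring thickness; default scales with the
#'   raster (`max(2, round(0.035 * image_size))`).
#' @param gap_px dark CSF-like gap between the ring and the brain
#'   disk; default `max(2, round(0.02 * image_size))`.
#' @param background_intensity,central_intensity,brain_intensity,lesion_intensity,skull_intensity
#'   class mean gray levels in `[0, 255]`.
#' @param noise_sigma additive Gaussian noise scale.
#' @param lesion_count_range inclusive (min, max) lesions per slice.
#' @param lesion_diameter_mm_range lesion diameter range in mm;
#'   must stay below 15.
#' @param edge_softness lesion edge taper as a fraction of the lesion
#'   radius (0 = hard disk).
#' @param pixel_spacing_mm mm per pixel; default `256 / image_size`.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 512L,
                         skull_outer_radius_frac = 0.46,
                         skull_thickness_px = NULL,
                         gap_px = NULL,
                         background_intensity = 5,
                         central_intensity = 60,
                         brain_intensity = 120,
                         lesion_intensity = 200,
                         skull_intensity = 230,
                         noise_sigma = 8,
                         lesion_count_range = c(0L, 4L),
                         lesion_diameter_mm_range = c(2, 14),
                         edge_softness = 0.3,
                         pixel_spacing_mm = NULL) {
  image_size <- as.integer(image_size)
  if (image_size < 32L) abort_config("phantom image_size must be >= 32")
  if (is.null(skull_thickness_px))
    skull_thickness_px <- max(2L, round(0.035 * image_size))
  if (is.null(gap_px)) gap_px <- max(2L, round(0.02 * image_size))
  if (is.null(pixel_spacing_mm)) pixel_spacing_mm <- 256 / image_size
  ints <- c(background_intensity, central_intensity, brain_intensity,
            lesion_intensity, skull_intensity)
  if (any(ints < 0 | ints > 255))
    abort_config("intensity means must lie in [0, 255]")
  if (!(skull_intensity > lesion_intensity &&
        lesion_intensity > brain_intensity &&
        brain_intensity > central_intensity &&
        central_intensity > background_intensity))
    abort_config("need skull > lesion > brain > central > background")
  if (lesion_diameter_mm_range[2] >= 15)
    abort_config("lesion diameters must stay < 15 mm (small-vessel definition)")
  if (lesion_count_range[1] < 0 ||
      lesion_count_range[2] < lesion_count_range[1])
    abort_config("bad lesion_count_range")
  r_out <- skull_outer_radius_frac * image_size
  if (r_out + 1 > image_size / 2)
    abort_config("skull ring does not fit in the image")
  if (r_out - skull_thickness_px - gap_px < image_size / 8)
    abort_config("ring/gap leave no room for the brain disk")
  structure(list(image_size = image_size,
                 skull_outer_radius_frac = skull_outer_radius_frac,
                 skull_thickness_px = skull_thickness_px,
                 gap_px = gap_px,
                 background_intensity = background_intensity,
                 central_intensity = central_intensity,
                 brain_intensity = brain_intensity,
                 lesion_intensity = lesion_intensity,
                 skull_intensity = skull_intensity,
                 noise_sigma = noise_sigma,
                 lesion_count_range = as.integer(lesion_count_range),
                 lesion_diameter_mm_range = lesion_diameter_mm_range,
                 edge_softness = edge_softness,
                 pixel_spacing_mm = pixel_spacing_mm),
            class = "phantom_spec")
}

#' Deterministic phantom geometry
#'
#' Centre and radii (in pixels) implied by a spec: cranium outer and
#' inner radii, brain-disk radius and the central-ellipse semi-axes.
#'
#' @param spec a [phantom_spec()].
#' @return list with `center`, `r_outer`, `r_inner`, `r_brain`,
#'   `central_axes` (row, col semi-axes).
#' @export
phantom_geometry <- function(spec) {
  ctr <- (spec$image_size + 1) / 2
  r_outer <- spec$skull_outer_radius_frac * spec$image_size
  r_inner <- r_outer - spec$skull_thickness_px
  r_brain <- r_inner - spec$gap_px
  list(center = c(row = ctr, col = ctr),
       r_outer = r_outer, r_inner = r_inner, r_brain = r_brain,
       central_axes = c(row = 0.32 * r_brain, col = 0.16 * r_brain))
}

#' Recommended brain-extraction threshold for phantom slices
#'
#' The phantom histogram has three masses (background, tissue,
#' cranium); Otsu's criterion splits off the large dark background
#' rather than the cranium, so extraction uses a fixed threshold at
#' the midpoint of the brain and skull means, which isolates the
#' bright ring (and lesions) as intended.
#'
#' @param spec a [phantom_spec()].
#' @return scalar threshold.
#' @export
phantom_extraction_threshold <- function(spec) {
  round((spec$brain_intensity + spec$skull_intensity) / 2)
}

#' Generate one phantom slice with ground truth
#'
#' Deterministic given `(spec, seed)`. Ground-truth classes: 0 for
#' background, cranium ring and the ring-brain gap (the 4-class
#' scheme has no separate skull class); 1 for brain tissue; 2 for the
#' central ellipse; 3 for lesion disks. Lesions are hyperintense
#' disks with a Gaussian-profile edge taper, placed uniformly inside
#' the brain disk, excluding the central structure, non-overlapping.
#' Intensity = class mean + Gaussian noise, clipped to `[0, 255]` and
#' rounded.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @param slice_index optional stack position stored on the slice.
#' @return list with `slice` (a [grayscale_slice()]), `truth` (a
#'   [label_map()]) and `lesions` (data frame of the planted centres,
#'   radii in px and diameters in mm).
#' @export
generate_slice <- function(spec, seed, slice_index = NA_integer_) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(as.integer(seed))
  sz <- spec$image_size
  geo <- phantom_geometry(spec)
  rr <- matrix(seq_len(sz), sz, sz) - geo$center[1]
  cc <- matrix(seq_len(sz), sz, sz, byrow = TRUE) - geo$center[2]
  d <- sqrt(rr^2 + cc^2)
  base <- matrix(spec$background_intensity, sz, sz)
  labels <- matrix(0L, sz, sz)
  base[d <= geo$r_outer & d > geo$r_inner] <- spec$skull_intensity
  brain <- d <= geo$r_brain
  base[brain] <- spec$brain_intensity
  labels[brain] <- 1L
  ell <- (rr / geo$central_axes[1])^2 + (cc / geo$central_axes[2])^2 <= 1
  base[ell & brain] <- spec$central_intensity
  labels[ell & brain] <- 2L

  counts <- seq(spec$lesion_count_range[1], spec$lesion_count_range[2])
  n_lesions <- if (length(counts) == 1L) counts else sample(counts, 1L)
  placed <- data.frame(row = numeric(0), col = numeric(0),
                       radius_px = numeric(0), diameter_mm = numeric(0))
  for (li in seq_len(n_lesions)) {
    ok <- FALSE
    for (try in seq_len(200L)) {
      diam_mm <- runif(1, spec$lesion_diameter_mm_range[1],
                       spec$lesion_diameter_mm_range[2])
      r_px <- max(0.6, diam_mm / 2 / spec$pixel_spacing_mm)
      rmax <- geo$r_brain - r_px - 2
      if (rmax <= 0) next
      ang <- runif(1, 0, 2 * pi)
      rad <- sqrt(runif(1)) * rmax
      pr <- geo$center[1] + rad * sin(ang)
      pc <- geo$center[2] + rad * cos(ang)
      # keep clear of the central ellipse (expanded by the radius)
      in_central <- ((pr - geo$center[1]) / (geo$central_axes[1] + r_px + 2))^2 +
        ((pc - geo$center[2]) / (geo$central_axes[2] + r_px + 2))^2 <= 1
      if (in_central) next
      if (nrow(placed) > 0) {
        dd <- sqrt((placed$row - pr)^2 + (placed$col - pc)^2)
        if (any(dd <= placed$radius_px + r_px + 2)) next
      }
      placed <- rbind(placed, data.frame(row = pr, col = pc,
                                         radius_px = r_px,
                                         diameter_mm = diam_mm))
      ok <- TRUE
      break
    }
    if (!ok)
      abort_placement(sprintf(
        "could not place lesion %d of %d after 200 attempts", li, n_lesions))
  }
  if (nrow(placed) > 0) {
    soft <- spec$edge_softness
    for (i in seq_len(nrow(placed))) {
      r_px <- placed$radius_px[i]
      w <- ceiling(r_px + 2 + soft * r_px + 2)
      rs <- max(1, floor(placed$row[i] - w)):min(sz, ceiling(placed$row[i] + w))
      cs <- max(1, floor(placed$col[i] - w)):min(sz, ceiling(placed$col[i] + w))
      dl <- sqrt(outer((rs - placed$row[i])^2, (cs - placed$col[i])^2, "+"))
      core <- dl <= r_px
      sub_lab <- labels[rs, cs]
      sub_base <- base[rs, cs]
      sub_base[core] <- spec$lesion_intensity
      sub_lab[core] <- 3L
      if (soft > 0) {
        scale <- soft * r_px + 0.5
        taper <- !core & sub_lab == 1L
        bump <- (spec$lesion_intensity - spec$brain_intensity) *
          exp(-((dl - r_px) / scale)^2)
        sub_base[taper] <- pmax(sub_base[taper],
                                spec$brain_intensity + bump[taper])
      }
      labels[rs, cs] <- sub_lab
      base[rs, cs] <- sub_base
    }
  }
  noisy <- base + rnorm(sz * sz, 0, spec$noise_sigma)
  noisy <- round(pmin(pmax(noisy, 0), 255))
  list(slice = grayscale_slice(noisy,
                               pixel_spacing_mm = spec$pixel_spacing_mm,
                               slice_index = slice_index),
       truth = label_map(labels),
       lesions = placed)
}

# Largest-remainder split of n into the 205/205/206 proportions.
split_sizes <- function(n) {
  quota <- n * c(train = 205, val = 205, test = 206) / 616
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- quota - base
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  out <- as.integer(base)
  names(out) <- names(quota)
  out
}

#' Generate a phantom dataset with a stratified split
#'
#' Per-slice seeds are derived from the master seed, so the dataset is
#' fully reproducible. The train/validation/test split follows the
#' 205/205/206 proportions of the clinical setup (largest-remainder
#' rounding for other n), stratified so lesion-bearing slices are
#' proportionally represented in every part.
#'
#' @param spec a [phantom_spec()].
#' @param n_slices number of slices (>= 3).
#' @param seed master seed.
#' @return object of class `phantom_dataset`: `slices`, `truths`,
#'   `lesions` (lists), `split` (factor train/val/test), `spec`,
#'   `seed`.
#' @export
generate_dataset <- function(spec, n_slices, seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_slices <- as.integer(n_slices)
  if (n_slices < 3L) abort_config("need at least 3 slices")
  seed <- as.integer(seed)
  slice_seeds <- (seed + 7919 * seq_len(n_slices)) %% 2147483647L
  out <- lapply(seq_len(n_slices), function(i)
    generate_slice(spec, slice_seeds[i], slice_index = i))
  has_lesion <- vapply(out, function(o) nrow(o$lesions) > 0, logical(1))
  sizes <- split_sizes(n_slices)
  split <- character(n_slices)
  set.seed(seed)
  remaining <- sizes
  for (stratum in list(which(has_lesion), which(!has_lesion))) {
    if (!length(stratum)) next
    idx <- stratum[sample.int(length(stratum))]
    # stratum share of each part, capped by remaining capacity
    quota <- length(idx) * sizes / n_slices
    take <- pmin(floor(quota), remaining)
    short <- length(idx) - sum(take)
    while (short > 0) {
      room <- remaining - take
      k <- which.max(ifelse(room > 0, quota - take, -Inf))
      take[k] <- take[k] + 1
      short <- short - 1
    }
    lab <- rep(names(sizes), times = take)
    split[idx] <- lab
    remaining <- remaining - take
  }
  structure(list(slices = lapply(out, `[[`, "slice"),
                 truths = lapply(out, `[[`, "truth"),
                 lesions = lapply(out, `[[`, "lesions"),
                 split = factor(split, levels = c("train", "val", "test")),
                 spec = spec, seed = seed),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset: %d slices (%s), %dpx, seed %d>\n",
              length(x$slices),
              paste(table(x$split), collapse = "/"),
              x$spec$image_size, x$seed))
  invisible(x)
}

#' Build a labeled patch table from a phantom dataset
#'
#' Convenience used by training and the CLI: tiles every slice of the
#' requested split parts and assigns ground-truth patch labels.
#'
#' @param ds a [generate_dataset()] result.
#' @param parts subset of `c("train", "val", "test")`.
#' @param patch_size,rule passed to the tiling and labeling.
#' @return list with `patches` (matrix), `labels` (integer vector) and
#'   `slice_of` (source slice index per patch).
#' @export
phantom_patches <- function(ds, parts = "train", patch_size = 7L,
                            rule = "any_lesion") {
  stopifnot(inherits(ds, "phantom_dataset"))
  sel <- which(ds$split %in% parts)
  if (!length(sel)) abort_config("no slices in the requested parts")
  pl <- lapply(sel, function(i) {
    g <- patch_grid(ds$slices[[i]]$height, ds$slices[[i]]$width, patch_size)
    ps <- extract_patches(ds$slices[[i]], g)
    list(p = ps$patches,
         l = assign_patch_labels(ds$truths[[i]], g, rule),
         s = rep(i, nrow(ps$patches)))
  })
  list(patches = do.call(rbind, lapply(pl, `[[`, "p")),
       labels = unlist(lapply(pl, `[[`, "l")),
       slice_of = unlist(lapply(pl, `[[`, "s")))
}
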