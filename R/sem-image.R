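# SEM-style particle counting: global histogram thresholding, connected
# components, single/cluster classification with the cluster-of-3 rule or
# area division, and conversion to number density and surface mass density.

#' Image record
#'
#' Wraps an 8-bit grayscale pixel matrix with its spatial calibration.
#'
#' @param pixels Numeric matrix of gray levels in `[0, 255]`.
#' @param nm_per_px Calibration: physical size of one pixel in nm.
#' @param provenance Free-text origin (file name or synthetic seed).
#' @return An object of class `image_record`.
#' @export
image_record <- function(pixels, nm_per_px, provenance = "") {
  stopifnot(is.matrix(pixels), is.numeric(pixels), nm_per_px > 0)
  structure(list(pixels = pixels, nm_per_px = nm_per_px,
                 provenance = provenance),
            class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record> %d x %d px at %g nm/px (%.3g x %.3g um)\n",
              nrow(x$pixels), ncol(x$pixels), x$nm_per_px,
              nrow(x$pixels) * x$nm_per_px / 1e3,
              ncol(x$pixels) * x$nm_per_px / 1e3))
  invisible(x)
}

#' Field area of an image in mm^2
#' @param image An [image_record()].
#' @return Area in mm^2.
#' @export
field_area_mm2 <- function(image) {
  stopifnot(inherits(image, "image_record"))
  npx <- nrow(image$pixels) * ncol(image$pixels)
  npx * (image$nm_per_px * 1e-6)^2
}

#' Scale calibration from a scale bar
#'
#' @param scale_bar_px Length of the scale bar in pixels.
#' @param scale_bar_nm Physical length of the bar in nm.
#' @return nm per pixel.
#' @export
calibrate_scale <- function(scale_bar_px, scale_bar_nm) {
  stopifnot(is.numeric(scale_bar_px), is.numeric(scale_bar_nm))
  if (scale_bar_px <= 0 || scale_bar_nm <= 0) {
    stop("scale bar lengths must be positive", call. = FALSE)
  }
  scale_bar_nm / scale_bar_px
}

#' Global threshold from the histogram's background peak
#'
#' Locates the most prominent peak of the smoothed 256-bin gray-level
#' histogram (the dark background in an SEM image of bright particles) and
#' returns the first gray level on its bright side where the smoothed count
#' falls below a fraction `f` of the peak count — i.e. a cut on the
#' descending flank of the background peak. Deterministic.
#'
#' @param image An [image_record()] or a numeric pixel matrix in `[0, 255]`.
#' @param f Fraction of the peak count defining the cut (default 0.01).
#' @param window Moving-average smoothing window in bins (default 5).
#' @return Threshold gray level (pixels strictly above it are foreground).
#' @export
histogram_threshold <- function(image, f = 0.01, window = 5) {
  px <- if (inherits(image, "image_record")) image$pixels else image
  stopifnot(is.numeric(px), f > 0, f < 1, window >= 1)
  g <- pmin(pmax(round(px), 0), 255)
  counts <- tabulate(as.integer(g) + 1L, nbins = 256L)
  if (sum(counts > 0) < 2) {
    stop("degenerate histogram: fewer than 2 occupied gray levels", call. = FALSE)
  }
  k <- rep(1 / window, window)
  smoothed <- stats::filter(counts, k, sides = 2)
  smoothed[is.na(smoothed)] <- counts[is.na(smoothed)]
  smoothed <- as.numeric(smoothed)
  peak <- which.max(smoothed)
  cut <- f * smoothed[peak]
  above <- which(seq_along(smoothed) > peak & smoothed < cut)
  if (length(above) == 0) {
    stop("no descending crossing found on the bright side of the background peak",
         call. = FALSE)
  }
  min(above) - 1L   # gray level (bins are 0-based)
}

#' Binary foreground mask from an image
#'
#' @param image An [image_record()] or pixel matrix.
#' @param threshold Gray level; defaults to [histogram_threshold()].
#' @param ... Passed to [histogram_threshold()].
#' @return Logical matrix, `TRUE` for foreground.
#' @export
threshold_mask <- function(image, threshold = NULL, ...) {
  px <- if (inherits(image, "image_record")) image$pixels else image
  if (is.null(threshold)) threshold <- histogram_threshold(px, ...)
  px > threshold
}

#' Count particles in a binary mask
#'
#' Labels connected components and classifies them against the expected
#' single-particle area `A1 = pi (expected_diameter_px / 2)^2`:
#' a component is a *single* if its area lies in `area_band * A1`
#' (default `[0.5, 1.5]`) and its circularity `4 pi A / P^2` is at least
#' `circularity` (default 0.75). In `detached` mode, non-single components
#' with area in `(1.5, 4.5] * A1` are small clusters counted as exactly 3
#' particles and anything larger is a large cluster counted by area
#' division; in `clustered` mode every non-single component contributes
#' `round(area / A1)` particles. Components below `0.5 * A1` are discarded
#' as noise. `auto` picks `clustered` when more than half of the foreground
#' area lies in non-single components. Edge objects are included
#' (plus-sampling): with equal-size particles this introduces no
#' size-dependent bias.
#'
#' @param mask Logical (or 0/1) matrix from [threshold_mask()].
#' @param expected_diameter_px Expected particle diameter in pixels (>= 4).
#' @param mode `"detached"`, `"clustered"` or `"auto"`.
#' @param area_band Relative area band for singles (default `c(0.5, 1.5)`).
#' @param circularity Minimum circularity for singles (default 0.75).
#' @return A list of class `image_counts`: `n_singles`,
#'   `n_small_clusters`, `n_large_clusters`, `particles_total`, `mode`,
#'   and a tibble `components` (area, perimeter, circularity, class, count).
#' @export
detect_particles <- function(mask, expected_diameter_px,
                             mode = c("detached", "clustered", "auto"),
                             area_band = c(0.5, 1.5), circularity = 0.75) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(mask))
  if (expected_diameter_px < 4) {
    stop("`expected_diameter_px` must be at least 4 px; check the scale calibration",
         call. = FALSE)
  }
  m <- matrix(as.numeric(mask), nrow = nrow(mask))
  a1 <- pi * (expected_diameter_px / 2)^2

  empty <- function(md) {
    structure(list(n_singles = 0L, n_small_clusters = 0L,
                   n_large_clusters = 0L, particles_total = 0L, mode = md,
                   components = tibble::tibble(area = numeric(),
                                               perimeter = numeric(),
                                               circularity = numeric(),
                                               class = character(),
                                               count = integer())),
              class = "image_counts")
  }
  if (!any(m > 0)) return(empty(mode))

  labels <- EBImage::bwlabel(m)
  shp <- EBImage::computeFeatures.shape(labels)
  if (is.null(shp) || nrow(shp) == 0) return(empty(mode))
  area <- shp[, "s.area"]
  per <- pmax(shp[, "s.perimeter"], 1)
  circ <- 4 * pi * area / per^2

  keep <- area >= area_band[1] * a1
  area <- area[keep]; circ <- circ[keep]; per <- per[keep]
  if (length(area) == 0) return(empty(mode))

  is_single <- area <= area_band[2] * a1 & circ >= circularity

  if (mode == "auto") {
    frac_nonsingle <- sum(area[!is_single]) / sum(area)
    mode <- if (frac_nonsingle > 0.5) "clustered" else "detached"
  }

  cls <- character(length(area))
  cnt <- integer(length(area))
  cls[is_single] <- "single"
  cnt[is_single] <- 1L
  ns <- !is_single
  if (mode == "detached") {
    small <- ns & area <= 4.5 * a1
    large <- ns & area > 4.5 * a1
    cls[small] <- "small_cluster"; cnt[small] <- 3L
    cls[large] <- "large_cluster"; cnt[large] <- as.integer(round(area[large] / a1))
  } else {
    cls[ns] <- ifelse(area[ns] <= 4.5 * a1, "small_cluster", "large_cluster")
    cnt[ns] <- pmax(1L, as.integer(round(area[ns] / a1)))
  }

  structure(
    list(n_singles = sum(cls == "single"),
         n_small_clusters = sum(cls == "small_cluster"),
         n_large_clusters = sum(cls == "large_cluster"),
         particles_total = sum(cnt),
         mode = mode,
         components = tibble::tibble(area = area, perimeter = per,
                                     circularity = circ, class = cls,
                                     count = cnt)),
    class = "image_counts")
}

#' @export
print.image_counts <- function(x, ...) {
  cat(sprintf("<image_counts> %d particles (%d singles, %d small clusters, %d large clusters), mode = %s\n",
              x$particles_total, x$n_singles, x$n_small_clusters,
              x$n_large_clusters, x$mode))
  invisible(x)
}

#' Particle number density of a counted image
#'
#' @param counts An [detect_particles()] result (or a particle count).
#' @param image An [image_record()] supplying the field area, or a field
#'   area in mm^2.
#' @return Particles per mm^2.
#' @export
particle_density <- function(counts, image) {
  n <- if (inherits(counts, "image_counts")) counts$particles_total else counts
  area <- if (inherits(image, "image_record")) field_area_mm2(image) else image
  stopifnot(area > 0)
  n / area
}

#' Surface mass density from a number density
#'
#' `Gamma = density * m`, with the density converted from per mm^2 to per
#' cm^2 (factor 100).
#'
#' @param density_mm2 Particle number density in mm^-2.
#' @param m Single-particle mass in ng.
#' @return Surface mass density in ng cm^-2.
#' @export
surface_mass_density <- function(density_mm2, m) {
  stopifnot(is.numeric(density_mm2), all(density_mm2 >= 0), m > 0)
  density_mm2 * 100 * m
}

#' Peak-normalised area under an intensity profile
#'
#' Scales a cross-section intensity profile by its maximum and integrates
#' it by the trapezoid rule with step `dx`. Used to compare penetration
#' depths of particle fluorescence into a hydrogel network.
#'
#' @param profile Intensity values along the profile.
#' @param dx Sampling step in nm (default 400).
#' @return Dimensionless area (nm x normalised intensity).
#' @export
normalized_profile_auc <- function(profile, dx = 400) {
  stopifnot(is.numeric(profile), length(profile) >= 2, dx > 0)
  peak <- max(profile)
  if (peak <= 0) stop("profile has no positive peak", call. = FALSE)
  x <- (seq_along(profile) - 1) * dx
  pracma::trapz(x, profile / peak)
}

#' Read an 8-bit grayscale SEM-style image
#'
#' Reads PNG or TIFF into an [image_record()]; multi-channel images are
#' averaged to gray. Requires the `png` or `tiff` package for the
#' respective format.
#'
#' @param path Image file path.
#' @param nm_per_px Scale calibration.
#' @return An [image_record()].
#' @export
read_sem_image <- function(path, nm_per_px) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(arr)) == 3) arr <- apply(arr, c(1, 2), mean)
  image_record(round(arr * 255), nm_per_px, provenance = path)
}

#' Write an image record as PNG
#'
#' @param image An [image_record()].
#' @param path Output path (.png).
#' @return `path` invisibly.
#' @export
write_sem_image <- function(image, path) {
  stopifnot(inherits(image, "image_record"))
  png::writePNG(pmin(pmax(image$pixels / 255, 0), 1), path)
  invisible(path)
}
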