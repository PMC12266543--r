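#' Disk median filter of a B-scan
#'
#' Replaces each pixel by the median over a disk-shaped neighbourhood
#' (Euclidean distance <= `radius` pixels), the standard despeckling step
#' for OCT B-scans. Borders are handled by symmetric (reflect) padding.
#'
#' @param image 2D numeric matrix (one B-scan).
#' @param radius Structuring-element radius in pixels (>= 1).
#' @return Filtered matrix of the same shape.
#' @export
median_filter_bscan <- function(image, radius = 5) {
  if (!is.matrix(image) || length(image) == 0) {
    stop_biofilmq("`image` must be a non-empty matrix",
                  "biofilmq_validation_error")
  }
  radius <- as.integer(radius)
  if (radius < 1L) {
    stop_biofilmq("`radius` must be >= 1", "biofilmq_validation_error")
  }
  disk_median_cpp(image, radius)
}

#' Global Otsu threshold of an intensity sample
#'
#' Exhaustive maximization of the between-class variance of the intensity
#' histogram over all cut points. Continuous data are binned into `nbins`
#' equal-width bins over the data range; integer data with at most `nbins`
#' distinct levels are binned at their native levels. Among equally optimal
#' cuts the lowest is returned.
#'
#' @param x Numeric vector (or array) of intensities.
#' @param nbins Number of histogram bins for continuous data.
#' @return Threshold value: the upper edge of the last bin assigned to the
#'   background class; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(x, nbins = 256) {
  x <- as.vector(x)
  x <- x[is.finite(x)]
  ux <- unique(x)
  if (length(ux) < 2L) {
    stop_biofilmq("degenerate histogram: intensities are constant",
                  "biofilmq_degenerate_histogram_error")
  }
  if (length(ux) <= nbins && all(x == round(x))) {
    lev <- sort(ux)
    counts <- tabulate(match(x, lev))
    mids <- lev
    # report the cut midway between the last background level and the next,
    # so the threshold lies strictly between the separated classes
    levels <- (lev[-length(lev)] + lev[-1]) / 2
    levels <- c(levels, lev[length(lev)])
  } else {
    rng <- range(x)
    edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
    bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
                nbins)
    counts <- tabulate(bin, nbins)
    mids <- (edges[-1] + edges[-(nbins + 1L)]) / 2
    levels <- edges[-1]  # threshold reported at upper bin edge
  }
  n <- sum(counts)
  w0 <- cumsum(counts) / n
  mu <- cumsum(counts * mids) / n
  mu_t <- mu[length(mu)]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, length(counts))
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  k <- which.max(sigma_b)
  levels[k]
}

#' Select a global segmentation threshold for an OCT volume
#'
#' @param volume An `oct_volume`.
#' @param method `"otsu"` (between-class variance maximization on the
#'   full-volume histogram) or `"fixed"`.
#' @param fixed_value Threshold to use when `method = "fixed"`.
#' @param nbins Histogram bins for Otsu on continuous data.
#' @return A single intensity threshold.
#' @export
select_threshold <- function(volume, method = c("otsu", "fixed"),
                             fixed_value = NULL, nbins = 256) {
  method <- match.arg(method)
  stopifnot(inherits(volume, "oct_volume"))
  if (method == "fixed") {
    if (is.null(fixed_value)) {
      stop_biofilmq("method = \"fixed\" requires `fixed_value`",
                    "biofilmq_validation_error")
    }
    return(fixed_value)
  }
  otsu_threshold(volume$intensities, nbins = nbins)
}

#' Threshold segmentation of an OCT volume
#'
#' @param volume An `oct_volume` (typically median-filtered).
#' @param threshold Intensity threshold; voxels strictly above it are
#'   foreground.
#' @return Logical 3D array.
#' @export
segment_volume <- function(volume, threshold) {
  stopifnot(inherits(volume, "oct_volume"), is.finite(threshold))
  volume$intensities > threshold
}

#' Per-column thickness map and mean thickness from a binary mask
#'
#' For each lateral column (A-scan), the thickness is the count of
#' foreground voxels along depth times the axial resolution. The mean is
#' taken over all columns, with zero-foreground columns included as 0.
#'
#' @param mask Logical 3D array (lateral_x, lateral_y, depth).
#' @param axial_resolution Axial voxel size in um.
#' @param threshold_used Optional intensity threshold to record in the
#'   result.
#' @return An object of class `thickness_result`: `thickness_map` (um
#'   matrix), `mean_thickness` (um), `threshold_used`, `n_columns`,
#'   `n_foreground_voxels`.
#' @export
thickness_map <- function(mask, axial_resolution, threshold_used = NA_real_) {
  if (!is.logical(mask) || length(dim(mask)) != 3L) {
    stop_biofilmq("`mask` must be a logical 3D array",
                  "biofilmq_validation_error")
  }
  check_positive_scalar(axial_resolution, "axial_resolution")
  counts <- apply(mask, c(1, 2), sum)
  tmap <- counts * axial_resolution
  structure(
    list(thickness_map = tmap,
         mean_thickness = mean(tmap),
         threshold_used = threshold_used,
         n_columns = length(tmap),
         n_foreground_voxels = sum(counts)),
    class = "thickness_result")
}

#' @export
print.thickness_result <- function(x, ...) {
  cat(sprintf(
    "OCT thickness: mean %.2f um over %d columns (%d foreground voxels, threshold %.4g)\n",
    x$mean_thickness, x$n_columns, x$n_foreground_voxels, x$threshold_used))
  invisible(x)
}

#' Quantify mean biofilm thickness from an OCT volume
#'
#' Full quantification chain: per-B-scan disk median filtering, global
#' intensity threshold selection, threshold segmentation, and per-column
#' voxel counting scaled by the axial resolution. A volume of constant
#' intensity (no signal at all) yields zero thickness with the constant as
#' the recorded threshold.
#'
#' @param volume An `oct_volume`.
#' @param radius Median-filter disk radius in pixels.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_value Threshold when `threshold_method = "fixed"`.
#' @param nbins Histogram bins for Otsu.
#' @return A `thickness_result` (see [thickness_map()]); `filter_radius`
#'   and `threshold_method` are recorded in the result.
#' @examples
#' sim <- gen_oct_volume(c(32, 32, 64), mean_thickness = 20,
#'                       noise_model = "none", seed = 1)
#' quantify_oct(sim$volume)
#' @export
quantify_oct <- function(volume, radius = 5,
                         threshold_method = c("otsu", "fixed"),
                         fixed_value = NULL, nbins = 256) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(inherits(volume, "oct_volume"))
  vol <- volume$intensities
  filtered <- vol
  for (j in seq_len(dim(vol)[2])) {
    filtered[, j, ] <- median_filter_bscan(vol[, j, ], radius = radius)
  }
  fvol <- new_oct_volume(filtered, volume$voxel_size, volume$provenance)
  threshold <- if (threshold_method == "fixed") {
    select_threshold(fvol, "fixed", fixed_value = fixed_value)
  } else if (length(unique(as.vector(filtered))) < 2L) {
    max(filtered)  # signal-free volume: nothing exceeds the constant
  } else {
    select_threshold(fvol, "otsu", nbins = nbins)
  }
  mask <- segment_volume(fvol, threshold)
  res <- thickness_map(mask, axial_resolution = volume$voxel_size[3],
                       threshold_used = threshold)
  res$filter_radius <- radius
  res$threshold_method <- threshold_method
  res
}
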