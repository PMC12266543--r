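# Lightweight S3 containers for the imaging data types.

#' Construct an OCT volume
#'
#' A 3D intensity array with anisotropic voxel sizes. The depth (axial) axis
#' is the third array dimension; the first two are lateral.
#'
#' @param intensities Nonnegative 3D numeric array
#'   (lateral_x, lateral_y, depth).
#' @param voxel_size Numeric length-3 (x, y, axial) in um, all positive.
#' @param provenance Free-text source tag.
#' @return An object of class `oct_volume`.
#' @export
new_oct_volume <- function(intensities, voxel_size = oct_default_voxel_size(),
                           provenance = "") {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    stop_biofilmq("`intensities` must be a 3D array", "biofilmq_validation_error")
  }
  if (any(intensities < 0)) {
    stop_biofilmq("intensities must be >= 0", "biofilmq_validation_error")
  }
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop_biofilmq("`voxel_size` must be three positive numbers",
                  "biofilmq_validation_error")
  }
  structure(list(intensities = intensities,
                 voxel_size = as.numeric(voxel_size),
                 provenance = provenance),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("OCT volume: %d x %d lateral x %d depth voxels (%g x %g x %g um)\n",
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Construct a confocal z-stack
#'
#' An ordered list of equally sized 2D intensity slices with pixel size and
#' inter-slice spacing. Slice spacing carries no default: it is a physical
#' acquisition constant that must be supplied with the data.
#'
#' @param slices List of numeric matrices, all the same shape.
#' @param pixel_size Pixel edge length in um (> 0).
#' @param slice_spacing Inter-slice spacing in um (> 0).
#' @return An object of class `clsm_stack`.
#' @export
new_clsm_stack <- function(slices, pixel_size, slice_spacing) {
  if (!is.list(slices) || length(slices) < 1L) {
    stop_biofilmq("`slices` must be a non-empty list of matrices",
                  "biofilmq_validation_error")
  }
  dims <- lapply(slices, dim)
  if (any(vapply(dims, is.null, logical(1))) ||
      length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop_biofilmq("all slices must be matrices of identical shape",
                  "biofilmq_validation_error")
  }
  if (prod(dims[[1]]) == 0) {
    stop_biofilmq("slices must be non-empty", "biofilmq_validation_error")
  }
  check_positive_scalar(pixel_size, "pixel_size")
  check_positive_scalar(slice_spacing, "slice_spacing")
  structure(list(slices = slices, pixel_size = pixel_size,
                 slice_spacing = slice_spacing),
            class = "clsm_stack")
}

#' Construct a co-registered green/red ratio image pair
#'
#' @param green,red Nonnegative numeric matrices of identical shape: green
#'   (576-608 nm band) and red (629-661 nm band) emission images.
#' @param pixel_size Pixel size in um.
#' @return An object of class `ratio_image_pair`.
#' @export
new_ratio_image_pair <- function(green, red,
                                 pixel_size = clsm_default_pixel_size()) {
  if (!is.matrix(green) || !is.matrix(red) ||
      !identical(dim(green), dim(red))) {
    stop_biofilmq("`green` and `red` must be matrices of identical shape",
                  "biofilmq_validation_error")
  }
  if (any(green < 0) || any(red < 0)) {
    stop_biofilmq("channel intensities must be >= 0",
                  "biofilmq_validation_error")
  }
  check_positive_scalar(pixel_size, "pixel_size")
  structure(list(green = green, red = red, pixel_size = pixel_size),
            class = "ratio_image_pair")
}
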