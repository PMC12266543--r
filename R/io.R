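# Reading and writing the pipeline's on-disk formats: multi-page TIFF with
# JSON sidecars for imaging data, CSV for calibration and trial tables.
# TIFF payloads are 16-bit; the sidecar records the intensity scale so
# arbitrary-range intensities round-trip to within quantization.

#' Write / read an OCT volume as multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per B-scan (constant lateral-y index); the sidecar stores
#' `voxel_size_um`, `depth_axis` and the intensity scale used for 16-bit
#' encoding.
#'
#' @param volume An `oct_volume`.
#' @param path TIFF file path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `write_oct_tiff()` returns `path` invisibly; `read_oct_tiff()`
#'   returns an `oct_volume`.
#' @export
write_oct_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  vol <- volume$intensities
  scale <- max(vol, 1e-12)
  pages <- lapply(seq_len(dim(vol)[2]),
                  function(j) vol[, j, , drop = TRUE] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(
    list(voxel_size_um = volume$voxel_size,
         depth_axis = "page-column",
         intensity_scale = scale,
         provenance = volume$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_oct_tiff
#' @param path TIFF file path written by [write_oct_tiff()].
#' @export
read_oct_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- dim(pages[[1]])
  vol <- array(0, dim = c(d[1], length(pages), d[2]))
  for (j in seq_along(pages)) vol[, j, ] <- pages[[j]]
  new_oct_volume(vol * meta$intensity_scale,
                 voxel_size = meta$voxel_size_um,
                 provenance = meta$provenance %||% "")
}

#' Write / read a confocal z-stack as multi-page TIFF with a JSON sidecar
#'
#' @param stack A `clsm_stack`.
#' @param path TIFF file path; sidecar at `<path>.json` stores
#'   `pixel_size_um`, `slice_spacing_um`, and the intensity scale.
#' @export
write_clsm_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "clsm_stack"))
  scale <- max(unlist(stack$slices), 1e-12)
  tiff::writeTIFF(lapply(stack$slices, function(s) s / scale), path,
                  bits.per.sample = 16)
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size,
         slice_spacing_um = stack$slice_spacing,
         intensity_scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_clsm_tiff
#' @export
read_clsm_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  new_clsm_stack(lapply(pages, function(p) p * meta$intensity_scale),
                 pixel_size = meta$pixel_size_um,
                 slice_spacing = meta$slice_spacing_um)
}

#' Write / read a ratiometric image pair as two TIFFs with a JSON sidecar
#'
#' Channels go to `<stem>_green.tif` and `<stem>_red.tif`; the sidecar
#' `<stem>.json` stores `pixel_size_um` and the shared intensity scale.
#'
#' @param pair A `ratio_image_pair`.
#' @param stem Path stem (no extension).
#' @export
write_ratio_pair_tiff <- function(pair, stem) {
  stopifnot(inherits(pair, "ratio_image_pair"))
  scale <- max(pair$green, pair$red, 1e-12)
  tiff::writeTIFF(pair$green / scale, paste0(stem, "_green.tif"),
                  bits.per.sample = 16)
  tiff::writeTIFF(pair$red / scale, paste0(stem, "_red.tif"),
                  bits.per.sample = 16)
  jsonlite::write_json(
    list(pixel_size_um = pair$pixel_size, intensity_scale = scale),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_ratio_pair_tiff
#' @export
read_ratio_pair_tiff <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  g <- tiff::readTIFF(paste0(stem, "_green.tif"))
  r <- tiff::readTIFF(paste0(stem, "_red.tif"))
  new_ratio_image_pair(g * meta$intensity_scale, r * meta$intensity_scale,
                       pixel_size = meta$pixel_size_um)
}

#' Read / write calibration and trial CSV tables
#'
#' `calibration.csv` has columns `pH,ratio`; `trial.csv` has columns
#' `participant,period,treatment,biofilm_id,outcome,pre_value` (`pre_value`
#' may be empty).
#'
#' @param table Data frame to write.
#' @param path CSV file path.
#' @export
write_calibration_csv <- function(table, path) {
  stopifnot(all(c("pH", "ratio") %in% names(table)))
  write.csv(table[, c("pH", "ratio")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  tab <- read.csv(path)
  if (!all(c("pH", "ratio") %in% names(tab))) {
    stop_biofilmq("calibration CSV needs columns pH,ratio",
                  "biofilmq_validation_error")
  }
  tab
}

#' @rdname write_calibration_csv
#' @export
write_trial_csv <- function(table, path) {
  cols <- c("participant", "period", "treatment", "biofilm_id", "outcome",
            "pre_value")
  missing_cols <- setdiff(setdiff(cols, "pre_value"), names(table))
  if (length(missing_cols)) {
    stop_biofilmq(paste("trial table lacks columns:",
                        paste(missing_cols, collapse = ", ")),
                  "biofilmq_validation_error")
  }
  if (!"pre_value" %in% names(table)) table$pre_value <- NA_real_
  write.csv(table[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_trial_csv <- function(path) {
  tab <- read.csv(path)
  needed <- c("participant", "period", "treatment", "biofilm_id", "outcome")
  if (!all(needed %in% names(tab))) {
    stop_biofilmq("trial CSV lacks required columns",
                  "biofilmq_validation_error")
  }
  tab$treatment <- factor(tab$treatment, levels = c("control", "enzyme"))
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
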