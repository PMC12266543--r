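#' Default acquisition geometry constants
#'
#' Voxel and pixel sizes mirroring the study's acquisition geometry: OCT
#' voxels of 4 x 4 x 1.45 um (lateral x, lateral y, axial), and a confocal
#' pixel size of 101.61 um / 1192 px.
#'
#' @export
oct_default_voxel_size <- function() c(4, 4, 1.45)

#' @rdname oct_default_voxel_size
#' @export
clsm_default_pixel_size <- function() 101.61 / 1192

#' Simulate an OCT biofilm volume with known thickness ground truth
#'
#' Renders a surface-attached biofilm layer over dark background in a 3D
#' intensity volume. The biofilm height field is low-pass-filtered Gaussian
#' noise rescaled to the requested mean thickness and clipped at zero; it is
#' quantized to whole axial voxels before rendering, and the quantized field
#' is the recorded ground truth. The biofilm is attached at the first depth
#' index (the carrier surface at the top of the cropped scan).
#'
#' Speckle noise emulates coherent imaging with 3-frame scan averaging:
#' multiplicative gamma(shape 3, mean 1) noise on foreground voxels and
#' additive Gaussian noise (sd = `intensity_bg / 4`) on background.
#'
#' @param dims Integer vector (lateral_x, lateral_y, depth) in voxels.
#' @param mean_thickness Target mean biofilm thickness in um.
#' @param roughness Lateral correlation length of the height field in
#'   voxels (Gaussian smoothing sigma).
#' @param rel_sd Relative standard deviation of the height field around its
#'   mean (before clipping).
#' @param intensity_fg,intensity_bg Mean foreground / background intensity.
#' @param noise_model One of `"speckle"`, `"gaussian"`, `"none"`.
#' @param voxel_size Numeric length-3 (x, y, axial) voxel size in um.
#' @param seed Integer seed; the same seed reproduces the volume
#'   bit-for-bit.
#' @return List with `volume` (an `oct_volume`: `intensities` array,
#'   `voxel_size`, `provenance`) and `truth` (`height_field` um quantized,
#'   `mean_thickness` um, `voxel_size`).
#' @examples
#' sim <- gen_oct_volume(c(32, 32, 64), mean_thickness = 20, seed = 1)
#' sim$truth$mean_thickness
#' @export
gen_oct_volume <- function(dims = c(64, 64, 128),
                           mean_thickness,
                           roughness = 8,
                           rel_sd = 0.25,
                           intensity_fg = 100,
                           intensity_bg = 10,
                           noise_model = c("speckle", "gaussian", "none"),
                           voxel_size = oct_default_voxel_size(),
                           seed) {
  noise_model <- match.arg(noise_model)
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) {
    stop_biofilmq("`dims` must be three positive integers",
                  "biofilmq_validation_error")
  }
  if (intensity_fg <= intensity_bg) {
    stop_biofilmq("`intensity_fg` must exceed `intensity_bg`",
                  "biofilmq_validation_error")
  }
  axial <- voxel_size[3]
  if (mean_thickness < 0 || mean_thickness > dims[3] * axial) {
    stop_biofilmq(sprintf(
      "mean_thickness %.3g um does not fit the axial extent %.3g um",
      mean_thickness, dims[3] * axial), "biofilmq_sizing_error")
  }
  local_seed(seed, {
    if (mean_thickness == 0) {
      nvox <- matrix(0L, dims[1], dims[2])
    } else {
      z <- gaussian_smooth2d(matrix(rnorm(dims[1] * dims[2]), dims[1], dims[2]),
                             sigma = roughness)
      z <- (z - mean(z)) / max(sd(as.vector(z)), 1e-12)
      h <- pmax(0, mean_thickness * (1 + rel_sd * z))
      h <- h * (mean_thickness / mean(h))
      nvox <- matrix(pmin(as.integer(round(h / axial)), dims[3]),
                     dims[1], dims[2])
    }
    vol <- array(intensity_bg, dim = dims)
    ncol_lat <- dims[1] * dims[2]
    zarr <- array(rep(seq_len(dims[3]), each = ncol_lat), dim = dims)
    fg <- zarr <= array(nvox, dim = dims)
    vol[fg] <- intensity_fg
    if (noise_model == "speckle") {
      nfg <- sum(fg)
      if (nfg > 0) vol[fg] <- vol[fg] * rgamma(nfg, shape = 3, rate = 3)
      vol[!fg] <- pmax(0, vol[!fg] + rnorm(sum(!fg), sd = intensity_bg / 4))
    } else if (noise_model == "gaussian") {
      vol[] <- pmax(0, vol + rnorm(length(vol), sd = intensity_bg / 2))
    }
    volume <- new_oct_volume(vol, voxel_size, provenance = "synthetic")
    truth <- list(height_field = nvox * axial,
                  mean_thickness = mean(nvox) * axial,
                  voxel_size = voxel_size)
    list(volume = volume, truth = truth)
  })
}

#' Simulate a sparse confocal z-stack with known biovolume
#'
#' Each slice contains bright disk-shaped cell clusters on dark background;
#' the number of disks per slice is Poisson with mean
#' `object_density * field area`. Ground-truth per-slice bacterial area is
#' the rendered object pixel count times the pixel area, and the true
#' biovolume is the Cavalieri sum of slice areas times slice spacing.
#'
#' @param dims Integer (rows, cols) image size in pixels.
#' @param n_slices Number of z-slices (the study acquired 3).
#' @param object_density Expected cell clusters per um^2.
#' @param object_radius_px Disk radius in pixels.
#' @param pixel_size Pixel edge length in um.
#' @param slice_spacing Inter-slice spacing in um.
#' @param intensity_fg,intensity_bg Foreground / background intensity.
#' @param noise_sd Additive Gaussian intensity noise SD (0 = noiseless).
#' @param seed Integer seed.
#' @return List with `stack` (a `clsm_stack`: `slices` list of matrices,
#'   `pixel_size`, `slice_spacing`) and `truth` (`slice_areas` um^2,
#'   `slice_spacing`, `true_biovolume` um^3, `object_masks`).
#' @export
gen_clsm_stack <- function(dims = c(256, 256),
                           n_slices = 3,
                           object_density = 0.02,
                           object_radius_px = 6,
                           pixel_size = clsm_default_pixel_size(),
                           slice_spacing = 2,
                           intensity_fg = 200,
                           intensity_bg = 10,
                           noise_sd = 0,
                           seed) {
  dims <- as.integer(dims)
  if (length(dims) != 2L || any(dims < 1L)) {
    stop_biofilmq("`dims` must be two positive integers",
                  "biofilmq_validation_error")
  }
  if (n_slices < 1) {
    stop_biofilmq("`n_slices` must be >= 1", "biofilmq_validation_error")
  }
  check_positive_scalar(pixel_size, "pixel_size")
  check_positive_scalar(slice_spacing, "slice_spacing")
  local_seed(seed, {
    area_um2 <- prod(dims) * pixel_size^2
    slices <- vector("list", n_slices)
    masks <- vector("list", n_slices)
    areas <- numeric(n_slices)
    for (s in seq_len(n_slices)) {
      n_obj <- if (object_density > 0) rpois(1, object_density * area_um2) else 0L
      mask <- if (n_obj > 0) {
        render_disks(dims[1], dims[2],
                     cx = runif(n_obj, 1, dims[1]),
                     cy = runif(n_obj, 1, dims[2]),
                     radius = object_radius_px)
      } else {
        matrix(FALSE, dims[1], dims[2])
      }
      img <- matrix(intensity_bg, dims[1], dims[2])
      img[mask] <- intensity_fg
      if (noise_sd > 0) {
        img <- pmax(img + rnorm(length(img), sd = noise_sd), 0)
      }
      slices[[s]] <- img
      masks[[s]] <- mask
      areas[s] <- sum(mask) * pixel_size^2
    }
    stack <- new_clsm_stack(slices, pixel_size, slice_spacing)
    truth <- list(slice_areas = areas,
                  slice_spacing = slice_spacing,
                  true_biovolume = sum(areas) * slice_spacing,
                  object_masks = masks)
    list(stack = stack, truth = truth)
  })
}

#' Simulate a two-channel ratiometric pH image pair with ground truth
#'
#' The red channel is a uniform dye base intensity field; the green channel
#' equals red times the calibration ratio R(pH) pixelwise before noise.
#' Simulated microbial cells are rendered as bright disks in both channels
#' and recorded in the ground-truth cell mask. Relative Gaussian noise is
#' applied independently per channel.
#'
#' @param dims Integer (rows, cols) image size in pixels.
#' @param true_ph Scalar or matrix (same shape as `dims`) of true pH,
#'   inside the calibrated domain.
#' @param calib_params Named 5PL parameters of the generating calibration
#'   curve (see [calib_curve()]).
#' @param cell_density Expected number of cell blobs per image.
#' @param cell_radius_px Blob radius in pixels.
#' @param base_intensity Mean red-channel dye intensity.
#' @param cell_intensity Intensity of rendered cell pixels (both channels).
#' @param noise_sd Relative (multiplicative) channel noise SD, e.g. 0.05.
#' @param pixel_size Pixel size in um.
#' @param seed Integer seed.
#' @param domain Calibrated pH range.
#' @return List with `pair` (a `ratio_image_pair`: `green`, `red`,
#'   `pixel_size`) and `truth` (`ph_field`, `cell_mask`, `calib_params`).
#' @export
gen_ratiometric_pair <- function(dims = c(128, 128),
                                 true_ph,
                                 calib_params = default_calib_params(),
                                 cell_density = 0,
                                 cell_radius_px = 8,
                                 base_intensity = 100,
                                 cell_intensity = 400,
                                 noise_sd = 0,
                                 pixel_size = clsm_default_pixel_size(),
                                 seed,
                                 domain = c(4.0, 7.8)) {
  dims <- as.integer(dims)
  ph_field <- if (length(true_ph) == 1L) {
    matrix(true_ph, dims[1], dims[2])
  } else {
    matrix(true_ph, dims[1], dims[2])
  }
  if (any(ph_field < domain[1]) || any(ph_field > domain[2])) {
    stop_biofilmq(sprintf("true pH outside the calibrated range [%g, %g]",
                          domain[1], domain[2]), "biofilmq_range_error")
  }
  grid <- seq(domain[1], domain[2], length.out = 256)
  if (any(diff(calib_curve(grid, calib_params)) >= 0)) {
    stop_biofilmq("generating calibration curve must be strictly decreasing",
                  "biofilmq_validation_error")
  }
  local_seed(seed, {
    red <- matrix(base_intensity, dims[1], dims[2])
    green <- red * calib_curve(ph_field, calib_params)
    n_cells <- if (cell_density > 0) rpois(1, cell_density) else 0L
    cell_mask <- if (n_cells > 0) {
      render_disks(dims[1], dims[2],
                   cx = runif(n_cells, 1, dims[1]),
                   cy = runif(n_cells, 1, dims[2]),
                   radius = cell_radius_px)
    } else {
      matrix(FALSE, dims[1], dims[2])
    }
    red[cell_mask] <- cell_intensity
    green[cell_mask] <- cell_intensity
    if (noise_sd > 0) {
      red <- pmax(red * (1 + rnorm(length(red), sd = noise_sd)), 0)
      green <- pmax(green * (1 + rnorm(length(green), sd = noise_sd)), 0)
    }
    pair <- new_ratio_image_pair(green, red, pixel_size)
    truth <- list(ph_field = ph_field, cell_mask = cell_mask,
                  calib_params = calib_params)
    list(pair = pair, truth = truth)
  })
}

#' Simulate a buffer calibration series
#'
#' Emulates the buffer calibration protocol: 20 buffer solutions at pH 4.0
#' to 7.8 in steps of 0.2 units, each measured as a mean green/red ratio
#' equal to the generating curve plus Gaussian noise.
#'
#' @param calib_params Generating 5PL parameters.
#' @param noise_sd Ratio noise SD (0 = exact curve).
#' @param seed Integer seed.
#' @return Data frame with columns `pH` and `ratio` (20 rows).
#' @export
gen_calibration_table <- function(calib_params = default_calib_params(),
                                  noise_sd = 0,
                                  seed) {
  if (noise_sd < 0) {
    stop_biofilmq("`noise_sd` must be >= 0", "biofilmq_validation_error")
  }
  local_seed(seed, {
    ph <- seq(4.0, 7.8, by = 0.2)
    ratio <- calib_curve(ph, calib_params)
    if (noise_sd > 0) ratio <- ratio + rnorm(length(ph), sd = noise_sd)
    data.frame(pH = ph, ratio = pmax(ratio, 1e-6))
  })
}

#' Simulate a clustered trial outcome table with known treatment effect
#'
#' Generates gamma-distributed positive outcomes (thickness-like, in um) for
#' a split-mouth trial: each participant (cluster) carries `n_per_arm`
#' biofilms per arm, a lognormal participant multiplier (mean 1, CV
#' `participant_cv`) scales all of that participant's outcome means, and
#' enzyme-arm means are multiplied by `effect_ratio`. Planted outliers
#' replace randomly chosen outcomes with values at least 10 times the global
#' mean. `pre_value` is a pre-treatment covariate drawn with mean twice the
#' participant's baseline (the washing step in the study removed about half
#' of the biofilm).
#'
#' @param n_participants Number of clusters.
#' @param n_per_arm Biofilms per participant per arm.
#' @param effect_ratio True multiplicative enzyme/control effect on the
#'   mean outcome (> 0).
#' @param participant_cv Between-participant coefficient of variation of
#'   the multiplicative cluster effect.
#' @param shape Gamma shape parameter of the outcome distribution.
#' @param baseline Control-arm mean outcome for an average participant (um).
#' @param n_outliers Number of planted aberrant records.
#' @param seed Integer seed.
#' @return List with `table` (data frame: `participant`, `period`,
#'   `treatment` factor control/enzyme, `biofilm_id`, `outcome`,
#'   `pre_value`) and `truth` (`effect_ratio`, `participant_multipliers`,
#'   `dispersion`, `outlier_indices`).
#' @export
gen_trial_dataset <- function(n_participants = 11,
                              n_per_arm = 6,
                              effect_ratio = 1,
                              participant_cv = 0.3,
                              shape = 8,
                              baseline = 20,
                              n_outliers = 0,
                              seed) {
  stopifnot(n_participants >= 1, n_per_arm >= 1, n_outliers >= 0)
  if (effect_ratio <= 0) {
    stop_biofilmq("`effect_ratio` must be > 0", "biofilmq_validation_error")
  }
  local_seed(seed, {
    sdlog <- sqrt(log(1 + participant_cv^2))
    mult <- rlnorm(n_participants, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    tab <- expand.grid(
      rep = seq_len(n_per_arm),
      treatment = c("control", "enzyme"),
      participant = sprintf("S%02d", seq_len(n_participants)),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tab$treatment <- factor(tab$treatment, levels = c("control", "enzyme"))
    pid <- as.integer(sub("S", "", tab$participant))
    mu <- baseline * mult[pid] * ifelse(tab$treatment == "enzyme",
                                        effect_ratio, 1)
    tab$outcome <- rgamma(nrow(tab), shape = shape, rate = shape / mu)
    tab$pre_value <- rgamma(nrow(tab), shape = shape,
                            rate = shape / (2 * baseline * mult[pid]))
    tab$period <- 1L
    tab$biofilm_id <- sprintf("%s_%s_%02d", tab$participant,
                              substr(as.character(tab$treatment), 1, 3),
                              tab$rep)
    tab$rep <- NULL
    tab <- tab[, c("participant", "period", "treatment", "biofilm_id",
                   "outcome", "pre_value")]
    outlier_idx <- integer(0)
    if (n_outliers > 0) {
      outlier_idx <- sort(sample(nrow(tab), n_outliers))
      tab$outcome[outlier_idx] <-
        mean(tab$outcome) * runif(n_outliers, 10, 15)
    }
    truth <- list(effect_ratio = effect_ratio,
                  participant_multipliers = mult,
                  dispersion = list(shape = shape, baseline = baseline),
                  outlier_indices = outlier_idx)
    list(table = tab, truth = truth)
  })
}
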