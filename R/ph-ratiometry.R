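#' Segment the extracellular region of a ratiometric image pair
#'
#' Builds the mask of pixels used for extracellular pH averaging: pixels
#' whose red-channel intensity lies above a noise floor (background
#' exclusion) and below a cell threshold (exclusion of bright microbial
#' cells). The cell threshold defaults to an Otsu split of the above-floor
#' red intensities, accepted as a genuine cell class only when the upper
#' class is clearly separated (upper/lower class mean ratio at least
#' `min_separation`); otherwise the image is treated as cell-free. The
#' floor defaults to a small fraction of the bright-signal level
#' (`floor_frac` times the 99th percentile of red), since dye-filled fields
#' of view need not contain any dark background.
#'
#' @param pair A `ratio_image_pair`.
#' @param low Noise-floor intensity; pixels with red <= `low` are excluded.
#'   `NULL` for the default.
#' @param high Cell threshold; pixels with red >= `high` are excluded.
#'   `NULL` for the Otsu-derived default.
#' @param floor_frac Fraction of the 99th-percentile red intensity used for
#'   the default floor.
#' @param min_separation Minimum upper/lower class mean ratio for the Otsu
#'   split to be accepted as a cell class.
#' @return Logical mask (TRUE = extracellular pixel used for averaging),
#'   with attributes `low` and `high` recording the thresholds
#'   (`high = Inf` when no cell class was found).
#' @export
segment_extracellular <- function(pair, low = NULL, high = NULL,
                                  floor_frac = 0.05, min_separation = 2) {
  stopifnot(inherits(pair, "ratio_image_pair"))
  red <- pair$red
  if (is.null(low)) {
    low <- floor_frac * as.numeric(quantile(red, 0.99))
  }
  above <- red > low
  if (!any(above)) {
    stop_biofilmq("no extracellular signal: all pixels at or below the noise floor",
                  "biofilmq_no_signal_error")
  }
  if (is.null(high)) {
    high <- Inf
    vals <- red[above]
    thr <- tryCatch(otsu_threshold(vals), error = function(e) NULL)
    if (!is.null(thr)) {
      lo_mean <- mean(vals[vals <= thr])
      hi_mean <- mean(vals[vals > thr])
      if (is.finite(lo_mean) && is.finite(hi_mean) && lo_mean > 0 &&
          hi_mean / lo_mean >= min_separation) {
        high <- thr
      }
    }
  }
  mask <- red > low & red < high
  if (!any(mask)) {
    stop_biofilmq("no extracellular signal left after cell exclusion",
                  "biofilmq_no_signal_error")
  }
  attr(mask, "low") <- low
  attr(mask, "high") <- high
  mask
}

#' Mean extracellular pH of a ratiometric image pair
#'
#' Per-pixel green/red ratios on the extracellular mask are converted to pH
#' through the calibration model, then averaged (`avg = "pixel-ph"`, the
#' default). Alternatively the masked mean ratio is converted once
#' (`avg = "mean-ratio"`); the two differ under the nonlinear calibration
#' map. Out-of-range ratios are clamped to the calibration domain and
#' counted.
#'
#' @param pair A `ratio_image_pair`.
#' @param model A `calibration_model`.
#' @param avg Averaging order, `"pixel-ph"` or `"mean-ratio"`.
#' @param low,high,floor_frac,min_separation Passed to
#'   [segment_extracellular()].
#' @return An object of class `ph_result`: `mean_ph`, `n_pixels_used`,
#'   `excluded_cell_fraction`, `excluded_background_fraction`,
#'   `n_clamped`, `avg`, thresholds used.
#' @examples
#' model <- fit_calibration(gen_calibration_table(noise_sd = 0, seed = 1))
#' sim <- gen_ratiometric_pair(c(32, 32), true_ph = 5.5, seed = 1)
#' mean_extracellular_ph(sim$pair, model)$mean_ph
#' @export
mean_extracellular_ph <- function(pair, model,
                                  avg = c("pixel-ph", "mean-ratio"),
                                  low = NULL, high = NULL,
                                  floor_frac = 0.05, min_separation = 2) {
  avg <- match.arg(avg)
  stopifnot(inherits(pair, "ratio_image_pair"),
            inherits(model, "calibration_model"))
  mask <- segment_extracellular(pair, low = low, high = high,
                                floor_frac = floor_frac,
                                min_separation = min_separation)
  n_total <- length(mask)
  low_used <- attr(mask, "low")
  high_used <- attr(mask, "high")
  n_bg <- sum(pair$red <= low_used)
  n_cell <- sum(pair$red >= high_used)
  ratio <- pair$green[mask] / pair$red[mask]
  r_hi <- model$ratio_range[1]
  r_lo <- model$ratio_range[2]
  n_clamped <- sum(ratio > r_hi | ratio < r_lo)
  mean_ph <- if (avg == "pixel-ph") {
    mean(ratio_to_ph(ratio, model, clamp = TRUE))
  } else {
    ratio_to_ph(mean(ratio), model, clamp = TRUE)
  }
  structure(
    list(mean_ph = mean_ph,
         n_pixels_used = sum(mask),
         excluded_cell_fraction = n_cell / n_total,
         excluded_background_fraction = n_bg / n_total,
         n_clamped = n_clamped,
         avg = avg,
         low = low_used,
         high = high_used),
    class = "ph_result")
}

#' @export
print.ph_result <- function(x, ...) {
  cat(sprintf(
    "Extracellular pH: %.3f (%d px used; %.1f%% cells, %.1f%% background excluded; %s averaging)\n",
    x$mean_ph, x$n_pixels_used, 100 * x$excluded_cell_fraction,
    100 * x$excluded_background_fraction, x$avg))
  invisible(x)
}
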