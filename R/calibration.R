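#' Five-parameter logistic calibration between pH and fluorescence ratio
#'
#' Dual-emission pH probes such as C-SNARF-4 yield a green/red emission ratio
#' R that decreases monotonically with pH over the calibrated range. The
#' package models the calibration with an asymmetric five-parameter logistic
#' (5PL)
#' \deqn{R(pH) = d + \frac{a - d}{\left(1 + (pH/c)^b\right)^g}}
#' with `a > d` and `b, g > 0`, which is strictly decreasing in pH and has
#' the closed-form inverse
#' \deqn{pH(R) = c \left( \left(\frac{a - d}{R - d}\right)^{1/g} - 1 \right)^{1/b}.}
#'
#' @param ph Numeric vector of pH values.
#' @param params Named numeric vector or list with elements `a`, `b`, `c`,
#'   `d`, `g`.
#' @return `calib_curve()` returns the ratio R evaluated at `ph`;
#'   `calib_curve_inverse()` returns the pH at which the curve equals
#'   `ratio`.
#' @seealso [fit_calibration()], [ratio_to_ph()]
#' @export
calib_curve <- function(ph, params) {
  p <- as.list(params)
  p$d + (p$a - p$d) / (1 + (ph / p$c)^p$b)^p$g
}

#' @rdname calib_curve
#' @param ratio Numeric vector of green/red ratios, strictly between the
#'   curve's asymptotes.
#' @export
calib_curve_inverse <- function(ratio, params) {
  p <- as.list(params)
  p$c * (((p$a - p$d) / (ratio - p$d))^(1 / p$g) - 1)^(1 / p$b)
}

#' Default generating calibration parameters
#'
#' A realistic green/red ratio curve for a dual-emission pH dye: the ratio
#' falls from about 1.18 at pH 4.0 to about 0.28 at pH 7.8 with an
#' inflection near pH 5.8, in line with published ratiometric calibrations
#' for this dye family over the pH 4.0--7.8 buffer series.
#'
#' @return Named numeric vector with elements `a`, `b`, `c`, `d`, `g`.
#' @export
default_calib_params <- function() {
  c(a = 1.25, b = 6, c = 5.8, d = 0.12, g = 0.9)
}

#' Fit a pH calibration curve to a buffer series
#'
#' Least-squares fit of the asymmetric five-parameter logistic to a table of
#' (pH, ratio) measurements from a buffer calibration series. The fitted
#' curve must be strictly monotone (decreasing) over the data range or the
#' fit is rejected.
#'
#' @param table Data frame with columns `pH` and `ratio` (at least 6 rows
#'   spanning at least 2 pH units).
#' @return An object of class `calibration_model`: a list with `params`
#'   (named 5PL coefficients), `fit_rmse`, `domain` (pH range of the data),
#'   `ratio_range` (ratio at the domain ends, decreasing order reversed),
#'   and `form = "logistic5"`.
#' @examples
#' tab <- gen_calibration_table(noise_sd = 0, seed = 1)
#' model <- fit_calibration(tab)
#' ratio_to_ph(calib_curve(6.0, model$params), model)
#' @export
fit_calibration <- function(table) {
  if (!all(c("pH", "ratio") %in% names(table))) {
    stop_biofilmq("calibration table needs columns `pH` and `ratio`",
                  "biofilmq_validation_error")
  }
  tab <- table[order(table$pH), , drop = FALSE]
  ph <- tab$pH
  ratio <- tab$ratio
  if (anyDuplicated(ph)) {
    stop_biofilmq("calibration pH values must be unique",
                  "biofilmq_validation_error")
  }
  if (length(ph) < 6 || diff(range(ph)) < 2) {
    stop_biofilmq("calibration needs >= 6 rows spanning >= 2 pH units",
                  "biofilmq_validation_error")
  }
  if (any(ratio <= 0)) {
    stop_biofilmq("calibration ratios must be positive",
                  "biofilmq_validation_error")
  }
  if (sd(ratio) < 1e-12 * max(abs(ratio))) {
    stop_biofilmq("calibration ratios are constant across pH: unidentifiable",
                  "biofilmq_fit_error")
  }
  start <- list(a = max(ratio) * 1.05,
                b = 5,
                c = ph[which.min(abs(ratio - (max(ratio) + min(ratio)) / 2))],
                d = max(min(ratio) * 0.8, 1e-4),
                g = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ratio ~ d + (a - d) / (1 + (pH / c)^b)^g,
      data = data.frame(pH = ph, ratio = ratio),
      start = start,
      lower = c(a = 1e-6, b = 0.2, c = 1, d = 0, g = 0.02),
      upper = c(a = Inf, b = 50, c = 20, d = max(ratio), g = 50),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)
    ),
    error = function(e) {
      stop_biofilmq(paste0("calibration fit failed: ", conditionMessage(e)),
                    "biofilmq_fit_error")
    }
  )
  params <- coef(fit)
  grid <- seq(min(ph), max(ph), length.out = 512)
  rhat <- calib_curve(grid, params)
  if (any(!is.finite(rhat)) || any(diff(rhat) >= 0)) {
    stop_biofilmq(
      "fitted calibration curve is not strictly decreasing over the data range",
      "biofilmq_fit_error")
  }
  resid <- ratio - calib_curve(ph, params)
  structure(
    list(form = "logistic5",
         params = params,
         fit_rmse = sqrt(mean(resid^2)),
         domain = range(ph),
         ratio_range = calib_curve(range(ph), params),
         version = 1L),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Calibration model (asymmetric 5-parameter logistic)\n")
  cat(sprintf("  domain: pH %.2f - %.2f\n", x$domain[1], x$domain[2]))
  cat(sprintf("  ratio at domain ends: %.4f (pH %.1f) to %.4f (pH %.1f)\n",
              x$ratio_range[1], x$domain[1], x$ratio_range[2], x$domain[2]))
  cat(sprintf("  fit RMSE: %.3g ratio units\n", x$fit_rmse))
  cat("  params:", paste(sprintf("%s=%.6g", names(x$params), x$params),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Convert a fluorescence ratio to pH via a fitted calibration model
#'
#' Analytic inversion of the fitted five-parameter logistic. Ratios outside
#' the calibrated ratio range correspond to pH outside the buffer series;
#' they are clamped to the domain endpoints when `clamp = TRUE` (the
#' default) and raise an error otherwise.
#'
#' @param ratio Numeric vector of positive green/red ratios.
#' @param model A `calibration_model` from [fit_calibration()].
#' @param clamp Clamp out-of-range ratios to the pH domain endpoints?
#' @return Numeric vector of pH values.
#' @export
ratio_to_ph <- function(ratio, model, clamp = TRUE) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop_biofilmq("ratios must be positive and finite",
                  "biofilmq_validation_error")
  }
  r_hi <- model$ratio_range[1]  # ratio at pH domain lower end (max ratio)
  r_lo <- model$ratio_range[2]  # ratio at pH domain upper end (min ratio)
  out_of_range <- ratio > r_hi | ratio < r_lo
  if (any(out_of_range) && !clamp) {
    stop_biofilmq(sprintf(
      "%d ratio value(s) outside the calibrated range [%.4g, %.4g]",
      sum(out_of_range), r_lo, r_hi), "biofilmq_range_error")
  }
  ph <- rep(NA_real_, length(ratio))
  inside <- !out_of_range
  ph[inside] <- calib_curve_inverse(ratio[inside], model$params)
  ph[ratio >= r_hi] <- model$domain[1]
  ph[ratio <= r_lo] <- model$domain[2]
  # guard rounding at the exact endpoints
  pmin(pmax(ph, model$domain[1]), model$domain[2])
}

#' Serialize / restore a calibration model
#'
#' `write_calibration_model()` writes the single JSON serialization of a
#' fitted model (form id, coefficients, domain, RMSE, version);
#' `read_calibration_model()` restores it.
#'
#' @param model A `calibration_model`.
#' @param path File path for the JSON serialization.
#' @export
write_calibration_model <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(
    list(form = model$form,
         params = as.list(model$params),
         fit_rmse = model$fit_rmse,
         domain = model$domain,
         ratio_range = model$ratio_range,
         version = model$version),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_model
#' @export
read_calibration_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$version)) {
    stop_biofilmq("calibration model file lacks a version field",
                  "biofilmq_validation_error")
  }
  structure(
    list(form = x$form, params = unlist(x$params), fit_rmse = x$fit_rmse,
         domain = x$domain, ratio_range = x$ratio_range,
         version = x$version),
    class = "calibration_model")
}
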