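#' Threshold segmentation of a confocal slice
#'
#' @param image 2D numeric matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_value Threshold when `method = "fixed"`.
#' @param nbins Histogram bins for Otsu on continuous data.
#' @return Logical mask of pixels strictly above the threshold.
#' @export
segment_slice <- function(image, method = c("otsu", "fixed"),
                          fixed_value = NULL, nbins = 256) {
  method <- match.arg(method)
  if (!is.matrix(image) || length(image) == 0) {
    stop_biofilmq("`image` must be a non-empty matrix",
                  "biofilmq_validation_error")
  }
  threshold <- if (method == "fixed") {
    if (is.null(fixed_value)) {
      stop_biofilmq("method = \"fixed\" requires `fixed_value`",
                    "biofilmq_validation_error")
    }
    fixed_value
  } else {
    otsu_threshold(image, nbins = nbins)
  }
  image > threshold
}

#' Cavalieri biovolume estimator
#'
#' Stereological volume estimate from a series of parallel sections: the
#' sum of section areas times the section spacing.
#'
#' @param slice_areas Numeric vector of per-slice bacterial areas (um^2).
#' @param slice_spacing Inter-slice spacing in um.
#' @return Biovolume in um^3.
#' @examples
#' biovolume_cavalieri(c(100, 80, 60), 2)  # 480
#' @export
biovolume_cavalieri <- function(slice_areas, slice_spacing) {
  check_positive_scalar(slice_spacing, "slice_spacing")
  if (length(slice_areas) < 1L) {
    stop_biofilmq("need at least one slice area", "biofilmq_validation_error")
  }
  if (any(!is.finite(slice_areas)) || any(slice_areas < 0)) {
    stop_biofilmq("slice areas must be finite and >= 0",
                  "biofilmq_validation_error")
  }
  sum(slice_areas) * slice_spacing
}

#' Quantify biofilm biovolume from a confocal z-stack
#'
#' Per-slice threshold segmentation with a single threshold shared across
#' the slices of one stack (computed on the pooled intensity histogram),
#' followed by the Cavalieri estimate: slice pixel counts times pixel area,
#' summed and multiplied by the slice spacing.
#'
#' @param stack A `clsm_stack`.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_value Threshold when `threshold_method = "fixed"`.
#' @param nbins Histogram bins for Otsu.
#' @return An object of class `biovolume_result`: `slice_areas` (um^2),
#'   `biovolume` (um^3), `threshold_used`.
#' @export
quantify_stack <- function(stack, threshold_method = c("otsu", "fixed"),
                           fixed_value = NULL, nbins = 256) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(inherits(stack, "clsm_stack"))
  pooled <- unlist(stack$slices, use.names = FALSE)
  threshold <- if (threshold_method == "fixed") {
    if (is.null(fixed_value)) {
      stop_biofilmq("threshold_method = \"fixed\" requires `fixed_value`",
                    "biofilmq_validation_error")
    }
    fixed_value
  } else {
    otsu_threshold(pooled, nbins = nbins)
  }
  areas <- vapply(stack$slices,
                  function(s) sum(s > threshold) * stack$pixel_size^2,
                  numeric(1))
  structure(
    list(slice_areas = areas,
         biovolume = biovolume_cavalieri(areas, stack$slice_spacing),
         threshold_used = threshold),
    class = "biovolume_result")
}

#' @export
print.biovolume_result <- function(x, ...) {
  cat(sprintf("Cavalieri biovolume: %.1f um^3 over %d slices (threshold %.4g)\n",
              x$biovolume, length(x$slice_areas), x$threshold_used))
  invisible(x)
}

#' Compare two paired quantification methods by Pearson correlation
#'
#' Pearson correlation with Fisher-z 95 percent confidence interval and a
#' two-sided p-value, for paired per-biofilm values from two methods (e.g.
#' OCT thickness vs CLSM biovolume).
#'
#' @param paired_values_a,paired_values_b Numeric vectors of equal length
#'   (>= 3), finite, with nonzero variance.
#' @return List with `r`, `ci` (length 2), `p_value`, `n`.
#' @export
compare_methods <- function(paired_values_a, paired_values_b) {
  a <- as.numeric(paired_values_a)
  b <- as.numeric(paired_values_b)
  if (length(a) != length(b) || length(a) < 3L) {
    stop_biofilmq("need equal-length vectors with n >= 3",
                  "biofilmq_validation_error")
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop_biofilmq("values must be finite", "biofilmq_validation_error")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    stop_biofilmq("correlation undefined: zero variance in one vector",
                  "biofilmq_degenerate_error")
  }
  ct <- cor.test(a, b, method = "pearson", conf.level = 0.95)
  list(r = unname(ct$estimate),
       ci = if (!is.null(ct$conf.int)) as.numeric(ct$conf.int) else c(NA, NA),
       p_value = ct$p.value,
       n = length(a))
}
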