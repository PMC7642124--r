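# Hounsfield-unit standardization from air and water phantom scans.

#' Construct a phantom calibration
#'
#' Holds the mean linear attenuation of water and air phantoms scanned under
#' the same acquisition conditions as the specimens, used to put reconstructed
#' intensities on the Hounsfield scale (water = 0 HU, air = -1000 HU).
#'
#' @param mu_water,mu_air Mean attenuation of the water / air phantom, in
#'   reconstruction units. `mu_water` must exceed `mu_air`.
#' @param acquisition_tag Label tying the calibration to a scan-parameter set.
#' @param trim_fraction Trim fraction recorded when the means come from
#'   [calibrate_from_phantom_stats()].
#' @return A `phantom_calibration` object.
#' @export
phantom_calibration <- function(mu_water, mu_air, acquisition_tag = NA_character_,
                                trim_fraction = NA_real_) {
  if (!is.finite(mu_water) || !is.finite(mu_air) || mu_water <= mu_air) {
    abort("mu_water must be finite and strictly greater than mu_air",
          class = "dicect_calibration_error")
  }
  structure(list(mu_water = mu_water, mu_air = mu_air,
                 acquisition_tag = acquisition_tag,
                 trim_fraction = trim_fraction),
            class = "phantom_calibration")
}

#' @export
print.phantom_calibration <- function(x, ...) {
  cat(sprintf("<phantom_calibration> mu_water = %.6g, mu_air = %.6g%s\n",
              x$mu_water, x$mu_air,
              if (is.na(x$acquisition_tag)) "" else
                sprintf(" (%s)", x$acquisition_tag)))
  invisible(x)
}

#' Estimate a phantom calibration from phantom voxel samples
#'
#' Summarizes each phantom's attenuation values by a trimmed mean (5% per
#' tail by default; reconstruction artifacts produce outliers) and returns a
#' [phantom_calibration()].
#'
#' @param water_values,air_values Numeric vectors of attenuation samples.
#' @param trim_fraction Fraction trimmed from each tail of each sample.
#' @param acquisition_tag Optional label.
#' @return A `phantom_calibration`.
#' @export
calibrate_from_phantom_stats <- function(water_values, air_values,
                                         trim_fraction = 0.05,
                                         acquisition_tag = NA_character_) {
  if (length(water_values) == 0 || length(air_values) == 0) {
    abort("phantom samples must be non-empty", class = "dicect_calibration_error")
  }
  mu_w <- mean(water_values, trim = trim_fraction)
  mu_a <- mean(air_values, trim = trim_fraction)
  if (!(mu_w > mu_a)) {
    abort(sprintf(
      "water phantom mean (%.6g) does not exceed air phantom mean (%.6g)",
      mu_w, mu_a), class = "dicect_calibration_error")
  }
  phantom_calibration(mu_w, mu_a, acquisition_tag = acquisition_tag,
                      trim_fraction = trim_fraction)
}

#' Convert attenuation values to Hounsfield units
#'
#' The standard affine Hounsfield scaling
#' `HU = 1000 * (value - mu_water) / (mu_water - mu_air)`, vectorized and
#' order preserving: the water mean maps to 0 HU and the air mean to
#' -1000 HU.
#'
#' @param value Numeric vector of attenuation values.
#' @param cal A `phantom_calibration`.
#' @return Numeric vector of Hounsfield units.
#' @export
#' @examples
#' cal <- phantom_calibration(0.2, 0.0)
#' to_hounsfield(c(0.2, 0.0, 0.1), cal)
to_hounsfield <- function(value, cal) {
  if (!inherits(cal, "phantom_calibration")) {
    abort("`cal` must be a phantom_calibration", class = "dicect_calibration_error")
  }
  1000 * (value - cal$mu_water) / (cal$mu_water - cal$mu_air)
}

#' Read / write a phantom calibration as YAML
#'
#' @param path File path.
#' @return `read_calibration()` returns a `phantom_calibration`;
#'   `write_calibration()` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  y <- yaml::read_yaml(path)
  phantom_calibration(y$mu_water, y$mu_air,
                      acquisition_tag = y$acquisition_tag %||% NA_character_,
                      trim_fraction = y$trim_fraction %||% NA_real_)
}

#' @rdname read_calibration
#' @param cal A `phantom_calibration`.
#' @export
write_calibration <- function(cal, path) {
  yaml::write_yaml(list(acquisition_tag = cal$acquisition_tag,
                        mu_water = cal$mu_water, mu_air = cal$mu_air,
                        trim_fraction = cal$trim_fraction), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
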