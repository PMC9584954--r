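#' Cofactor quantification configuration
#'
#' @param epsilon_430 Molar extinction coefficient of coenzyme F430 at
#'   430 nm, in M^-1 cm^-1 (default 22500).
#' @param sites_per_complex Number of F430-binding active sites per
#'   complex; the (alpha beta gamma)2 architecture carries two.
#' @param wavelength_nm Wavelength the extinction coefficient refers to,
#'   recorded in outputs. Quantification uses 430 nm (free-cofactor
#'   maximum) even though the holoenzyme absorbs maximally at 425 nm.
#' @return A list of class `cofactor_config`.
#' @export
cofactor_config <- function(epsilon_430 = 22500, sites_per_complex = 2,
                            wavelength_nm = 430) {
  stopifnot(epsilon_430 > 0, sites_per_complex > 0)
  structure(
    list(epsilon_430 = epsilon_430,
         sites_per_complex = sites_per_complex,
         wavelength_nm = wavelength_nm),
    class = "cofactor_config"
  )
}

#' F430 concentration from absorbance (Beer-Lambert)
#'
#' `c = A430 / (epsilon * pathlength) * dilution_factor`.
#'
#' @param a430 Absorbance at 430 nm (vectorized).
#' @param pathlength_cm Cuvette pathlength in cm (default 1.0, a 10 mm
#'   quartz cuvette).
#' @param dilution_factor Dilution applied before measurement (>= 1).
#' @param config A [cofactor_config()].
#' @return Concentration in mol/L.
#' @export
#' @examples
#' f430_concentration(0.225)  # 1e-5 M
f430_concentration <- function(a430, pathlength_cm = 1.0,
                               dilution_factor = 1.0,
                               config = cofactor_config()) {
  if (any(a430 < 0)) stop("absorbance must be nonnegative")
  stopifnot(all(pathlength_cm > 0), all(dilution_factor >= 1))
  a430 / (config$epsilon_430 * pathlength_cm) * dilution_factor
}

#' Active-site occupancy of a cofactor-binding complex
#'
#' Fraction of active sites carrying F430:
#' `occupancy_pct = (c_F430 / c_complex) / sites_per_complex * 100`.
#' Both molarities must be in the same units. The complement
#' (`reduction_pct = 100 - occupancy_pct`) is reported alongside because
#' a reduced cofactor content can be read per-complex or as total yield;
#' both readings are exposed rather than collapsed.
#'
#' @param f430_molar F430 concentration (mol/L).
#' @param complex_molar Complex concentration (mol/L), > 0.
#' @param config A [cofactor_config()].
#' @return List: `occupancy_pct`, `reduction_pct`, `f430_per_complex`,
#'   `wavelength_nm`.
#' @export
#' @examples
#' occupancy(2.0e-5, 1.0e-5)$occupancy_pct   # 100: both sites filled
#' occupancy(1.4e-5, 1.0e-5)$reduction_pct   # 30
occupancy <- function(f430_molar, complex_molar,
                      config = cofactor_config()) {
  if (complex_molar <= 0) stop("complex concentration must be positive")
  if (f430_molar < 0) stop("F430 concentration must be nonnegative")
  ratio <- f430_molar / complex_molar
  if (ratio > config$sites_per_complex * 1.05) {
    warning(sprintf(
      "super-stoichiometric F430: %.2f per complex exceeds the %d sites",
      ratio, config$sites_per_complex))
  }
  pct <- ratio / config$sites_per_complex * 100
  list(occupancy_pct = pct, reduction_pct = 100 - pct,
       f430_per_complex = ratio, wavelength_nm = config$wavelength_nm)
}

#' HPLC quantification against an authentic-standard curve
#'
#' Fits the ordinary least-squares calibration line
#' `area = slope * concentration + intercept` through the standard points
#' and inverts unknown peak areas through the fit.
#'
#' @param curve_points Data frame with columns `concentration` and
#'   `peak_area` (>= 2 distinct concentrations).
#' @param unknown_areas Numeric vector of areas to quantify (may be
#'   empty).
#' @return List of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `points`, and `concentrations` for the unknowns.
#' @export
hplc_quantify <- function(curve_points, unknown_areas = numeric()) {
  stopifnot(is.data.frame(curve_points),
            all(c("concentration", "peak_area") %in% names(curve_points)))
  if (length(unique(curve_points$concentration)) < 2L) {
    stop("standard curve needs >= 2 distinct concentrations")
  }
  fit <- stats::lm(peak_area ~ concentration, data = curve_points)
  co <- stats::coef(fit)
  ss_tot <- sum((curve_points$peak_area -
                   mean(curve_points$peak_area))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(
    list(slope = unname(co[["concentration"]]),
         intercept = unname(co[["(Intercept)"]]),
         r_squared = r2,
         points = curve_points,
         concentrations = (unknown_areas - co[["(Intercept)"]]) /
           co[["concentration"]]),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve: area = %.4g * conc + %.4g (r^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}
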