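# Boltzmann constant in pN.nm per kelvin (1.380649e-23 J/K, 1 J = 1e21 pN.nm)
.kB_pN_nm_per_K <- 1.380649e-2

#' Conical tip geometry for contact-mechanics fits
#'
#' Describes the indenter used in force-indentation analysis: a cone of
#' half-opening angle `half_angle_rad` pressing on an incompressible
#' elastic half-space with Poisson ratio `poisson_ratio`. The defaults
#' (0.31 rad, 0.5) are the values commonly used for sharp silicon nitride
#' probes on living yeast cells.
#'
#' @param half_angle_rad Cone half-opening angle in radians, in (0, pi/2).
#' @param poisson_ratio Poisson ratio of the sample, in \[0, 0.5\]
#'   (0.5 = incompressible).
#' @return A `tip_geometry` object (a named list).
#' @examples
#' tip_geometry()
#' @export
tip_geometry <- function(half_angle_rad = 0.31, poisson_ratio = 0.5) {
  if (!is.numeric(half_angle_rad) || length(half_angle_rad) != 1 ||
      half_angle_rad <= 0 || half_angle_rad >= pi / 2) {
    abort("`half_angle_rad` must be a single number in (0, pi/2).")
  }
  if (!is.numeric(poisson_ratio) || length(poisson_ratio) != 1 ||
      poisson_ratio < 0 || poisson_ratio > 0.5 + 1e-12) {
    abort("`poisson_ratio` must be a single number in [0, 0.5].")
  }
  structure(
    list(half_angle_rad = half_angle_rad, poisson_ratio = poisson_ratio),
    class = "tip_geometry"
  )
}

#' @export
print.tip_geometry <- function(x, ...) {
  cat(sprintf(
    "<tip_geometry> cone half-angle %.3f rad, Poisson ratio %.2f\n",
    x$half_angle_rad, x$poisson_ratio
  ))
  invisible(x)
}

#' Thermal context for polymer extension models
#'
#' Carries the absolute temperature and the derived thermal energy
#' `kBT` in pN.nm, the natural force-length unit of single-molecule
#' force spectroscopy. At room temperature (298 K) `kBT` is about
#' 4.11 pN.nm.
#'
#' @param temperature_K Absolute temperature in kelvin (> 0).
#' @return A `thermal_context` object with fields `temperature_K` and
#'   `kBT_pN_nm`.
#' @examples
#' thermal_context()$kBT_pN_nm # ~4.11
#' @export
thermal_context <- function(temperature_K = 298) {
  if (!is.numeric(temperature_K) || length(temperature_K) != 1 ||
      temperature_K <= 0) {
    abort("`temperature_K` must be a single positive number.")
  }
  structure(
    list(
      temperature_K = temperature_K,
      kBT_pN_nm = .kB_pN_nm_per_K * temperature_K
    ),
    class = "thermal_context"
  )
}

#' @export
print.thermal_context <- function(x, ...) {
  cat(sprintf(
    "<thermal_context> T = %.1f K, kBT = %.3f pN.nm\n",
    x$temperature_K, x$kBT_pN_nm
  ))
  invisible(x)
}
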