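#' Convert between degrees of visual angle and retinal microns
#'
#' Linear conversion using a per-participant retinal magnification scale.
#' The default scale of 282 um/deg is the cohort median foveal magnification
#' used throughout the package's synthetic defaults.
#'
#' @param deg,um value(s) to convert.
#' @param scale microns of retina per degree of visual angle; must be > 0.
#' @return Converted numeric vector.
#' @examples
#' deg_to_um(1)            # 282
#' um_to_deg(deg_to_um(3)) # 3
#' @export
deg_to_um <- function(deg, scale = 282) {
  check_scale(scale)
  deg * scale
}

#' @rdname deg_to_um
#' @export
um_to_deg <- function(um, scale = 282) {
  check_scale(scale)
  um / scale
}

check_scale <- function(scale) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("`scale` must be a single positive number (um per degree)",
         call. = FALSE)
  }
  invisible(scale)
}

#' Hexagonal-packing conversion between inter-cell distance and density
#'
#' Under the asymmetric hexagonal-packing assumption, a cell with mean
#' inter-cell distance `icd` (in um) sits in a mosaic of local density
#' `D = 1e6 / (icd^2 * cos(pi/6))` cells per mm^2.  `density_to_icd()` is the
#' exact algebraic inverse.
#'
#' @param icd inter-cell distance(s) in um; must be > 0.
#' @param density local density(ies) in cells/mm^2; must be > 0.
#' @return `icd_to_density()`: cells/mm^2; `density_to_icd()`: um.
#' @examples
#' icd_to_density(10)                     # 11547.005
#' density_to_icd(icd_to_density(3.2))   # 3.2
#' @export
icd_to_density <- function(icd) {
  if (any(!is.finite(icd)) || any(icd <= 0)) {
    stop("`icd` must be finite and > 0 (um)", call. = FALSE)
  }
  1e6 / (icd^2 * cos(pi / 6))
}

#' @rdname icd_to_density
#' @export
density_to_icd <- function(density) {
  if (any(!is.finite(density)) || any(density <= 0)) {
    stop("`density` must be finite and > 0 (cells/mm^2)", call. = FALSE)
  }
  sqrt(1e6 / (density * cos(pi / 6)))
}
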