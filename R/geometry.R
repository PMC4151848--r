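#' Strip geometry for a tensile-test specimen
#'
#' Bundles the measured geometry of an excised arterial wall strip together
#' with the two material constants used throughout the wall formulas: the
#' mass density of the aortic wall (1.06 g/cm^3) and Poisson's ratio (0.50,
#' i.e. incompressibility). Poisson's ratio is stored to document the
#' assumption; it enters the stress and thickness formulas only implicitly
#' through the incompressibility factor (1 + strain).
#'
#' @param L0 Initial (just-taut) length of the strip, cm.
#' @param width Strip width, cm.
#' @param weight Strip weight, g.
#' @param circ_length Circumferential length of the excised strip, cm.
#'   Optional (`NA`) when only longitudinal quantities are needed.
#' @param rho Wall mass density, g/cm^3.
#' @param poisson_ratio Poisson's ratio of the wall, dimensionless.
#'
#' @return An object of class `strip_geometry` (a named list).
#' @examples
#' g <- strip_geometry(L0 = 0.8, width = 0.3, weight = 0.004, circ_length = 0.34)
#' wall_thickness(g)
#' @export
strip_geometry <- function(L0, width, weight, circ_length = NA_real_,
                           rho = 1.06, poisson_ratio = 0.50) {
  for (nm in c("L0", "width", "weight")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop_invalid_geometry(sprintf("`%s` must be a single positive number", nm))
    }
  }
  if (!is.na(circ_length) && circ_length <= 0) {
    stop_invalid_geometry("`circ_length` must be positive when given")
  }
  if (rho <= 0) stop_invalid_geometry("`rho` must be positive")
  if (poisson_ratio <= 0 || poisson_ratio > 0.5) {
    stop_invalid_geometry("`poisson_ratio` must lie in (0, 0.5]")
  }
  structure(
    list(L0 = L0, width = width, weight = weight, circ_length = circ_length,
         rho = rho, poisson_ratio = poisson_ratio),
    class = "strip_geometry"
  )
}

#' @export
print.strip_geometry <- function(x, ...) {
  cat("Strip geometry: L0 =", x$L0, "cm, width =", x$width, "cm, weight =",
      x$weight, "g\n")
  if (!is.na(x$circ_length)) {
    cat("  circumferential length =", x$circ_length, "cm\n")
  }
  cat("  density =", x$rho, "g/cm^3, Poisson ratio =", x$poisson_ratio, "\n")
  invisible(x)
}

# Unstressed cross-sectional area in cm^2, from weight, density and length.
cross_section_cm2 <- function(geometry) {
  geometry$weight / (geometry$rho * geometry$L0)
}

#' Wall thickness from strip weight and footprint
#'
#' Thickness is recovered gravimetrically as h = W / (rho * L0 * Wd): the
#' strip weight divided by density times the footprint area, assuming a
#' uniform rectangular strip.
#'
#' @param geometry A [strip_geometry()].
#' @return Wall thickness in micrometres.
#' @examples
#' wall_thickness(strip_geometry(1, 0.3, 0.002))  # 62.89 um
#' @export
wall_thickness <- function(geometry) {
  stopifnot(inherits(geometry, "strip_geometry"))
  h_cm <- geometry$weight / (geometry$rho * geometry$L0 * geometry$width)
  h_cm * 1e4
}

#' Derived wall geometry of the intact vessel
#'
#' Computes the descriptive geometry reported per specimen: the unstressed
#' cross-sectional area of the strip, the internal radius and diameter of the
#' vessel estimated from the circumferential length of the excised strip
#' (radius = l / 2*pi), and the wall weight per unit luminal area.
#' The weight per area in mg/cm^2 is algebraically rho * 1000 * h(cm), i.e.
#' 0.106 x thickness in micrometres at the default density.
#'
#' @param geometry A [strip_geometry()]; `circ_length` must be set for the
#'   radius/diameter estimates.
#' @return A list with `cross_section_area` (mm^2), `internal_radius` (mm),
#'   `internal_diameter` (mm) and `weight_per_area` (mg/cm^2).
#' @export
wall_geometry_summary <- function(geometry) {
  stopifnot(inherits(geometry, "strip_geometry"))
  a_cm2 <- cross_section_cm2(geometry)
  r_mm <- if (is.na(geometry$circ_length)) NA_real_ else {
    geometry$circ_length * 10 / (2 * pi)
  }
  list(
    cross_section_area = a_cm2 * 100,           # cm^2 -> mm^2
    internal_radius = r_mm,
    internal_diameter = if (is.na(r_mm)) NA_real_ else 2 * r_mm,
    weight_per_area = geometry$weight * 1000 / (geometry$L0 * geometry$width)
  )
}

#' Arterial pressure sustained by the wall via Laplace's law
#'
#' The Laplace relation for a thin-walled cylinder, AP = T / R = E * h *
#' strain / R, links the incremental elastic modulus, wall thickness and
#' operating strain to the pressure the wall can sustain at internal radius
#' R. Used to reason about how wall remodelling (thinner media, smaller
#' radius) translates into arterial pressure.
#'
#' @param E Incremental elastic modulus, kPa.
#' @param h Wall thickness, micrometres.
#' @param strain Operating circumferential strain, dimensionless.
#' @param R Internal radius, mm.
#' @return Estimated pressure in kPa.
#' @examples
#' laplace_pressure(E = 200, h = 190, strain = 0.5, R = 0.66)
#' @export
laplace_pressure <- function(E, h, strain, R) {
  if (!is.numeric(R) || any(R <= 0)) {
    stop_invalid_geometry("internal radius `R` must be positive")
  }
  if (any(E < 0) || any(h < 0) || any(strain < 0)) {
    stop_aorta("aortamech_invalid_input",
               "E, h and strain must be non-negative")
  }
  # h um -> mm so that E (kPa) * (h/R dimensionless) stays in kPa
  E * (h / 1000) * strain / R
}
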