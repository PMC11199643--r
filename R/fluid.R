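# Unit conventions: geometry is SI (m) internally; pressures are mmHg,
# flows ml/s and resistances mmHg.s/ml at the user surface. The single
# conversion constant lives here.

#' @keywords internal
.pa_per_mmhg <- 133.322

# Pa.s/m^3 -> mmHg.s/ml
.rsi_to_clin <- 1e-6 / .pa_per_mmhg

#' Blood fluid properties
#'
#' Density and dynamic viscosity of blood treated as an incompressible
#' Newtonian fluid. Defaults are the standard large-artery values
#' rho = 1060 kg/m^3 and mu = 3.45 mPa s.
#'
#' @param density mass density in kg/m^3.
#' @param viscosity dynamic viscosity in Pa s.
#' @return An object of class `fluid_properties`.
#' @examples
#' fluid_properties()
#' @export
fluid_properties <- function(density = 1060, viscosity = 3.45e-3) {
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    stop("`density` must be a single positive number (kg/m^3)")
  if (!is.numeric(viscosity) || length(viscosity) != 1L || viscosity <= 0)
    stop("`viscosity` must be a single positive number (Pa s)")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("Fluid: density %.0f kg/m^3, viscosity %.3g mPa s\n",
              x$density, x$viscosity * 1e3))
  invisible(x)
}

# Hagen-Poiseuille resistance integral of a (possibly linearly tapered)
# circular segment over the axial window [x0, x1], in SI units (Pa.s/m^3).
# r(x) = r_prox + (r_dist - r_prox) * x / length.
.hp_resistance_si <- function(viscosity, length, r_prox, r_dist = r_prox,
                              x0 = 0, x1 = length) {
  stopifnot(length > 0, r_prox > 0, r_dist > 0, x0 >= 0, x1 <= length,
            x1 >= x0)
  if (abs(r_prox - r_dist) <= 1e-12 * max(r_prox, r_dist)) {
    return(8 * viscosity * (x1 - x0) / (pi * r_prox^4))
  }
  slope <- (r_dist - r_prox) / length
  r0 <- r_prox + slope * x0
  r1 <- r_prox + slope * x1
  (8 * viscosity / pi) * (1 / (3 * slope)) * (1 / r0^3 - 1 / r1^3)
}

#' Hagen-Poiseuille resistance of a vessel segment
#'
#' Viscous flow resistance of a straight circular segment under steady
#' laminar fully developed (parabolic) flow. A uniform radius gives
#' `8 mu L / (pi r^4)`; a linear taper is integrated analytically,
#' `(8 mu / pi) L / (3 (r_p - r_d)) (1/r_d^3 - 1/r_p^3)`. An axial
#' sub-window `[from, to]` supports partial (cut-plane) resistances.
#'
#' @param length segment length in m.
#' @param r_prox,r_dist proximal and distal radii in m (equal = uniform).
#' @param fluid a [fluid_properties()] object.
#' @param from,to axial window in m over which to integrate
#'   (defaults: the whole segment).
#' @return Resistance in mmHg s/ml.
#' @examples
#' # 10 mm long, 1.5 mm radius: about 0.130 mmHg s/ml
#' poiseuille_resistance(0.010, 1.5e-3)
#' @export
poiseuille_resistance <- function(length, r_prox, r_dist = r_prox,
                                  fluid = fluid_properties(),
                                  from = 0, to = length) {
  .hp_resistance_si(fluid$viscosity, length, r_prox, r_dist, from, to) *
    .rsi_to_clin
}

#' Flow resistance of a network segment
#'
#' Applies [poiseuille_resistance()] to a segment row of a
#' [build_synthetic_cow()] network (vectorised over rows).
#'
#' @param segment one or more rows of a network `segments` data frame.
#' @param fluid a [fluid_properties()] object.
#' @return Resistance(s) in mmHg s/ml.
#' @export
segment_resistance <- function(segment, fluid = fluid_properties()) {
  vapply(seq_len(nrow(segment)), function(i) {
    poiseuille_resistance(segment$length_m[i], segment$r_prox_m[i],
                          segment$r_dist_m[i], fluid)
  }, numeric(1))
}
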