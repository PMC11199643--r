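#' Carotid stenosis descriptor
#'
#' Describes a focal constriction by its NASCET degree (percent diameter
#' reduction relative to the normal distal lumen), throat geometry and a
#' dimensionless turbulent loss coefficient.
#'
#' @param degree_nascet percent diameter reduction, in `[0, 100)`.
#' @param throat_radius radius of the stenotic throat in m.
#' @param throat_length axial length of the throat in m (>= 0).
#' @param turbulent_loss_coefficient dimensionless coefficient of the
#'   expansion-loss term; the classic constriction-flow value 1.52 is the
#'   default.
#' @return An object of class `stenosis_descriptor`.
#' @seealso [stenosis_from_degree()], [stenosis_pressure_drop()]
#' @export
stenosis_descriptor <- function(degree_nascet, throat_radius, throat_length,
                                turbulent_loss_coefficient = 1.52) {
  if (degree_nascet < 0 || degree_nascet >= 100)
    stop("`degree_nascet` must be in [0, 100)")
  if (throat_radius <= 0) stop("`throat_radius` must be > 0")
  if (throat_length < 0) stop("`throat_length` must be >= 0")
  structure(list(degree_nascet = degree_nascet,
                 throat_radius = throat_radius,
                 throat_length = throat_length,
                 turbulent_loss_coefficient = turbulent_loss_coefficient),
            class = "stenosis_descriptor")
}

#' Build a stenosis descriptor from a NASCET degree
#'
#' The throat radius follows from the normal vessel radius and the percent
#' diameter reduction: `r_throat = r_vessel (1 - degree/100)`.
#'
#' @param degree_nascet percent diameter reduction, in `[0, 100)`.
#' @param vessel_radius normal (distal) vessel radius in m.
#' @param throat_length throat length in m; default 3 mm (a typical focal
#'   plaque throat).
#' @param turbulent_loss_coefficient see [stenosis_descriptor()].
#' @return A `stenosis_descriptor`.
#' @export
stenosis_from_degree <- function(degree_nascet, vessel_radius,
                                 throat_length = 0.003,
                                 turbulent_loss_coefficient = 1.52) {
  stenosis_descriptor(degree_nascet,
                      throat_radius = vessel_radius * (1 - degree_nascet / 100),
                      throat_length = throat_length,
                      turbulent_loss_coefficient = turbulent_loss_coefficient)
}

#' Pressure drop across a stenosis
#'
#' Semi-empirical two-term constriction law of the Young-Tsai type: a
#' viscous Poiseuille term over the throat, linear in flow, plus a
#' turbulent (Borda-Carnot) expansion-loss term quadratic in flow,
#' `dP = 8 mu L_t / (pi r_t^4) Q + K_t (rho/2) (Q/A_0)^2 (A_0/A_t - 1)^2`,
#' where `A_t` is the throat area and `A_0` the normal lumen area implied
#' by the NASCET degree (equivalently `K_t (rho/2) u_t^2 (1 - A_t/A_0)^2`
#' with `u_t` the throat velocity). A zero degree with zero throat length
#' gives zero drop; degree zero in general reduces to the Poiseuille drop
#' of the equivalent straight segment.
#'
#' @param stenosis a [stenosis_descriptor()].
#' @param flow_ml_s flow rate through the stenosis in ml/s (>= 0).
#' @param fluid a [fluid_properties()] object.
#' @return Pressure drop in mmHg (monotone increasing in flow and degree).
#' @export
stenosis_pressure_drop <- function(stenosis, flow_ml_s,
                                   fluid = fluid_properties()) {
  if (any(flow_ml_s < 0)) stop("`flow_ml_s` must be >= 0")
  q_si <- flow_ml_s * 1e-6
  r_t <- stenosis$throat_radius
  a_t <- pi * r_t^2
  r0 <- r_t / (1 - stenosis$degree_nascet / 100)
  a0 <- pi * r0^2
  viscous <- 8 * fluid$viscosity * stenosis$throat_length / (pi * r_t^4) * q_si
  turbulent <- stenosis$turbulent_loss_coefficient * (fluid$density / 2) *
    (q_si / a0)^2 * (a0 / a_t - 1)^2
  (viscous + turbulent) / .pa_per_mmhg
}

# Coefficients of dP = a Q + b Q^2 (clinical units: mmHg per ml/s and
# mmHg per (ml/s)^2).
.stenosis_coefficients <- function(stenosis, fluid = fluid_properties()) {
  r_t <- stenosis$throat_radius
  a_t <- pi * r_t^2
  r0 <- r_t / (1 - stenosis$degree_nascet / 100)
  a0 <- pi * r0^2
  a <- 8 * fluid$viscosity * stenosis$throat_length / (pi * r_t^4) *
    1e-6 / .pa_per_mmhg
  b <- stenosis$turbulent_loss_coefficient * (fluid$density / 2) *
    (1e-6 / a0)^2 * (a0 / a_t - 1)^2 / .pa_per_mmhg
  c(linear = a, quadratic = b)
}

# Effective (flow-dependent) series resistance dP/Q in mmHg.s/ml, used by
# the damped iteration in the forward solver.
.stenosis_effective_resistance <- function(stenosis, flow_ml_s,
                                           fluid = fluid_properties()) {
  co <- .stenosis_coefficients(stenosis, fluid)
  unname(co["linear"] + co["quadratic"] * abs(flow_ml_s))
}
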