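#' Bulk blood flow from pressure drop and vascular resistance
#'
#' The lumped hemodynamic relation `BF = dP / R`: flow through a vascular
#' segment equals the pressure drop across it divided by its resistance.
#'
#' @param pressure_drop Pressure drop across the segment (Pa), > 0.
#' @param resistance Vascular resistance (Pa s / m^3), > 0.
#' @return Volumetric flow rate (m^3/s).
#' @export
bulk_flow <- function(pressure_drop, resistance) {
  check_number(pressure_drop, "pressure_drop", lower = 0, strict_lower = TRUE)
  check_number(resistance, "resistance", lower = 0, strict_lower = TRUE)
  pressure_drop / resistance
}

#' Poiseuille flow through a cylindrical vessel
#'
#' Laminar volumetric flow rate `Q = dP * pi * R^4 / (8 * eta * L)`.  The
#' fourth-power dependence on radius is why modest vessel narrowing
#' produces disproportionate flow loss, the hemodynamic core of ischemia.
#'
#' @param pressure_drop Pressure drop along the vessel (Pa), > 0.
#' @param radius Inner vessel radius (m), > 0.
#' @param viscosity Dynamic viscosity of the fluid (Pa s), > 0.
#' @param length Vessel length (m), > 0.
#' @return Volumetric flow rate (m^3/s).
#' @export
poiseuille_flow <- function(pressure_drop, radius, viscosity, length) {
  check_number(pressure_drop, "pressure_drop", lower = 0, strict_lower = TRUE)
  check_number(radius, "radius", lower = 0, strict_lower = TRUE)
  check_number(viscosity, "viscosity", lower = 0, strict_lower = TRUE)
  check_number(length, "length", lower = 0, strict_lower = TRUE)
  pressure_drop * pi * radius^4 / (8 * viscosity * length)
}

#' Instantaneous pulsatile velocity
#'
#' Raised-sine cardiac modulation around a mean velocity:
#' `v(t) = mean_velocity * (1 + m * sin(2 pi f t))`.  With modulation
#' depth `m < 1` the velocity never goes negative and its average over an
#' integer number of periods equals `mean_velocity`.
#'
#' @param t Time (s); vectorised.
#' @param mean_velocity Cycle-averaged velocity (cm/s), >= 0.
#' @param m Modulation depth, in `[0, 1)`.
#' @param f Pulse frequency (Hz), default 1 (resting heart rate).
#' @return Instantaneous velocity (cm/s), same length as `t`.
#' @export
pulsation_velocity <- function(t, mean_velocity, m, f = 1) {
  check_number(mean_velocity, "mean_velocity", lower = 0)
  check_number(m, "m", lower = 0)
  if (m >= 1)
    stopf("pulse modulation m = %g would produce negative velocities; need m < 1", m)
  check_number(f, "f", lower = 0, strict_lower = TRUE)
  mean_velocity * (1 + m * sin(2 * pi * f * t))
}

#' Field correlation surviving a time step at a given velocity
#'
#' Maps scatterer velocity to speckle-field decorrelation through a
#' single correlation-time scale: `rho = exp(-v * dt / k_v)`, i.e. the
#' field decorrelation time is `tau_c = k_v / v`.  At `v = 0` the speckle
#' is frozen (`rho = 1`); `rho` falls monotonically toward 0 as velocity
#' grows.
#'
#' @param velocity Scatterer velocity (cm/s), >= 0.
#' @param dt Time step (s), > 0.
#' @param decorrelation_scale The scale `k_v` (cm), > 0.
#' @return Correlation coefficient in `[0, 1]`.
#' @export
decorrelation_factor <- function(velocity, dt, decorrelation_scale) {
  check_number(velocity, "velocity", lower = 0)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_number(decorrelation_scale, "decorrelation_scale",
               lower = 0, strict_lower = TRUE)
  exp(-velocity * dt / decorrelation_scale)
}
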