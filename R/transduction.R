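# Piezoresistive transduction: strain -> resistance -> divider voltage.
#
# A skin-mounted silicon-nanomembrane gauge converts facial strain into a
# relative resistance change dR/R; a two-resistor voltage divider converts the
# resistance into a measurable voltage from a fixed supply. These functions
# model that chain and its algebraic inverses.

#' Strain gauge specification
#'
#' Material and circuit constants of one piezoresistive strain gauge. The
#' gauge factor combines a geometric contribution (through the Poisson ratio)
#' with a piezoresistive contribution (through the piezoresistive coefficient
#' and the Young's modulus); the viscoelastic relaxation time is the ratio of
#' the viscosity term to the Young's modulus.
#'
#' @param poisson_ratio Poisson's ratio, dimensionless, in `[0, 0.5]`.
#' @param piezo_coeff piezoresistive coefficient in 1/Pa (dominates the gauge
#'   factor in doped semiconductors; ~0 for metals).
#' @param youngs_modulus Young's modulus in Pa, positive. Single-crystalline
#'   silicon is around 1.6e11 Pa.
#' @param viscosity viscous behaviour term in Pa*s, non-negative.
#' @param base_resistance unstrained gauge resistance R0 in Ohm, positive.
#' @return an object of class `gauge_spec`.
#' @examples
#' g <- gauge_spec(poisson_ratio = 0.27, piezo_coeff = 6.215e-10,
#'                 youngs_modulus = 1.6e11)
#' gauge_factor(g)
#' @export
gauge_spec <- function(poisson_ratio = 0.27,
                       piezo_coeff = 6.215e-10,
                       youngs_modulus = 1.6e11,
                       viscosity = 0,
                       base_resistance = 1000) {
  stop_if_not_scalar_number(poisson_ratio, "poisson_ratio")
  stop_if_not_scalar_number(piezo_coeff, "piezo_coeff")
  stop_if_not_scalar_number(youngs_modulus, "youngs_modulus")
  stop_if_not_scalar_number(viscosity, "viscosity")
  stop_if_not_scalar_number(base_resistance, "base_resistance")
  if (poisson_ratio < 0 || poisson_ratio > 0.5) {
    stop("poisson_ratio must lie in [0, 0.5]", call. = FALSE)
  }
  if (youngs_modulus <= 0) stop("youngs_modulus must be > 0", call. = FALSE)
  if (base_resistance <= 0) stop("base_resistance must be > 0", call. = FALSE)
  if (viscosity < 0) stop("viscosity must be >= 0", call. = FALSE)
  structure(
    list(
      poisson_ratio = poisson_ratio,
      piezo_coeff = piezo_coeff,
      youngs_modulus = youngs_modulus,
      viscosity = viscosity,
      base_resistance = base_resistance
    ),
    class = "gauge_spec"
  )
}

#' Voltage divider circuit
#'
#' The gauge sits on the supply side and a fixed resistor goes to ground; the
#' measured voltage is taken across the fixed resistor. Both conversion
#' directions share this topology, so the round trip is exact.
#'
#' @param supply_voltage supply voltage in V (default 3, the common DAQ supply).
#' @param fixed_resistance fixed resistor in Ohm, positive.
#' @return an object of class `divider_circuit`.
#' @export
divider_circuit <- function(supply_voltage = 3.0, fixed_resistance = 1000) {
  stop_if_not_scalar_number(supply_voltage, "supply_voltage")
  stop_if_not_scalar_number(fixed_resistance, "fixed_resistance")
  if (supply_voltage <= 0) stop("supply_voltage must be > 0", call. = FALSE)
  if (fixed_resistance <= 0) stop("fixed_resistance must be > 0", call. = FALSE)
  structure(
    list(supply_voltage = supply_voltage, fixed_resistance = fixed_resistance),
    class = "divider_circuit"
  )
}

#' Gauge factor
#'
#' G = 1 + 2*nu + pi*E: the relative resistance change per unit strain. The
#' geometric part (1 + 2*nu) caps near 2 for metals; the piezoresistive part
#' pi*E dominates for doped silicon (G on the order of 100).
#'
#' @param spec a [gauge_spec()].
#' @return the dimensionless gauge factor.
#' @export
gauge_factor <- function(spec) {
  stopifnot(inherits(spec, "gauge_spec"))
  1 + 2 * spec$poisson_ratio + spec$piezo_coeff * spec$youngs_modulus
}

#' Viscoelastic relaxation time
#'
#' T = eta / E, in seconds. A stiff material (high E) relaxes fast, which is
#' what makes silicon gauges track rapid articulation.
#'
#' @param spec a [gauge_spec()].
#' @return relaxation time in seconds.
#' @export
relaxation_time <- function(spec) {
  stopifnot(inherits(spec, "gauge_spec"))
  spec$viscosity / spec$youngs_modulus
}

#' Convert a strain trace to relative resistance change
#'
#' Linearised transduction dR/R = G * strain, valid over the elastic range
#' (|strain| <= 0.3) the gauges are operated in.
#'
#' @param spec a [gauge_spec()].
#' @param strain_trace numeric vector of dimensionless strain values.
#' @return numeric vector of dR/R values, same length as the input.
#' @export
strain_to_relative_resistance <- function(spec, strain_trace) {
  stopifnot(inherits(spec, "gauge_spec"), is.numeric(strain_trace))
  if (any(!is.finite(strain_trace))) {
    stop("strain_trace must be finite", call. = FALSE)
  }
  if (any(abs(strain_trace) > 0.3)) {
    stop("strain out of the elastic range |strain| <= 0.3", call. = FALSE)
  }
  gauge_factor(spec) * strain_trace
}

#' Convert gauge resistance to divider voltage
#'
#' V_in = V_s * R_f / (R + R_f), with the gauge in the high-side position.
#'
#' @param circuit a [divider_circuit()].
#' @param R_trace numeric vector of gauge resistances in Ohm, all positive.
#' @return numeric vector of measured voltages in V.
#' @export
resistance_to_voltage <- function(circuit, R_trace) {
  stopifnot(inherits(circuit, "divider_circuit"), is.numeric(R_trace))
  if (any(!is.finite(R_trace)) || any(R_trace <= 0)) {
    stop("all resistances must be finite and > 0", call. = FALSE)
  }
  circuit$supply_voltage * circuit$fixed_resistance /
    (R_trace + circuit$fixed_resistance)
}

#' Convert measured divider voltage back to relative resistance change
#'
#' Inverts [resistance_to_voltage()]: R = R_f * (V_s - V) / V, then
#' dR/R = (R - R0) / R0.
#'
#' @param circuit a [divider_circuit()].
#' @param V_trace numeric vector of voltages, strictly inside (0, V_s).
#' @param R0 unstrained gauge resistance in Ohm.
#' @return numeric vector of dR/R values.
#' @export
voltage_to_relative_resistance <- function(circuit, V_trace, R0) {
  stopifnot(inherits(circuit, "divider_circuit"), is.numeric(V_trace))
  stop_if_not_scalar_number(R0, "R0")
  if (R0 <= 0) stop("R0 must be > 0", call. = FALSE)
  if (any(!is.finite(V_trace)) ||
      any(V_trace <= 0) || any(V_trace >= circuit$supply_voltage)) {
    stop("voltages must lie strictly inside (0, supply_voltage)", call. = FALSE)
  }
  R <- circuit$fixed_resistance * (circuit$supply_voltage - V_trace) / V_trace
  (R - R0) / R0
}

#' Serialize a gauge or divider specification to JSON
#'
#' @param x a [gauge_spec()] or [divider_circuit()].
#' @return a JSON string with the documented config keys.
#' @export
spec_to_json <- function(x) {
  stopifnot(inherits(x, "gauge_spec") || inherits(x, "divider_circuit"))
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
}

#' Deserialize a gauge or divider specification from JSON
#'
#' The key set determines the type: `supply_voltage`/`fixed_resistance` yield a
#' divider, the five gauge keys a gauge.
#'
#' @param json a JSON string produced by [spec_to_json()] or hand-written with
#'   the same keys.
#' @return a [gauge_spec()] or [divider_circuit()].
#' @export
spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  if (all(c("supply_voltage", "fixed_resistance") %in% names(x))) {
    divider_circuit(x$supply_voltage, x$fixed_resistance)
  } else {
    gauge_spec(x$poisson_ratio, x$piezo_coeff, x$youngs_modulus,
               x$viscosity, x$base_resistance)
  }
}
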