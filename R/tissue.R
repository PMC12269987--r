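#' Thermal and perfusion properties of perfused tissue
#'
#' Defaults are the standard liver values: conductivity 0.642 W/m/K, heat
#' capacity 3500 J/kg/K, blood density 1050 kg/m^3, blood heat capacity
#' 3500 J/kg/K, perfusion rate 0.0151 1/s, arterial temperature 37 degC,
#' metabolic heat 10713 W/m^3, and the dual-phase lags measured on liver,
#' tau_q = 5.66 s (heat flux) and tau_t = 22 s (temperature gradient).
#' Tissue density is not part of the standard liver table; 1050 kg/m^3
#' (blood-like) is used.
#'
#' @param density Tissue density rho, kg/m^3.
#' @param heat_capacity Tissue specific heat c, J/kg/K.
#' @param conductivity Tissue thermal conductivity k, W/m/K.
#' @param blood_density rho_b, kg/m^3.
#' @param blood_heat_capacity c_b, J/kg/K.
#' @param perfusion_rate omega_b, 1/s (volumetric blood exchange rate).
#' @param arterial_temperature T_b, degC.
#' @param metabolic_heat Q_m, W/m^3.
#' @param tau_q Heat-flux phase lag, s (SPL and DPL models).
#' @param tau_t Temperature-gradient phase lag, s (DPL model only).
#' @return Object of class `"tissue_properties"`.
#' @export
#' @examples
#' liver <- tissue_properties()
#' liver$conductivity
tissue_properties <- function(density = 1050,
                              heat_capacity = 3500,
                              conductivity = 0.642,
                              blood_density = 1050,
                              blood_heat_capacity = 3500,
                              perfusion_rate = 0.0151,
                              arterial_temperature = 37,
                              metabolic_heat = 10713,
                              tau_q = 5.66,
                              tau_t = 22) {
  check_positive(density, "density")
  check_positive(heat_capacity, "heat_capacity")
  check_positive(conductivity, "conductivity")
  check_positive(blood_density, "blood_density")
  check_positive(blood_heat_capacity, "blood_heat_capacity")
  check_nonneg(perfusion_rate, "perfusion_rate")
  check_nonneg(metabolic_heat, "metabolic_heat")
  check_nonneg(tau_q, "tau_q")
  check_nonneg(tau_t, "tau_t")
  structure(
    list(density = density, heat_capacity = heat_capacity,
         conductivity = conductivity, blood_density = blood_density,
         blood_heat_capacity = blood_heat_capacity,
         perfusion_rate = perfusion_rate,
         arterial_temperature = arterial_temperature,
         metabolic_heat = metabolic_heat, tau_q = tau_q, tau_t = tau_t),
    class = "tissue_properties"
  )
}

#' Perfusion heat-sink coefficient omega_b rho_b c_b
#'
#' @param props A [tissue_properties()].
#' @return W/m^3/K.
#' @export
perfusion_coefficient <- function(props) {
  stopifnot(inherits(props, "tissue_properties"))
  props$perfusion_rate * props$blood_density * props$blood_heat_capacity
}

#' Uniform steady-state temperature of perfused tissue
#'
#' With no spatial gradients the bioheat balance reduces to
#' `T = T_b + (Q_m + q_total) / (omega_b rho_b c_b)`. This is the ceiling
#' an insulated, uniformly heated tissue approaches, and an upper bound for
#' the center of a finite heated region.
#'
#' @param props A [tissue_properties()].
#' @param q_total Additional uniform volumetric source (e.g. nanoparticle
#'   heating) in W/m^3.
#' @return Temperature in degC.
#' @export
#' @examples
#' steady_state_uniform(tissue_properties())            # metabolic only
#' steady_state_uniform(tissue_properties(), 4.77978e5) # heated ceiling
steady_state_uniform <- function(props, q_total = 0) {
  stopifnot(inherits(props, "tissue_properties"))
  check_nonneg(q_total, "q_total")
  w <- perfusion_coefficient(props)
  if (w <= 0) {
    stop_invalid("no finite uniform steady state when perfusion is zero")
  }
  props$arterial_temperature + (props$metabolic_heat + q_total) / w
}
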