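#' Describe a magnetic nanoparticle species
#'
#' Bundles the geometric and magnetic constants of one (possibly core-shell)
#' nanoparticle species used by the relaxation and heating calculations.
#'
#' @param name Text label, e.g. `"Zn0.4Co0.6Fe2O4@Zn0.4Mn0.6Fe2O4"`.
#' @param core_diameter Magnetic core diameter D in m.
#' @param coating_thickness Non-magnetic surfactant/coating thickness delta
#'   in m; enters only the hydrodynamic volume.
#' @param domain_magnetization Single-domain magnetization Md in A/m.
#' @param bulk_saturation Bulk saturation magnetization Msb in A/m, used by
#'   [dead_layer_saturation()]; optional.
#' @param dead_layer Magnetically disordered surface-layer thickness d in m;
#'   optional, must satisfy `d < core_diameter / 2` when given.
#' @param anisotropy Effective magnetic anisotropy constant K in J/m^3.
#' @param attempt_time Neel attempt (spin relaxation) time tau0 in s.
#' @param density Nanoparticle mass density in kg/m^3. Ferrite-class default.
#' @param volume_fraction Volume fraction phi of nanoparticles in the
#'   nanofluid, dimensionless in (0, 1).
#' @param measured_slp Measured specific loss power in W/g, as reported by
#'   calorimetry; optional.
#'
#' @return An object of class `"nanoparticle_spec"` (named list).
#' @seealso [field_spec()], [carrier_fluid()], [relaxation_times()]
#' @export
#' @examples
#' np <- nanoparticle_spec()
#' np$core_diameter
nanoparticle_spec <- function(name = "magnetite-like",
                              core_diameter = 15e-9,
                              coating_thickness = 1e-9,
                              domain_magnetization = 6.3e5,
                              bulk_saturation = NULL,
                              dead_layer = NULL,
                              anisotropy = 1.5e4,
                              attempt_time = 1e-9,
                              density = 5.18e3,
                              volume_fraction = 0.0013,
                              measured_slp = NULL) {
  check_positive(core_diameter, "core_diameter")
  check_nonneg(coating_thickness, "coating_thickness")
  check_positive(domain_magnetization, "domain_magnetization")
  check_positive(anisotropy, "anisotropy")
  check_positive(attempt_time, "attempt_time")
  check_positive(density, "density")
  check_positive(volume_fraction, "volume_fraction")
  if (volume_fraction >= 1) {
    stop_invalid("`volume_fraction` must lie strictly between 0 and 1")
  }
  if (!is.null(bulk_saturation)) check_positive(bulk_saturation, "bulk_saturation")
  if (!is.null(dead_layer)) {
    check_nonneg(dead_layer, "dead_layer")
    if (dead_layer >= core_diameter / 2) {
      stop_invalid("`dead_layer` must be smaller than the core radius")
    }
  }
  if (!is.null(measured_slp)) check_positive(measured_slp, "measured_slp")
  structure(
    list(
      name = as.character(name),
      core_diameter = core_diameter,
      coating_thickness = coating_thickness,
      domain_magnetization = domain_magnetization,
      bulk_saturation = bulk_saturation,
      dead_layer = dead_layer,
      anisotropy = anisotropy,
      attempt_time = attempt_time,
      density = density,
      volume_fraction = volume_fraction,
      measured_slp = measured_slp
    ),
    class = "nanoparticle_spec"
  )
}

#' Describe the applied AC magnetic field
#'
#' @param amplitude Field amplitude H0 in A/m. Default 37.4 kA/m.
#' @param frequency Field frequency f in Hz. Default 500 kHz.
#' @return Object of class `"field_spec"`.
#' @export
#' @examples
#' field_spec(amplitude = 3.73e4, frequency = 5e5)
field_spec <- function(amplitude = 3.74e4, frequency = 5e5) {
  check_positive(amplitude, "amplitude")
  check_positive(frequency, "frequency")
  structure(list(amplitude = amplitude, frequency = frequency),
            class = "field_spec")
}

#' Describe the carrier fluid / thermal environment of the nanoparticles
#'
#' @param viscosity Dynamic viscosity eta of the nanofluid in Pa s.
#' @param temperature Absolute temperature T in K. Defaults to body
#'   temperature (310 K).
#' @return Object of class `"carrier_fluid"`.
#' @export
carrier_fluid <- function(viscosity = 1.22e-3, temperature = 310) {
  check_positive(viscosity, "viscosity")
  check_positive(temperature, "temperature")
  structure(list(viscosity = viscosity, temperature = temperature),
            class = "carrier_fluid")
}

#' @export
#' @method print nanoparticle_spec
print.nanoparticle_spec <- function(x, ...) {
  cat("<nanoparticle_spec>", x$name, "\n")
  cat(sprintf("  core D = %.3g nm, coating = %.3g nm\n",
              x$core_diameter * 1e9, x$coating_thickness * 1e9))
  cat(sprintf("  Md = %.3g A/m, K = %.3g J/m^3, tau0 = %.3g s\n",
              x$domain_magnetization, x$anisotropy, x$attempt_time))
  cat(sprintf("  phi = %.3g, density = %.3g kg/m^3\n",
              x$volume_fraction, x$density))
  if (!is.null(x$measured_slp)) {
    cat(sprintf("  measured SLP = %.5g W/g\n", x$measured_slp))
  }
  invisible(x)
}
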