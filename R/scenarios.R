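# Reference tumor heat source (W/m^3): volumetric dissipation of the
# Zn0.4Co0.6Fe2O4@Zn0.4Mn0.6Fe2O4 core-shell species in the liver scenario.
.q_np_reference <- 4.77978e5
.reference_slp <- 3866  # W/g, the catalogue species behind .q_np_reference

#' Catalogue of measured core-shell nanoparticle heating powers
#'
#' Loads the shipped table of calorimetric specific loss powers for the
#' four ferrite species (one single-phase, three core-shell) measured at
#' equal radius under the same AC field. The exposure safety product
#' `f * H0` is computed from the amplitude and frequency columns.
#'
#' @param file Path to a catalogue YAML; default the shipped one.
#' @return data.frame with columns `name`, `core`, `shell`, `H0` (A/m),
#'   `f` (Hz), `slp` (W/g), `f_H0` (A/(m s)).
#' @export
#' @examples
#' cat <- nanoparticle_catalogue()
#' cat[order(-cat$slp), c("name", "slp")]
nanoparticle_catalogue <- function(file = system.file("extdata",
                                                      "catalogue.yaml",
                                                      package = "nanotherm")) {
  if (!nzchar(file) || !file.exists(file)) {
    stop("catalogue file not found: ", file)
  }
  raw <- yaml::read_yaml(file)
  if (is.null(raw$nanoparticles) || length(raw$nanoparticles) == 0) {
    stop("catalogue file has no `nanoparticles` records: ", file)
  }
  recs <- lapply(raw$nanoparticles, function(r) {
    data.frame(name = r$name, core = r$core,
               shell = if (is.null(r$shell)) NA_character_ else r$shell,
               H0 = r$H0_kA_m * 1e3, f = r$f_kHz * 1e3, slp = r$slp_w_g)
  })
  out <- do.call(rbind, recs)
  out$f_H0 <- out$f * out$H0
  out
}

scenario_names <- c("fig2_timecourse", "fig3_profile", "fig4_probes",
                    "fig5_profiles", "fig7_np_comparison",
                    "fig9_model_comparison", "fig10_profile_comparison",
                    "fig11_surfaces")

mm <- function(v) v * 1e-3

#' Build a named liver-hyperthermia scenario
#'
#' Returns a complete, runnable configuration for each of the standard
#' experiments of the study: center-probe time course, axial temperature
#' profiles, the six-probe family at x = 0, 2, ..., 10 mm, nanoparticle
#' comparisons (source scaled linearly by catalogue SLP), and the
#' Fourier/SPL/DPL model comparison at the 1.5 mm probe over 600 s.
#'
#' All scenarios share the default liver geometry: a 40 x 40 mm domain
#' with a 10 mm half-width heated slab (needle-track injection geometry),
#' Robin outer boundary (h = 200 W/K/m^2, 37 degC), uniform initial 37
#' degC, and the reference tumor source 4.77978e5 W/m^3.
#'
#' @param name One of `"fig2_timecourse"`, `"fig3_profile"`,
#'   `"fig4_probes"`, `"fig5_profiles"`, `"fig7_np_comparison"`,
#'   `"fig9_model_comparison"`, `"fig10_profile_comparison"`,
#'   `"fig11_surfaces"`.
#' @param ... Overrides for any scenario field (e.g. `dx`, `dt`,
#'   `duration`, `tumor_shape`, `tumor_radius`) — mainly for coarse/quick
#'   runs.
#' @return Object of class `"nanotherm_scenario"`.
#' @export
#' @examples
#' sc <- build_scenario("fig9_model_comparison", dx = 2e-3, dt = 5)
#' sc$models
build_scenario <- function(name, ...) {
  if (!name %in% scenario_names) {
    stop_invalid("unknown scenario `", name, "`; available: ",
                 paste(scenario_names, collapse = ", "))
  }
  cat <- nanoparticle_catalogue()
  zn <- cat[which.max(cat$slp), ]
  base <- list(
    name = name,
    nanoparticle = as.list(zn[, c("name", "core", "shell", "H0", "f", "slp")]),
    q_np_source = "paper_constant",
    q_np_value = .q_np_reference,
    tissue = unclass(tissue_properties()),
    x_half = 0.02, y_half = 0.02, dx = 0.5e-3, dy = 0.5e-3,
    tumor_shape = "slab", tumor_radius = 0.01,
    boundary = "robin", h = 200, T_ext = 37,
    models = "dpl",
    probes = list(c(0, 0)),
    snapshot_minutes = numeric(0),
    duration = 3600, dt = 0.5, T0 = 37, source_ramp = 0
  )
  tweak <- switch(
    name,
    fig2_timecourse = list(),
    fig3_profile = list(snapshot_minutes = 60, probes = list()),
    fig4_probes = list(probes = lapply(mm(c(0, 2, 4, 6, 8, 10)),
                                       function(x) c(x, 0))),
    fig5_profiles = list(snapshot_minutes = c(0.5, 2, 4, 6, 8, 10),
                         probes = list(), duration = 600),
    fig7_np_comparison = list(q_np_source = "from_slp"),
    fig9_model_comparison = list(models = c("pennes", "spl", "dpl"),
                                 probes = list(c(mm(1.5), 0)),
                                 duration = 600),
    fig10_profile_comparison = list(models = c("pennes", "spl", "dpl"),
                                    snapshot_minutes = c(5, 10),
                                    probes = list(c(mm(1.5), 0)),
                                    duration = 600),
    fig11_surfaces = list(models = c("pennes", "spl", "dpl"),
                          snapshot_minutes = 60, probes = list())
  )
  base[names(tweak)] <- tweak
  dots <- list(...)
  bad <- setdiff(names(dots), names(base))
  if (length(bad)) stop_invalid("unknown scenario fields: ",
                                paste(bad, collapse = ", "))
  base[names(dots)] <- dots
  validate_scenario(structure(base, class = "nanotherm_scenario"))
}

#' Validate a scenario configuration
#'
#' Checks the type invariants: positive source for heated scenarios,
#' non-empty model list, consistent grid parameters, probes inside the
#' domain.
#'
#' @param sc A `"nanotherm_scenario"`.
#' @return The scenario, invisibly classed, or an error.
#' @export
validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "nanotherm_scenario"))
  if (length(sc$models) == 0) stop_invalid("scenario has no models")
  if (!all(sc$models %in% c("pennes", "spl", "dpl"))) {
    stop_invalid("models must be among pennes, spl, dpl")
  }
  if (sc$q_np_value <= 0) stop_invalid("heated scenario needs q_np_value > 0")
  if (sc$tumor_shape != "none" && sc$tumor_radius <= 0) {
    stop_invalid("tumor_radius must be positive")
  }
  check_positive(sc$dx, "dx"); check_positive(sc$dt, "dt")
  if (sc$duration < sc$dt) stop_invalid("duration shorter than one step")
  do.call(tissue_properties, sc$tissue)  # re-validates tissue fields
  for (p in sc$probes) {
    if (abs(p[1]) > sc$x_half || abs(p[2]) > sc$y_half) {
      stop_invalid("probe outside domain")
    }
  }
  sc
}

#' Materialise the grid of a scenario
#'
#' @param sc A `"nanotherm_scenario"`.
#' @return A [simulation_grid()].
#' @export
scenario_grid <- function(sc) {
  stopifnot(inherits(sc, "nanotherm_scenario"))
  simulation_grid(x_half = sc$x_half, y_half = sc$y_half,
                  dx = sc$dx, dy = sc$dy,
                  tumor_shape = sc$tumor_shape,
                  tumor_radius = sc$tumor_radius,
                  boundary = sc$boundary, h = sc$h, T_ext = sc$T_ext)
}

#' Write / read a scenario as YAML
#'
#' The on-disk form round-trips exactly: serialize, parse, serialize is
#' byte-identical.
#'
#' @param sc A `"nanotherm_scenario"`.
#' @param path File path.
#' @return `read_scenario()` returns the scenario; `write_scenario()` its
#'   path, invisibly.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "nanotherm_scenario"))
  writeLines(yaml::as.yaml(unclass(sc), precision = 15), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_scenario(structure(raw, class = "nanotherm_scenario"))
}

#' Randomized parameter perturbations of a scenario
#'
#' Draws `n` reproducible copies of `base` with selected parameters
#' multiplied by independent uniform factors in `[1 - r, 1 + r]`.
#' Perturbable parameters are the tissue fields (by name, e.g.
#' `conductivity`, `perfusion_rate`) and `q_np_value`. The global RNG
#' state is left untouched.
#'
#' @param base A `"nanotherm_scenario"`.
#' @param ranges Named list of relative half-widths in `[0, 1)`, e.g.
#'   `list(conductivity = 0.1, perfusion_rate = 0.1)`.
#' @param n Number of draws.
#' @param seed Integer seed; the stream is a pure function of it.
#' @return List of `n` validated scenarios; each carries its draw in
#'   `$perturbation`.
#' @export
#' @examples
#' base <- build_scenario("fig2_timecourse", dx = 4e-3, dt = 5)
#' draws <- perturb_scenario(base, list(perfusion_rate = 0.1), n = 3,
#'                           seed = 42)
#' sapply(draws, function(d) d$tissue$perfusion_rate)
perturb_scenario <- function(base, ranges, n = 1, seed = 1) {
  stopifnot(inherits(base, "nanotherm_scenario"))
  if (length(ranges) && (is.null(names(ranges)) || any(names(ranges) == ""))) {
    stop_invalid("`ranges` must be a fully named list")
  }
  allowed <- c(names(base$tissue), "q_np_value")
  bad <- setdiff(names(ranges), allowed)
  if (length(bad)) stop_invalid("cannot perturb: ", paste(bad, collapse = ", "))
  for (r in ranges) {
    if (r < 0 || r >= 1) stop_invalid("relative ranges must be in [0, 1)")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    sc <- base
    draw <- list()
    for (nm in names(ranges)) {
      fac <- stats::runif(1, 1 - ranges[[nm]], 1 + ranges[[nm]])
      draw[[nm]] <- fac
      if (nm == "q_np_value") sc$q_np_value <- sc$q_np_value * fac
      else sc$tissue[[nm]] <- sc$tissue[[nm]] * fac
    }
    sc$perturbation <- list(seed = seed, draw_index = i, factors = draw)
    validate_scenario(sc)
  })
}

#' @export
#' @method print nanotherm_scenario
print.nanotherm_scenario <- function(x, ...) {
  cat("<nanotherm_scenario>", x$name, "\n")
  cat(sprintf("  models: %s; duration %g s, dt %g s, dx %g mm\n",
              paste(x$models, collapse = ", "), x$duration, x$dt,
              x$dx * 1e3))
  cat(sprintf("  tumor: %s, half-width %g mm; Q_np = %.6g W/m^3 (%s)\n",
              x$tumor_shape, x$tumor_radius * 1e3, x$q_np_value,
              x$q_np_source))
  cat(sprintf("  nanoparticle: %s (SLP %.5g W/g)\n",
              x$nanoparticle$name, x$nanoparticle$slp))
  invisible(x)
}
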