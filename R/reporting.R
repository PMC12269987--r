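scenario_probe_matrix <- function(sc) {
  if (length(sc$probes) == 0) return(NULL)
  do.call(rbind, sc$probes)
}

solve_scenario_model <- function(sc, model, q_np = sc$q_np_value) {
  grid <- scenario_grid(sc)
  solve_bioheat(grid, do.call(tissue_properties, sc$tissue), model = model,
                q_np = q_np, dt = sc$dt, t_end = sc$duration, T0 = sc$T0,
                source_ramp = sc$source_ramp,
                probes = scenario_probe_matrix(sc),
                snapshot_times = sc$snapshot_minutes * 60)
}

field_to_table <- function(grid, field) {
  data.frame(x = rep(grid$x, times = grid$ny),
             y = rep(grid$y, each = grid$nx),
             T = as.numeric(field))
}

#' Run a scenario and (optionally) write its output tables
#'
#' Executes every model the scenario requests, records probe time series,
#' field snapshots and the spacetime maximum, and — when `output_dir` is
#' given — writes one probe CSV and one long-format snapshot CSV per
#' model plus a JSON summary. Runs are deterministic: identical
#' configurations produce bit-identical tables. Resolved parameters are
#' logged to stderr.
#'
#' @param sc A scenario from [build_scenario()] / [read_scenario()].
#' @param output_dir Output directory, created if needed; `NULL` (default)
#'   writes nothing.
#' @param quiet Suppress the stderr parameter log.
#' @return Object of class `"nanotherm_run"`: list with the scenario, one
#'   [solve_bioheat()] solution per model, a `summary` data.frame (model,
#'   T_max, t_at_max, x, y) and the written `files`.
#' @export
#' @examples
#' sc <- build_scenario("fig2_timecourse", dx = 4e-3, dt = 5, duration = 60)
#' run <- run_scenario(sc, quiet = TRUE)
#' run$summary
run_scenario <- function(sc, output_dir = NULL, quiet = FALSE) {
  sc <- validate_scenario(sc)
  if (!quiet) {
    message(sprintf(
      "nanotherm: scenario %s | models %s | grid %g mm / dt %g s | Q_np %.6g W/m^3 | %g s",
      sc$name, paste(sc$models, collapse = "+"), sc$dx * 1e3, sc$dt,
      sc$q_np_value, sc$duration))
  }
  solutions <- lapply(sc$models, function(m) solve_scenario_model(sc, m))
  names(solutions) <- sc$models
  summary <- do.call(rbind, lapply(sc$models, function(m) {
    mx <- solutions[[m]]$max
    data.frame(model = m, T_max = mx$value, t_at_max = mx$time,
               x = mx$location[["x"]], y = mx$location[["y"]])
  }))
  files <- character(0)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (m in sc$models) {
      sol <- solutions[[m]]
      if (!is.null(sol$probes)) {
        f <- file.path(output_dir, paste0("probes_", m, ".csv"))
        utils::write.csv(sol$probes, f, row.names = FALSE)
        files <- c(files, f)
      }
      for (nm in names(sol$snapshots)) {
        f <- file.path(output_dir, paste0("field_", m, "_t", nm, "s.csv"))
        utils::write.csv(field_to_table(sol$grid, sol$snapshots[[nm]]), f,
                         row.names = FALSE)
        files <- c(files, f)
      }
    }
    f <- file.path(output_dir, "summary.json")
    jsonlite::write_json(
      list(scenario = sc$name, models = sc$models,
           q_np_value = sc$q_np_value,
           resolved = unclass(sc)[c("dx", "dt", "duration", "tumor_shape",
                                    "tumor_radius", "boundary", "h")],
           summary = summary),
      f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, f)
  }
  structure(list(scenario = sc, solutions = solutions, summary = summary,
                 files = files),
            class = "nanotherm_run")
}

#' Compare conduction models on one scenario
#'
#' Runs every requested model on the identical grid and source and ranks
#' them by spacetime maximum temperature. With the liver lags
#' (tau_q = 5.66 s, tau_t = 22 s) the dual-phase-lag model predicts a
#' lower maximum than both single-phase-lag and Fourier/Pennes.
#'
#' @param sc A scenario requesting at least two models (e.g.
#'   `build_scenario("fig9_model_comparison")`).
#' @param quiet Suppress the stderr log.
#' @return data.frame sorted by increasing `T_max`, with attribute
#'   `"dpl_coolest"` (logical) when DPL is among the models.
#' @export
compare_models <- function(sc, quiet = TRUE) {
  run <- run_scenario(sc, quiet = quiet)
  out <- run$summary[order(run$summary$T_max), ]
  rownames(out) <- NULL
  if ("dpl" %in% out$model) {
    attr(out, "dpl_coolest") <- out$model[1] == "dpl"
  }
  out
}

#' Compare nanoparticle species on one scenario
#'
#' Runs the scenario's first model once per catalogue species, scaling the
#' tumor source linearly with the measured SLP at fixed mass
#' concentration: `Q_np,i = Q_ref * SLP_i / SLP_ref`, where the reference
#' is the Zn-doped core-shell species with its literature source strength.
#' By monotonicity of the linear solver the maximum-temperature ordering
#' equals the SLP ordering.
#'
#' @param sc A scenario (its nanoparticle record is replaced per species).
#' @param catalogue data.frame from [nanoparticle_catalogue()].
#' @param quiet Suppress the stderr log.
#' @return data.frame (one row per species, sorted by decreasing `T_max`)
#'   with columns `name`, `slp` (W/g), `q_np` (W/m^3), `T_max` (degC).
#' @export
compare_nanoparticles <- function(sc, catalogue = nanoparticle_catalogue(),
                                  quiet = TRUE) {
  sc <- validate_scenario(sc)
  model <- sc$models[1]
  ref_slp <- .reference_slp
  rows <- lapply(seq_len(nrow(catalogue)), function(i) {
    rec <- catalogue[i, ]
    q_np <- .q_np_reference * rec$slp / ref_slp
    if (!quiet) message(sprintf("nanotherm: %s Q_np = %.6g W/m^3",
                                rec$name, q_np))
    sol <- solve_scenario_model(sc, model, q_np = q_np)
    data.frame(name = rec$name, slp = rec$slp, q_np = q_np,
               T_max = sol$max$value)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$T_max), ]
  rownames(out) <- NULL
  out
}

#' @export
#' @method print nanotherm_run
print.nanotherm_run <- function(x, ...) {
  cat("<nanotherm_run>", x$scenario$name, "\n")
  print(x$summary, row.names = FALSE)
  if (length(x$files)) cat("  files:", length(x$files), "written\n")
  invisible(x)
}

#' Quick-look plots
#'
#' Base-graphics convenience views: probe time series (`plot`) and a
#' filled image of the final temperature field (`image`).
#'
#' @param x A [solve_bioheat()] result.
#' @param ... Passed to the underlying graphics call.
#' @return Invisibly, `x`.
#' @export
plot.bioheat_solution <- function(x, ...) {
  if (is.null(x$probes)) {
    graphics::image(x$grid$x * 1e3, x$grid$y * 1e3, x$final,
                    xlab = "x (mm)", ylab = "y (mm)",
                    main = paste("final T (degC),", x$model), ...)
  } else {
    graphics::matplot(x$probes$t / 60, x$probes[, -1, drop = FALSE],
                      type = "l", lty = 1, xlab = "t (min)",
                      ylab = "T (degC)", main = x$model, ...)
  }
  invisible(x)
}

#' @rdname plot.bioheat_solution
#' @export
#' @method image bioheat_solution
image.bioheat_solution <- function(x, ...) {
  graphics::image(x$grid$x * 1e3, x$grid$y * 1e3, x$final,
                  xlab = "x (mm)", ylab = "y (mm)", ...)
  invisible(x)
}
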