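#' Nanoparticle source ramp and its exact time derivative
#'
#' The heat source is switched on at t = 0. By default it is a step held
#' constant afterwards, making its time derivative identically zero for
#' t > 0 (the lagged-source term `tau_q dQ/dt` then vanishes). With
#' `ramp > 0` the source instead rises linearly over `[0, ramp]` and the
#' derivative is the exact ramp slope there, zero after.
#'
#' @param grid A [simulation_grid()].
#' @param q_np Plateau source strength (scalar, W/m^3) or full source
#'   matrix; see [source_map()].
#' @param t Time in s.
#' @param ramp Ramp duration in s (0 = step).
#' @return `source_at_time()`: nx-by-ny source matrix (W/m^3);
#'   `source_time_derivative()`: nx-by-ny derivative matrix (W/m^3/s).
#' @export
source_at_time <- function(grid, q_np, t, ramp = 0) {
  q <- source_map(grid, q_np)
  if (ramp > 0 && t < ramp) q * max(t, 0) / ramp else q
}

#' @rdname source_at_time
#' @export
source_time_derivative <- function(grid, q_np, t, ramp = 0) {
  q <- source_map(grid, q_np)
  if (ramp > 0 && t > 0 && t <= ramp) q / ramp else q * 0
}

model_lags <- function(model, props) {
  switch(model,
         pennes = c(tau_q = 0, tau_t = 0),
         spl = c(tau_q = props$tau_q, tau_t = 0),
         dpl = c(tau_q = props$tau_q, tau_t = props$tau_t),
         stop_invalid("unknown model `", model, "`"))
}

#' Solve a bioheat equation on a 2D grid
#'
#' Advances the dual-phase-lag bioheat equation
#' \deqn{\rho c \tau_q T_{tt} + (\rho c + \tau_q \omega_b \rho_b c_b
#'   - \tau_t k \nabla^2) T_t = k \nabla^2 T
#'   - \omega_b \rho_b c_b (T - T_b) + Q_m + Q_{np}
#'   + \tau_q (\dot Q_m + \dot Q_{np})}
#' with a three-time-level fully implicit scheme: the second time
#' derivative is the standard central three-level difference, the first
#' derivative is backward, spatial operators are taken at the new level,
#' and the mixed `tau_t k lap(T_t)` term is applied to the backward time
#' difference. One sparse symmetric positive-definite solve per step; the
#' Cholesky factor is computed once and reused. The first step is
#' bootstrapped with `T^{-1} = T^0` (zero initial heating rate).
#'
#' `model = "pennes"` and `model = "spl"` are the same discretisation with
#' `tau_q = tau_t = 0` and `tau_t = 0` respectively, so the lag models
#' reduce exactly to their parabolic/hyperbolic limits.
#'
#' @param grid A [simulation_grid()].
#' @param props A [tissue_properties()].
#' @param model `"pennes"`, `"spl"` or `"dpl"`.
#' @param q_np Nanoparticle source plateau (scalar W/m^3, applied inside
#'   the tumor mask) or a full nx-by-ny matrix.
#' @param dt Time step in s.
#' @param t_end Final time in s.
#' @param T0 Uniform initial temperature, degC (default 37).
#' @param source_ramp Linear switch-on time of `q_np` in s (0 = step).
#' @param probes n-by-2 matrix of probe coordinates in m, or `NULL`.
#'   Probe temperatures are recorded at every step by bilinear
#'   interpolation.
#' @param snapshot_times Times (s) at which to store the full field; each
#'   is matched to the nearest time step.
#' @param forcing Optional `function(t)` returning a full nx-by-ny source
#'   matrix (W/m^3) that replaces the `q_np`/ramp machinery — used for
#'   manufactured-solution verification.
#' @param forcing_dot Optional `function(t)` with the time derivative of
#'   `forcing`, entering through the `tau_q dQ/dt` term. Default zero.
#' @return Object of class `"bioheat_solution"`: final field (`final`),
#'   probe series (`probes`, data.frame with column `t` then one column per
#'   probe), stored `snapshots` (named by time), running spacetime maximum
#'   (`max`), and the resolved parameters.
#' @export
#' @examples
#' g <- simulation_grid(dx = 2e-3, dy = 2e-3)
#' sol <- solve_bioheat(g, tissue_properties(), model = "dpl",
#'                      q_np = 4.77978e5, dt = 2, t_end = 60,
#'                      probes = rbind(c(0, 0)))
#' max_temperature(sol)$value
solve_bioheat <- function(grid, props, model = c("dpl", "spl", "pennes"),
                          q_np = 0, dt = 0.5, t_end = 3600, T0 = 37,
                          source_ramp = 0, probes = NULL,
                          snapshot_times = numeric(0),
                          forcing = NULL, forcing_dot = NULL) {
  stopifnot(inherits(grid, "simulation_grid"),
            inherits(props, "tissue_properties"))
  model <- match.arg(model)
  check_positive(dt, "dt")
  if (t_end < dt) stop_invalid("`t_end` must be at least one time step")
  lags <- model_lags(model, props)
  tau_q <- lags[["tau_q"]]; tau_t <- lags[["tau_t"]]

  n <- grid$nx * grid$ny
  op <- assemble_diffusion(grid, props)
  M <- op$M; g <- op$g
  rc <- props$density * props$heat_capacity
  w <- perfusion_coefficient(props)
  a2 <- rc * tau_q / dt^2
  a1 <- (rc + tau_q * w) / dt
  A <- Matrix::forceSymmetric(
    Matrix::Diagonal(n, a2 + a1 + w) - (1 + tau_t / dt) * M
  )
  ch <- Matrix::Cholesky(A, LDL = FALSE)

  if (is.null(forcing)) {
    q_full <- source_map(grid, q_np)
    src <- function(t) {
      if (source_ramp > 0 && t < source_ramp) q_full * max(t, 0) / source_ramp
      else q_full
    }
    src_dot <- function(t) {
      if (source_ramp > 0 && t > 0 && t <= source_ramp) q_full / source_ramp
      else q_full * 0
    }
  } else {
    src <- forcing
    src_dot <- if (is.null(forcing_dot)) function(t) matrix(0, grid$nx, grid$ny)
               else forcing_dot
  }

  W <- NULL
  if (!is.null(probes)) {
    pw <- probe_weights(grid, probes)
    W <- Matrix::sparseMatrix(
      i = rep(seq_along(pw), each = 4L),
      j = unlist(lapply(pw, `[[`, "cells")),
      x = unlist(lapply(pw, `[[`, "weights")),
      dims = c(length(pw), n)
    )
  }

  nsteps <- round(t_end / dt)
  snap_steps <- unique(pmin(pmax(round(snapshot_times / dt), 0L), nsteps))
  snapshots <- list()

  Tn <- rep(T0, n)
  Tnm1 <- Tn
  if (0L %in% snap_steps) snapshots[["0"]] <- matrix(Tn, grid$nx, grid$ny)
  probe_mat <- if (!is.null(W)) {
    out <- matrix(NA_real_, nsteps + 1L, nrow(W))
    out[1L, ] <- as.numeric(W %*% Tn)
    out
  }
  run_max <- list(value = T0, time = 0, cell = 1L)
  const_b <- w * props$arterial_temperature + props$metabolic_heat + g

  for (m in seq_len(nsteps)) {
    t_new <- m * dt
    rhs <- a2 * (2 * Tn - Tnm1) + a1 * Tn + const_b +
      as.numeric(src(t_new)) + tau_q * as.numeric(src_dot(t_new))
    if (tau_t > 0) rhs <- rhs - (tau_t / dt) * as.numeric(M %*% Tn)
    Tnew <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
    if (any(!is.finite(Tnew))) {
      stop("bioheat solve produced non-finite temperatures at t = ",
           t_new, " s (model ", model, ")")
    }
    Tnm1 <- Tn
    Tn <- Tnew
    if (!is.null(W)) probe_mat[m + 1L, ] <- as.numeric(W %*% Tn)
    step_max <- which.max(Tn)
    # sub-nanokelvin increases are roundoff, not a new spacetime maximum
    if (Tn[step_max] > run_max$value + 1e-9) {
      run_max <- list(value = Tn[step_max], time = t_new, cell = step_max)
    }
    if (m %in% snap_steps) {
      snapshots[[format(t_new)]] <- matrix(Tn, grid$nx, grid$ny)
    }
  }

  ci <- run_max$cell
  loc <- c(x = grid$x[(ci - 1L) %% grid$nx + 1L],
           y = grid$y[(ci - 1L) %/% grid$nx + 1L])
  probes_df <- NULL
  if (!is.null(W)) {
    probes_df <- data.frame(t = seq(0, by = dt, length.out = nsteps + 1L))
    pm <- as.data.frame(probe_mat)
    names(pm) <- paste0("p", seq_len(ncol(pm)))
    probes_df <- cbind(probes_df, pm)
  }
  structure(
    list(final = matrix(Tn, grid$nx, grid$ny),
         previous = matrix(Tnm1, grid$nx, grid$ny),
         probes = probes_df, probe_points = probes,
         snapshots = snapshots,
         max = list(value = run_max$value, time = run_max$time,
                    location = loc),
         grid = grid, props = props, model = model, dt = dt, t_end = t_end,
         tau_q = tau_q, tau_t = tau_t, source_ramp = source_ramp),
    class = "bioheat_solution"
  )
}

#' Spacetime maximum temperature of a solve
#'
#' @param sol A [solve_bioheat()] result.
#' @return List with `value` (degC), `time` (s) and `location` (m).
#' @export
max_temperature <- function(sol) {
  stopifnot(inherits(sol, "bioheat_solution"))
  sol$max
}

#' Probe time series of a solve as a long table
#'
#' @param sol A [solve_bioheat()] result obtained with `probes`.
#' @return data.frame with columns `t`, `x`, `y`, `T`.
#' @export
probe_series <- function(sol) {
  stopifnot(inherits(sol, "bioheat_solution"))
  if (is.null(sol$probes)) stop_invalid("solution was run without probes")
  k <- nrow(sol$probe_points)
  data.frame(
    t = rep(sol$probes$t, k),
    x = rep(sol$probe_points[, 1], each = nrow(sol$probes)),
    y = rep(sol$probe_points[, 2], each = nrow(sol$probes)),
    T = unlist(sol$probes[, -1, drop = FALSE], use.names = FALSE)
  )
}

#' First time a probe reaches a threshold temperature
#'
#' Scans a probe column of the stored time series for the first crossing of
#' `threshold` and linearly interpolates between the bracketing steps.
#'
#' @param sol A [solve_bioheat()] result obtained with `probes`.
#' @param threshold Temperature in degC.
#' @param probe Probe index (column), default 1.
#' @return Crossing time in s, or `NA` if the threshold is never reached.
#' @export
time_to_threshold <- function(sol, threshold, probe = 1L) {
  stopifnot(inherits(sol, "bioheat_solution"))
  if (is.null(sol$probes)) stop_invalid("solution was run without probes")
  v <- sol$probes[[probe + 1L]]
  t <- sol$probes$t
  hit <- which(v >= threshold)
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1L]
  if (i == 1L) return(t[1L])
  t[i - 1L] + (threshold - v[i - 1L]) / (v[i] - v[i - 1L]) * (t[i] - t[i - 1L])
}

#' @export
#' @method print bioheat_solution
print.bioheat_solution <- function(x, ...) {
  cat(sprintf("<bioheat_solution> model = %s, t_end = %g s, dt = %g s\n",
              x$model, x$t_end, x$dt))
  cat(sprintf("  grid %d x %d, dx = %g mm\n", x$grid$nx, x$grid$ny,
              x$grid$dx * 1e3))
  cat(sprintf("  max T = %.3f degC at t = %g s, (x, y) = (%.1f, %.1f) mm\n",
              x$max$value, x$max$time,
              x$max$location[["x"]] * 1e3, x$max$location[["y"]] * 1e3))
  invisible(x)
}
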