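# Independent oracles used across the suite. These are deliberately plain
# transcriptions of the closed forms, kept separate from the package's
# implementation paths.

kB_o <- 1.380649e-23
mu0_o <- 4 * pi * 1e-7

# Arithmetic oracle for the default single-species parameters
# (D = 15 nm, delta = 1 nm, K = 1.5e4 J/m^3, tau0 = 1e-9 s, Md = 6.3e5 A/m,
# phi = 0.0013, eta = 1.22e-3 Pa s, T = 310 K, H0 = 37.4 kA/m, f = 500 kHz).
magnetics_oracle <- function(D = 15e-9, delta = 1e-9, K = 1.5e4,
                             tau0 = 1e-9, Md = 6.3e5, phi = 0.0013,
                             eta = 1.22e-3, Temp = 310, H0 = 3.74e4,
                             f = 5e5) {
  kT <- kB_o * Temp
  VM <- pi * D^3 / 6
  VH <- pi * (D + 2 * delta)^3 / 6
  tauB <- 3 * eta * VH / kT
  G <- K * VM / kT
  tauN_ros <- sqrt(pi) / 2 * tau0 * exp(G) / sqrt(G)
  tauN_arr <- tau0 * exp(G)
  tau_ros <- 1 / (1 / tauN_ros + 1 / tauB)
  xi <- mu0_o * Md * H0 * VM / kT
  chi_i <- mu0_o * Md^2 * phi * VM / (3 * kT)
  chord <- (3 / xi) * (cosh(xi) / sinh(xi) - 1 / xi)
  chi_0 <- chi_i * chord
  wt <- 2 * pi * f * tau_ros
  chi_loss <- chi_0 * wt / (1 + wt^2)
  P <- pi * mu0_o * H0^2 * f * chi_loss
  list(VM = VM, VH = VH, tauB = tauB, G = G, tauN_ros = tauN_ros,
       tauN_arr = tauN_arr, tau_ros = tau_ros, xi = xi, chi_i = chi_i,
       chi_0 = chi_0, chi_loss = chi_loss, P = P)
}

# Closed-form steady temperature profile of a uniformly heated slab
# |x| <= a in an infinite perfused medium (1D screening solution).
slab_steady_profile <- function(x, props, q_np, a) {
  w <- props$perfusion_rate * props$blood_density * props$blood_heat_capacity
  L <- sqrt(props$conductivity / w)
  S <- q_np / w
  base <- props$arterial_temperature + props$metabolic_heat / w
  u <- ifelse(abs(x) <= a,
              S * (1 - exp(-a / L) * cosh(x / L)),
              S * sinh(a / L) * exp(-abs(x) / L))
  base + u
}

# Same for a uniformly heated disc of radius a (2D, modified Bessel).
disc_steady_center <- function(props, q_np, a) {
  w <- props$perfusion_rate * props$blood_density * props$blood_heat_capacity
  L <- sqrt(props$conductivity / w)
  S <- q_np / w
  z <- a / L
  props$arterial_temperature + props$metabolic_heat / w +
    S * (1 - z * besselK(z, 1))
}

# Manufactured-solution error for one model at one resolution. The exact
# field T* = Tb + A cos(pi x/Lx) cos(pi y/Ly) phi(t) with
# phi(t) = (1 - exp(-t/tau*))^2 has zero initial value AND zero initial
# rate, matching the solver's start-up assumption; the full residual of
# the lagged equation is injected through `forcing`.
mms_error <- function(model, dx, dt, t_end = 60, A = 5, tau_star = 20) {
  props <- tissue_properties(metabolic_heat = 0)
  g <- simulation_grid(dx = dx, dy = dx, tumor_shape = "none",
                       boundary = "insulated")
  rc <- props$density * props$heat_capacity
  w <- perfusion_coefficient(props)
  lags <- switch(model,
                 pennes = c(0, 0),
                 spl = c(props$tau_q, 0),
                 dpl = c(props$tau_q, props$tau_t))
  lam <- (pi / g$x_half)^2 + (pi / g$y_half)^2
  cxy <- outer(cos(pi * g$x / g$x_half), cos(pi * g$y / g$y_half))
  u <- function(t) exp(-t / tau_star)
  phi <- function(t) (1 - u(t))^2
  dphi <- function(t) 2 * (u(t) - u(t)^2) / tau_star
  d2phi <- function(t) 2 * (2 * u(t)^2 - u(t)) / tau_star^2
  k <- props$conductivity
  forcing <- function(t) {
    cxy * A * (rc * lags[1] * d2phi(t) + (rc + lags[1] * w) * dphi(t) +
                 lags[2] * k * lam * dphi(t) + k * lam * phi(t) +
                 w * phi(t))
  }
  sol <- solve_bioheat(g, props, model, dt = dt, t_end = t_end,
                       T0 = props$arterial_temperature, forcing = forcing)
  exact <- props$arterial_temperature + A * cxy * phi(t_end)
  max(abs(sol$final - exact))
}

# The headline liver run (default geometry, production resolution),
# computed once and shared across test files.
headline_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- simulation_grid()  # 40 x 40 mm, dx = 0.5 mm, slab half-width 10 mm
      cache <<- solve_bioheat(
        g, tissue_properties(), model = "dpl", q_np = 4.77978e5,
        dt = 0.5, t_end = 3600,
        probes = rbind(c(0, 0), c(0.01, 0)),
        snapshot_times = 3600
      )
    }
    cache
  }
})

coarse_scenario <- function(name, ...) {
  build_scenario(name, dx = 2e-3, dy = 2e-3, dt = 2, ...)
}
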