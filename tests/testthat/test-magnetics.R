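test_that("particle volumes follow the sphere formulas and cubic scaling", {
  np <- nanoparticle_spec(core_diameter = 15e-9, coating_thickness = 1e-9)
  v <- particle_volumes(np)
  expect_equal(v$V_M, 1.7671458676e-24, tolerance = 1e-9)
  expect_equal(v$V_H, 2.5724407845e-24, tolerance = 1e-9)
  expect_gte(v$V_H, v$V_M)

  bare <- nanoparticle_spec(coating_thickness = 0)
  vb <- particle_volumes(bare)
  expect_identical(vb$V_H, vb$V_M)

  big <- nanoparticle_spec(core_diameter = 30e-9)
  expect_equal(particle_volumes(big)$V_M / v$V_M, 8, tolerance = 1e-12)

  expect_error(nanoparticle_spec(core_diameter = -1e-9),
               class = "nanotherm_invalid_parameter")
})

test_that("relaxation times match the arithmetic oracle in both Neel forms", {
  o <- magnetics_oracle()
  np <- nanoparticle_spec()
  env <- carrier_fluid()

  ros <- relaxation_times(np, env, "rosensweig")
  expect_equal(ros$tau_brown, o$tauB, tolerance = 1e-10)
  expect_equal(ros$gamma, o$G, tolerance = 1e-10)
  expect_equal(ros$tau_neel, o$tauN_ros, tolerance = 1e-10)
  expect_equal(ros$tau_eff, o$tau_ros, tolerance = 1e-10)

  arr <- relaxation_times(np, env, "arrhenius")
  expect_equal(arr$tau_neel, o$tauN_arr, tolerance = 1e-10)

  # headline magnitudes for the default species
  expect_equal(ros$tau_brown, 2.201e-6, tolerance = 1e-3)
  expect_equal(ros$gamma, 6.196, tolerance = 1e-3)
  expect_equal(ros$tau_eff, 1.62e-7, tolerance = 5e-3)
})

test_that("effective relaxation is a harmonic sum with the right limits", {
  # huge barrier: Neel frozen out, tau_eff -> tau_brown, no overflow
  frozen <- nanoparticle_spec(anisotropy = 1e6)  # Gamma ~ 413
  rt <- relaxation_times(frozen)
  expect_true(is.finite(rt$tau_eff))
  expect_equal(rt$tau_eff, rt$tau_brown, tolerance = 1e-6)

  huge <- nanoparticle_spec(anisotropy = 1e7, core_diameter = 30e-9)
  rt2 <- relaxation_times(huge)  # Gamma far beyond exp() overflow
  expect_false(is.finite(rt2$tau_neel))
  expect_true(is.finite(rt2$tau_eff))
  expect_equal(rt2$tau_eff, rt2$tau_brown)

  # property: tau_eff <= min(tauN, tauB), monotone in each, over random specs
  set.seed(7)
  for (i in 1:25) {
    np <- nanoparticle_spec(
      core_diameter = runif(1, 6e-9, 30e-9),
      coating_thickness = runif(1, 0, 5e-9),
      anisotropy = 10^runif(1, 3.5, 5),
      attempt_time = 10^runif(1, -12, -9)
    )
    env <- carrier_fluid(viscosity = 10^runif(1, -3.5, -2),
                         temperature = runif(1, 290, 330))
    rt <- relaxation_times(np, env)
    expect_lte(rt$tau_eff, min(rt$tau_brown, rt$tau_neel) * (1 + 1e-12))
    expect_gt(rt$tau_eff, 0)
    # log-space evaluation agrees with the direct exponential when the
    # direct path cannot overflow
    if (rt$gamma <= 500) {
      direct <- sqrt(pi) / 2 * np$attempt_time * exp(rt$gamma) /
        sqrt(rt$gamma)
      expect_equal(rt$tau_neel, direct, tolerance = 1e-10)
    }
  }
})

test_that("relaxation curve is monotone with a unique Neel/Brown crossover", {
  np <- nanoparticle_spec()
  radii <- seq(7e-9, 15e-9, length.out = 81)
  curve <- relaxation_curve(np, carrier_fluid(), radii)
  expect_equal(nrow(curve), 81)
  expect_true(all(diff(curve$tau_neel) > 0))
  expect_true(all(diff(curve$tau_brown) > 0))
  # Neel spans many orders of magnitude, Brown only (r + delta)^3
  expect_gt(log10(curve$tau_neel[81] / curve$tau_neel[1]), 10)
  expect_lt(curve$tau_brown[81] / curve$tau_brown[1], 10)
  # unique crossover: the sign of log(tauN/tauB) changes exactly once
  sgn <- sign(log(curve$tau_neel / curve$tau_brown))
  expect_equal(sum(diff(sgn) != 0), 1)

  # single radius reduces to relaxation_times
  one <- relaxation_curve(np, carrier_fluid(), 7.5e-9)
  rt <- relaxation_times(np, carrier_fluid())
  expect_equal(one$tau_eff, rt$tau_eff)
  expect_equal(nrow(relaxation_curve(np, carrier_fluid(), numeric(0))), 0)
})

test_that("optimal frequency satisfies 2 pi nu tau = 1", {
  expect_equal(optimal_frequency(1 / (2 * pi)), 1)
  expect_equal(optimal_frequency(1.62e-7), 9.824e5, tolerance = 1e-3)
  taus <- 10^seq(-9, -3, length.out = 7)
  expect_equal(optimal_frequency(taus) * taus * 2 * pi, rep(1, 7))
})

test_that("susceptibilities match the oracle and obey the Langevin limits", {
  o <- magnetics_oracle()
  np <- nanoparticle_spec()
  s <- susceptibilities(np, field_spec(), carrier_fluid(), o$tau_ros)
  expect_equal(s$xi, o$xi, tolerance = 1e-10)
  expect_equal(s$chi_i, o$chi_i, tolerance = 1e-10)
  expect_equal(s$chi_0, o$chi_0, tolerance = 1e-10)
  expect_equal(s$chi_loss, o$chi_loss, tolerance = 1e-10)
  expect_equal(s$xi, 12.23, tolerance = 1e-3)
  expect_equal(s$chi_i, 0.0893, tolerance = 1e-2)

  # chi_0 <= chi_i always, equality in the weak-field limit
  expect_lte(s$chi_0, s$chi_i)
  weak <- susceptibilities(np, field_spec(amplitude = 1e-8),
                           carrier_fluid(), o$tau_ros)
  expect_equal(weak$chi_0, weak$chi_i, tolerance = 1e-8)
  # loss bounded by chi_0 / 2 for any frequency
  expect_lte(s$chi_loss, s$chi_0 / 2)
})

test_that("loss susceptibility peaks at omega tau = 1 with value chi_0 / 2", {
  np <- nanoparticle_spec()
  tau <- magnetics_oracle()$tau_ros
  nu_star <- optimal_frequency(tau)
  freqs <- exp(seq(log(nu_star / 50), log(nu_star * 50), length.out = 2001))
  losses <- vapply(freqs, function(f) {
    susceptibilities(np, field_spec(frequency = f), carrier_fluid(),
                     tau)$chi_loss
  }, numeric(1))
  i <- which.max(losses)
  expect_equal(freqs[i], nu_star, tolerance = 1e-2)  # grid resolution
  chi_0 <- susceptibilities(np, field_spec(frequency = nu_star),
                            carrier_fluid(), tau)$chi_0
  expect_equal(max(losses), chi_0 / 2, tolerance = 1e-6)
})

test_that("volumetric power follows pi mu0 H0^2 f chi'' with H0^2 scaling", {
  o <- magnetics_oracle()
  f <- field_spec()
  expect_equal(volumetric_power(f, o$chi_loss), o$P, tolerance = 1e-12)
  expect_equal(volumetric_power(f, o$chi_loss), 2.24e7, tolerance = 2e-2)
  expect_identical(volumetric_power(f, 0), 0)
  f2 <- field_spec(amplitude = 2 * f$amplitude)
  expect_equal(volumetric_power(f2, 0.01) / volumetric_power(f, 0.01), 4)
})

test_that("SLP conversions round-trip and reproduce the calorimetric form", {
  np <- nanoparticle_spec()
  cal <- slp_conversions(np, calorimetric = list(C = 3500, dT = 7, dt = 600))
  expect_equal(cal$slp, 40.83333333, tolerance = 1e-8)

  set.seed(11)
  for (i in 1:10) {
    np_i <- nanoparticle_spec(density = runif(1, 3e3, 8e3),
                              volume_fraction = runif(1, 1e-4, 1e-2))
    P <- runif(1, 1e4, 1e8)
    hr <- slp_conversions(np_i, power = P)
    expect_equal(hr$q_np, P, tolerance = 1e-12)  # power -> SLP -> Q_np
  }

  # a measured SLP of 3866 W/g delivers the reference liver source at a
  # mass concentration of ~0.1236 kg/m^3
  gamma <- 4.77978e5 / 3.866e6
  hr <- slp_conversions(np, slp = 3866 * 1000, gamma_np = gamma)
  expect_equal(hr$q_np, 4.77978e5, tolerance = 1e-12)
  expect_equal(gamma, 0.123636, tolerance = 1e-4)

  expect_error(slp_conversions(np, power = 1, slp = 1),
               class = "nanotherm_invalid_parameter")
  expect_error(slp_conversions(np), class = "nanotherm_invalid_parameter")
})

test_that("literal legacy SLP formula is loss-factor shaped", {
  np <- nanoparticle_spec()
  f <- field_spec()
  tau <- magnetics_oracle()$tau_ros
  # frozen regression value for the default parameters (nominal W/g)
  expect_equal(slp_lrt_literal(np, f, tau), 1248689.218, tolerance = 1e-8)
  # vanishes with tau -> 0
  expect_lt(slp_lrt_literal(np, f, 1e-18), 1e-3)
  # the printed formula carries an extra factor nu relative to the loss
  # factor, so over frequency it rises monotonically and saturates at the
  # plateau C / (2 pi tau) instead of peaking at 2 pi nu tau = 1
  nu_star <- optimal_frequency(tau)
  vals <- vapply(c(0.3, 1, 3, 1000) * nu_star, function(nu) {
    slp_lrt_literal(np, field_spec(frequency = nu), tau)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_equal(vals[3] / vals[4], 0.9, tolerance = 1e-4)
})

test_that("dead-layer and volume-fraction relations behave", {
  expect_equal(dead_layer_saturation(1e5, 7.5e-9, 0), 1e5)
  expect_equal(dead_layer_saturation(1e5, 7.5e-9, 1e-9) / 1e5,
               (6.5 / 7.5)^3, tolerance = 1e-12)
  d <- seq(0, 7e-9, length.out = 20)
  ms <- vapply(d, function(di) dead_layer_saturation(1e5, 7.5e-9, di),
               numeric(1))
  expect_true(all(diff(ms) < 0))
  expect_error(dead_layer_saturation(1e5, 7.5e-9, 8e-9),
               class = "nanotherm_invalid_parameter")

  expect_equal(volume_fraction_from_magnetization(819, 6.3e5), 0.0013)
  expect_equal(volume_fraction_from_magnetization(6.3e5, 6.3e5), 1)
  expect_equal(volume_fraction_from_magnetization(819, 6.3e5) * 6.3e5, 819)
  expect_error(volume_fraction_from_magnetization(2, 1),
               class = "nanotherm_invalid_parameter")
})
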