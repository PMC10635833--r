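test_that("trap calibration recovers the slope of the linear regime", {
  x <- seq(-0.15, 0.15, length.out = 31)
  cal <- calibrate_trap_stiffness(data.frame(x_um = x, f_pN = 50 * x))
  expect_equal(cal$k, 50, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1)

  # cubic contamination: OLS slope on the windowed grid, checked against
  # the closed-form normal equations sum(xy)/sum(x^2) (centered design)
  xg <- seq(-0.1, 0.1, length.out = 21)
  f <- 50 * xg + 200 * xg^3
  slope_hand <- sum(xg * f) / sum(xg^2)
  cal2 <- calibrate_trap_stiffness(data.frame(x_um = xg, f_pN = f))
  expect_equal(cal2$k, slope_hand, tolerance = 1e-10)

  expect_warning(
    cal3 <- calibrate_trap_stiffness(data.frame(x_um = xg, f_pN = 0 * xg)),
    "zero")
  expect_equal(cal3$k, 0)
  expect_true(cal3$degenerate)

  expect_error(
    calibrate_trap_stiffness(data.frame(x_um = c(-1, 1), f_pN = c(-1, 1))),
    "fewer than 3")
})

test_that("quadrature lock-in returns exact amplitudes for pure tones", {
  fs <- 5000; f <- 4
  t <- seq(0, 10 / f, by = 1 / fs); t <- t[-length(t)]
  sweep <- structure(list(
    data = data.frame(time_s = t, x_trap1_um = 0.1 * sin(2 * pi * f * t),
                      f1_pN = 3 * sin(2 * pi * f * t),
                      f2_pN = 0 * t, freq_hz = f),
    drive_frequencies = f, sampling_rate = fs
  ), class = "force_sweep")
  amps <- lockin_spectrum(sweep)
  expect_equal(Mod(amps$F1), 3, tolerance = 1e-10)
  expect_equal(Mod(amps$F2), 0, tolerance = 1e-10)
  expect_equal(Mod(amps$x_sys), 0.1, tolerance = 1e-10)

  # noisy tone: amplitude estimate unbiased (median over seeds within 1%)
  est <- vapply(1:100, function(s) {
    set.seed(s)
    y <- 3 * sin(2 * pi * f * t) + rnorm(length(t), 0, 0.3)
    Mod(quadrature_amplitude(t, y, f))
  }, numeric(1))
  expect_lt(abs(median(est) - 3) / 3, 0.01)
})

test_that("system spring constant follows the differential-force formula", {
  amps <- data.frame(freq_hz = 1, F1 = complex(real = 5),
                     F2 = complex(real = -5), x_sys = complex(real = 1))
  expect_equal(system_spring_constant(amps)$chi_sys, complex(real = 5))

  amps2 <- data.frame(freq_hz = 1, F1 = complex(real = 2),
                      F2 = complex(real = 2), x_sys = complex(real = 1))
  expect_equal(system_spring_constant(amps2)$chi_sys, complex(real = 0))

  amps3 <- rbind(amps, data.frame(freq_hz = 2, F1 = complex(real = 1),
                                  F2 = complex(real = -1),
                                  x_sys = complex(real = 0)))
  expect_warning(out <- system_spring_constant(amps3), "zero drive")
  expect_equal(nrow(out), 1)
})

test_that("trap-coupling correction matches hand-evaluated values and limits", {
  # xi = 0, k1 = k2 = 50, chi_sys = 5 -> chi = 6.25
  cs <- data.frame(freq_hz = 1, chi_sys = complex(real = 5))
  chi <- droplet_spring_constant(cs, 50, 50, xi = 0)
  expect_equal(Re(chi$chi), 6.25, tolerance = 1e-12)
  expect_equal(Im(chi$chi), 0, tolerance = 1e-12)

  # stiff-trap limit: the relative correction follows the series
  # expansion chi_sys (k1 + k2) / (k1 k2) and vanishes with trap
  # stiffness (2.04% at k = 100 chi, below 0.5% by k = 1000 chi)
  cs2 <- data.frame(freq_hz = 2^(0:5), chi_sys = complex(real = rep(5, 6)))
  rel_100 <- with(droplet_spring_constant(cs2, 500, 500, xi = 0),
                  Mod(chi - cs2$chi_sys) / Mod(cs2$chi_sys))
  expect_equal(rel_100, rep((2 * 5 / 500) / (1 - 2 * 5 / 500), 6),
               tolerance = 1e-10)
  rel_1000 <- with(droplet_spring_constant(cs2, 5000, 5000, xi = 0),
                   Mod(chi - cs2$chi_sys) / Mod(cs2$chi_sys))
  expect_true(all(rel_1000 < 0.005))
  expect_true(all(rel_1000 < rel_100))

  # zero input stays zero
  cs3 <- data.frame(freq_hz = 1, chi_sys = complex(real = 0))
  expect_equal(droplet_spring_constant(cs3, 50, 50, 0)$chi, complex(real = 0))
})

test_that("shear modulus geometry factors and worked value are exact", {
  geom <- contact_geometry(0.5)
  expect_equal(geom$geometry_poly, 1.8571875, tolerance = 1e-12)
  expect_equal(geom$tension_prefactor, 2.34, tolerance = 1e-12)

  chi <- data.frame(freq_hz = 1, chi = complex(real = 6.25))
  sp <- shear_modulus(chi, gamma = 1, theta0 = 0.5, radius = 2.5)
  expect_equal(sp$G_prime, (6.25 - 2.34) / (2.5 * 1.8571875),
               tolerance = 1e-12)
  expect_equal(sp$G_prime, 0.8421, tolerance = 1e-4)

  # chi equal to the capillary term: pure surface tension, G* = 0
  chi0 <- data.frame(freq_hz = 1, chi = complex(real = 2.34))
  expect_equal(shear_modulus(chi0, 1, 0.5, 2.5)$G_prime, 0, tolerance = 1e-12)

  expect_error(shear_modulus(chi, 1, 0.004, 2.5), "polynomial")
})

test_that("resting stiffness and surface tension follow the step formulas", {
  te <- resting_stiffness_and_tension(1, -1, 50, 50, A = 0.1, theta0 = 0.5)
  expect_equal(te$delta_x0, 0.14, tolerance = 1e-12)
  expect_equal(te$chi0, 2 / 0.28, tolerance = 1e-12)
  expect_equal(te$chi0, 7.1429, tolerance = 1e-4)
  expect_equal(te$gamma, (2 / 0.28 / pi) * (log(2) + 0.68), tolerance = 1e-12)
  expect_equal(te$gamma, 3.1220, tolerance = 1e-4)

  # unloaded droplet
  te0 <- resting_stiffness_and_tension(0, 0, 50, 50, 0.1, 0.5)
  expect_equal(te0$delta_x0, 0.1)
  expect_equal(te0$chi0, 0)
  expect_equal(te0$gamma, 0)

  # theta0 -> 1: only the 0.68 offset survives
  te1 <- resting_stiffness_and_tension(1, -1, 50, 50, 0.1, 1 - 1e-12)
  expect_equal(te1$gamma, 0.68 * te1$chi0 / pi, tolerance = 1e-9)

  expect_error(resting_stiffness_and_tension(-10, 10, 50, 50, 0.1, 0.5),
               "non-physical")
})

test_that("step-relaxation fits recover exponential decay parameters", {
  fs <- 1000
  t <- seq(0, 4.999, by = 1 / fs)
  f <- 1 + 2 * exp(-t / 0.5)
  # spot value: t = 0.5 s gives 1 + 2/e
  expect_equal(f[t == 0.5], 1 + 2 * exp(-1), tolerance = 1e-12)
  fit <- fit_step_relaxation(t, f, step_onsets = 0)
  expect_equal(fit$F0, 1, tolerance = 1e-8)
  expect_equal(fit$Fp, 3, tolerance = 1e-8)
  expect_equal(fit$tau, 0.5, tolerance = 1e-8)

  # constant trace: tau unidentifiable, flagged
  fitc <- fit_step_relaxation(t, rep(2, length(t)), 0)
  expect_true(fitc$degenerate)
  expect_equal(fitc$F0, fitc$Fp)

  # segments restarted at each onset are averaged before fitting
  tr <- trap_truth(noise_sd_force = 0, seed = 1)
  st <- simulate_step_relaxation(tr, 1, 3, -1, -3, tau = 0.5, n_steps = 3)
  fit3 <- fit_step_relaxation(st$time, st$f1, st$step_onsets)
  expect_equal(fit3$tau, 0.5, tolerance = 1e-6)
})

test_that("Maxwell fit recovers exact spectra and the crossover identity", {
  f <- 2^seq(-1, 6)
  sp <- maxwell_modulus(f, E = 2, eta = 0.1)
  fit <- fit_maxwell(sp)
  expect_equal(fit$E, 2, tolerance = 1e-9)
  expect_equal(fit$eta, 0.1, tolerance = 1e-9)
  expect_equal(fit$omega_c, 2 / (2 * pi * 0.1), tolerance = 1e-9)
  expect_equal(fit$omega_c, 3.1831, tolerance = 1e-4)
  expect_lt(sum(fit$residuals^2), 1e-16)
  expect_false(fit$extrapolated)

  # at the crossover frequency the model element has G' = G'' = E/2
  at_c <- maxwell_modulus(fit$omega_c, fit$E, fit$eta)
  expect_equal(at_c$G_prime, fit$E / 2, tolerance = 1e-9)
  expect_equal(at_c$G_doubleprime, fit$E / 2, tolerance = 1e-9)

  # fluid below the crossover, solid above
  below <- maxwell_modulus(f[f < fit$omega_c], fit$E, fit$eta)
  above <- maxwell_modulus(f[f > fit$omega_c], fit$E, fit$eta)
  expect_true(all(below$G_doubleprime > below$G_prime))
  expect_true(all(above$G_prime > above$G_doubleprime))

  # crossover outside the measured band is flagged as extrapolated
  f_low <- c(16, 32, 64, 128)
  fit2 <- fit_maxwell(maxwell_modulus(f_low, 2, 0.1))
  expect_true(fit2$extrapolated)

  expect_error(fit_maxwell(sp[1:3, ]), ">= 4")
})

test_that("moduli scale inversely with droplet radius (units audit)", {
  chi <- data.frame(freq_hz = 1, chi = complex(real = 10))
  g1 <- shear_modulus(chi, 1, 0.5, radius = 2)$G_prime
  g2 <- shear_modulus(chi, 1, 0.5, radius = 4)$G_prime
  expect_equal(g1 / g2, 2, tolerance = 1e-12)
})
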