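test_that("noiseless dual-trap sweep round-trips material truth exactly", {
  m <- material_truth(E = 2, eta_dashpot = 0.1, gamma = 1, theta0 = 0.5,
                      diameter = 5)
  tr <- trap_truth(k1 = 50, k2 = 50, seed = 11)
  sw <- simulate_dual_trap_sweep(m, tr)

  # programmed coupled stiffness recovered at machine precision
  amps <- lockin_spectrum(sw)
  cs <- system_spring_constant(amps)
  expect_equal(Mod(cs$chi_sys - sw$truth$chi_sys), rep(0, 8),
               tolerance = 1e-9)

  res <- droplet_rheology(sw, 50, 50, gamma = 1, theta0 = 0.5)
  expect_lt(abs(res$maxwell$E - 2) / 2, 1e-6)
  expect_lt(abs(res$maxwell$eta - 0.1) / 0.1, 1e-6)
  expect_lt(abs(res$maxwell$omega_c - m$crossover_hz) / m$crossover_hz, 1e-6)
})

test_that("sweep generator enforces sampling and reproducibility contracts", {
  m <- material_truth(2, 0.1)
  expect_error(trap_truth(sampling_rate = 100), "20x")

  tr <- trap_truth(seed = 42, noise_sd_force = 0.2)
  s1 <- simulate_dual_trap_sweep(m, tr)
  s2 <- simulate_dual_trap_sweep(m, tr)
  expect_identical(s1$data, s2$data)

  # zero drive amplitude: forces are pure noise, lock-in amplitudes ~ 0
  tr0 <- trap_truth(step_amplitude_nm = 0, noise_sd_force = 0.1, seed = 3)
  s0 <- simulate_dual_trap_sweep(m, tr0)
  amps <- lockin_spectrum(s0)
  expect_true(all(Mod(amps$F1) < 0.05))
  expect_true(all(Mod(amps$x_sys) < 1e-12))
})

test_that("lock-in amplitude equals the programmed drive amplitude", {
  m <- material_truth(2, 0.1)
  tr <- trap_truth(seed = 1)
  sw <- simulate_dual_trap_sweep(m, tr)
  amps <- lockin_spectrum(sw)
  expect_equal(Mod(amps$x_sys), rep(0.1, 8), tolerance = 1e-3 * 0.1)
  expect_equal(Mod(amps$x_sys), rep(0.1, 8), tolerance = 1e-10)
})

test_that("step-relaxation traces follow the programmed exponential", {
  tr <- trap_truth(noise_sd_force = 0, seed = 1)
  st <- simulate_step_relaxation(tr, F0_1 = 1, Fp_1 = 3, F0_2 = -1,
                                 Fp_2 = -3, tau = 0.5)
  i <- which.min(abs(st$time - 0.5))
  expect_equal(st$f1[i], 1 + 2 * exp(-1), tolerance = 1e-3)
  expect_equal(st$f1[i], 1.7358, tolerance = 1e-3)

  # zero step response: constant trace
  stc <- simulate_step_relaxation(tr, 2, 2, -2, -2, tau = 0.5)
  expect_true(all(stc$f1 == 2))

  expect_error(simulate_step_relaxation(tr, 1, 3, -1, -3, tau = 0),
               "positive")
})

test_that("tension-consistent step forces close the gamma round trip", {
  m <- material_truth(2, 0.1, gamma = 1, theta0 = 0.5)
  tr <- trap_truth(seed = 2)
  sf <- consistent_step_forces(m, tr)
  st <- simulate_step_relaxation(tr, sf$F0_1, sf$Fp_1, sf$F0_2, sf$Fp_2,
                                 sf$tau)
  f1 <- fit_step_relaxation(st$time, st$f1, st$step_onsets)
  f2 <- fit_step_relaxation(st$time, st$f2, st$step_onsets)
  te <- resting_stiffness_and_tension(f1$F0, f2$F0, tr$k1, tr$k2,
                                      tr$step_amplitude_nm / 1000, m$theta0)
  expect_equal(te$gamma, 1, tolerance = 1e-3)
})

test_that("FRAP generator encodes the target recovery before noise", {
  raw <- simulate_frap(Mf = 0.6, t_half = 5, noise_sd = 0)
  cv <- normalize_frap(raw)
  post <- cv[cv$phase %in% c("postbleach1", "postbleach2"), ]
  expected <- 0.6 * (1 - exp(-log(2) / 5 * post$t_s))
  expect_equal(post$intensity, expected, tolerance = 1e-9)
  # at one half-time the curve reads Mf/2 = 0.30
  expect_equal(0.6 * (1 - exp(-log(2))), 0.30, tolerance = 1e-12)

  # immobile condensate: flat post-bleach curve at 0
  raw0 <- simulate_frap(Mf = 0, t_half = 5, noise_sd = 0)
  cv0 <- normalize_frap(raw0)
  expect_true(all(abs(cv0$intensity[cv0$phase != "prebleach"]) < 1e-9))

  expect_error(simulate_frap(Mf = 1.2, t_half = 5), "Mf")
  expect_error(simulate_frap(0.5, 5, bleach_depth = 0), "bleach_depth")
})

test_that("track generator produces the stated transport statistics", {
  # ballistic: MSD(tau) = (speed tau)^2 exactly without noise
  tb <- simulate_tracks("directed", n_tracks = 1, speed = 1,
                        loc_noise_sd = 0, seed = 1)
  msd <- mean_squared_displacement(tb)
  expect_equal(msd$msd_um2, msd$lag_s^2, tolerance = 1e-10)

  # stationary without noise: MSD identically zero
  ts <- simulate_tracks("stationary", n_tracks = 3, loc_noise_sd = 0,
                        seed = 1)
  expect_true(all(mean_squared_displacement(ts)$msd_um2 == 0))

  # brownian ensemble: exponent ~ 1, intercept ~ 4D
  tbr <- simulate_tracks("brownian", n_tracks = 100, D_coef = 0.05,
                         loc_noise_sd = 0, seed = 7)
  pl <- fit_powerlaw(mean_squared_displacement(tbr))
  expect_gt(pl$exponent, 0.9)
  expect_lt(pl$exponent, 1.1)
  expect_equal(pl$prefactor, 4 * 0.05, tolerance = 0.1 * 4 * 0.05)

  expect_error(simulate_tracks("warp"), "arg")
  expect_error(simulate_tracks("brownian", n_frames = 5), "n_frames")
})

test_that("FRET stack generator inverts the unmixing equations", {
  # worked example: index 1/6 with I_DD = 100, I_AA = 50, d = 0.5, a = 0.2
  # gives cF = 20 and I_DA = 20 + 50 + 10 = 80
  idx <- matrix(1 / 6, 4, 4)
  st <- simulate_fret_stacks(idx, donor_bleed_d = 0.5, crossex_a = 0.2,
                             donor_signal = 100, acceptor_signal = 50)
  expect_equal(st$I_DA, matrix(80, 4, 4), tolerance = 1e-12)

  # round trip at zero noise is exact
  idx2 <- matrix(runif(64, 0, 0.8), 8, 8)
  st2 <- simulate_fret_stacks(idx2, 0.5, 0.2)
  fm <- fret_index_map(st2$I_DD, st2$I_DA, st2$I_AA, 0.5, 0.2,
                       mask = matrix(TRUE, 8, 8))
  expect_equal(fm$index_map, idx2, tolerance = 1e-9)

  # zero-FRET control: corrected FRET channel vanishes
  st0 <- simulate_fret_stacks(matrix(0, 4, 4), 0.5, 0.2)
  fm0 <- fret_index_map(st0$I_DD, st0$I_DA, st0$I_AA, 0.5, 0.2,
                        mask = matrix(TRUE, 4, 4))
  expect_equal(fm0$mean_index, 0, tolerance = 1e-12)

  expect_error(simulate_fret_stacks(matrix(1.5, 2, 2)), "index")
  expect_error(simulate_fret_stacks(idx, donor_bleed_d = -1), "non-negative")
})

test_that("coloc generator controls co-occurrence and is deterministic", {
  ci <- simulate_coloc_images(coloc_fraction = 1, noise_sd = 0, seed = 4)
  mask <- ci$ch1 > 1
  expect_equal(pearson_colocalization(ci$ch1, ci$ch2, mask)$rho, 1,
               tolerance = 1e-12)

  c1 <- simulate_coloc_images(seed = 9)
  c2 <- simulate_coloc_images(seed = 9)
  expect_identical(c1$ch1, c2$ch1)
  expect_identical(c1$ch2, c2$ch2)

  expect_error(simulate_coloc_images(n_puncta = 5000,
                                     image_shape = c(50, 20)), "denser")
})
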