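# Forward model: from material truth to the coupled system stiffness.
# Built as the exact algebraic inverse of the analysis chain so that a
# noiseless sweep round-trips to the truth at machine precision.

# inverse of shear_modulus(): chi from G*
chi_from_modulus <- function(G_star, gamma, theta0, radius) {
  geom <- contact_geometry(theta0)
  G_star * radius * geom$geometry_poly + geom$tension_prefactor * gamma
}

# inverse of droplet_spring_constant(): chi_sys from chi
chi_sys_from_chi <- function(chi, k1, k2, xi, freq_hz) {
  w <- 2 * pi * freq_hz
  S <- k1 + k2 + 1i * xi * w
  chi * 2 * k1 * (2 * k2 + 1i * xi * w) /
    (4 * k1 * k2 + 1i * xi * w * (k1 + k2) + 4 * chi * S)
}

# complex Maxwell modulus G* = E i w tau / (1 + i w tau), tau = eta/E
maxwell_G_star <- function(f_hz, E, eta) {
  iwt <- 1i * 2 * pi * f_hz * eta / E
  E * iwt / (1 + iwt)
}

# programmed coupled stiffness at the drive frequencies
chi_sys_truth <- function(material, traps) {
  f <- traps$drive_frequencies
  G <- maxwell_G_star(f, material$E, material$eta_dashpot)
  chi <- chi_from_modulus(G, material$gamma, material$theta0,
                          material$radius)
  xi <- droplet_drag(material$medium_viscosity, material$diameter)
  chi_sys_from_chi(chi, traps$k1, traps$k2, xi, f)
}

#' Simulate a dual-trap sinusoidal sweep on a Maxwell droplet
#'
#' Trap 1 is driven sinusoidally at each frequency of
#' `traps$drive_frequencies` with amplitude `traps$step_amplitude_nm`;
#' trap 2 is stationary. The forces on the two traps are generated from
#' the programmed coupled stiffness (the forward model is the exact
#' algebraic inverse of the analysis chain: Maxwell modulus to droplet
#' stiffness to coupled system stiffness), split antisymmetrically
#' (`F1 = +chi_sys x_sys`, `F2 = -chi_sys x_sys`; the analysis only uses
#' their difference). Gaussian force noise (additive sd in pN and/or
#' multiplicative relative sd) is added afterwards, seeded.
#'
#' @param material a [material_truth()].
#' @param traps a [trap_truth()].
#' @return object of class `force_sweep`: list with `data` (data.frame
#'   `time_s`, `x_trap1_um`, `f1_pN`, `f2_pN`, `freq_hz`), the drive
#'   frequencies, sampling rate, drive amplitude (um), droplet `diameter`
#'   and `medium_viscosity` (needed downstream for the drag), the truth
#'   parameters and the seed.
#' @export
simulate_dual_trap_sweep <- function(material, traps) {
  stopifnot(inherits(material, "material_truth"), inherits(traps, "trap_truth"))
  if (traps$sampling_rate < 20 * max(traps$drive_frequencies)) {
    stop("sampling rate too low for the highest drive frequency")
  }
  A <- traps$step_amplitude_nm / 1000  # um
  fs <- traps$sampling_rate
  chis <- chi_sys_truth(material, traps)

  set.seed(traps$seed)
  t_offset <- 0
  segs <- vector("list", length(traps$drive_frequencies))
  for (i in seq_along(traps$drive_frequencies)) {
    f <- traps$drive_frequencies[i]
    n <- round(traps$cycles_per_frequency * fs / f)
    t_rel <- (seq_len(n) - 1) / fs
    x1 <- A * sin(2 * pi * f * t_rel)
    # phasor convention: s(t) = Re(S) sin(wt) + Im(S) cos(wt)
    X <- complex(real = -A, imaginary = 0)        # x_sys = -x_trap1
    F1 <- chis[i] * X
    f1 <- Re(F1) * sin(2 * pi * f * t_rel) + Im(F1) * cos(2 * pi * f * t_rel)
    f2 <- -f1
    if (traps$noise_frac_force > 0) {
      f1 <- f1 * (1 + stats::rnorm(n, 0, traps$noise_frac_force))
      f2 <- f2 * (1 + stats::rnorm(n, 0, traps$noise_frac_force))
    }
    if (traps$noise_sd_force > 0) {
      f1 <- f1 + stats::rnorm(n, 0, traps$noise_sd_force)
      f2 <- f2 + stats::rnorm(n, 0, traps$noise_sd_force)
    }
    segs[[i]] <- data.frame(
      time_s = t_offset + t_rel, x_trap1_um = x1,
      f1_pN = f1, f2_pN = f2, freq_hz = f
    )
    t_offset <- t_offset + n / fs
  }
  out <- list(
    data = do.call(rbind, segs),
    drive_frequencies = traps$drive_frequencies,
    sampling_rate = fs,
    amplitude_um = A,
    diameter = material$diameter,
    medium_viscosity = material$medium_viscosity,
    truth = list(material = material, traps = traps,
                 chi_sys = chis),
    seed = traps$seed
  )
  class(out) <- "force_sweep"
  out
}

#' @export
print.force_sweep <- function(x, ...) {
  cat(sprintf("Dual-trap force sweep: %d samples, %d frequencies (%g-%g Hz), fs = %g Hz\n",
              nrow(x$data), length(x$drive_frequencies),
              min(x$drive_frequencies), max(x$drive_frequencies),
              x$sampling_rate))
  invisible(x)
}

#' Simulate step-indentation force relaxation traces
#'
#' Each of `n_steps` repetitions follows
#' `F(t) = F0 + (Fp - F0) exp(-t/tau)` from its own onset, for both
#' traps, with seeded additive Gaussian noise.
#'
#' @param traps a [trap_truth()] (supplies sampling rate, noise sd, seed).
#' @param F0_1,Fp_1 resting and peak force on trap 1, pN.
#' @param F0_2,Fp_2 resting and peak force on trap 2, pN.
#' @param tau relaxation time constant, s.
#' @param n_steps number of step repetitions.
#' @param step_period_s time between step onsets, s (0.2 Hz steps = 5 s).
#' @return list with `time` (s), `f1`, `f2` (pN), `step_onsets` (s).
#' @export
simulate_step_relaxation <- function(traps, F0_1, Fp_1, F0_2, Fp_2, tau,
                                     n_steps = 3, step_period_s = 5) {
  stopifnot(inherits(traps, "trap_truth"))
  if (tau <= 0) stop("tau must be positive")
  fs <- traps$sampling_rate
  n_per <- round(step_period_s * fs)
  onsets <- (seq_len(n_steps) - 1) * step_period_s
  t <- (seq_len(n_steps * n_per) - 1) / fs
  t_rel <- t %% step_period_s
  f1 <- F0_1 + (Fp_1 - F0_1) * exp(-t_rel / tau)
  f2 <- F0_2 + (Fp_2 - F0_2) * exp(-t_rel / tau)
  set.seed(traps$seed)
  if (traps$noise_sd_force > 0) {
    f1 <- f1 + stats::rnorm(length(t), 0, traps$noise_sd_force)
    f2 <- f2 + stats::rnorm(length(t), 0, traps$noise_sd_force)
  }
  list(time = t, f1 = f1, f2 = f2, step_onsets = onsets,
       truth = list(F0_1 = F0_1, Fp_1 = Fp_1, F0_2 = F0_2, Fp_2 = Fp_2,
                    tau = tau))
}

#' Step forces consistent with a droplet's surface tension
#'
#' Computes antisymmetric resting forces such that the tension chain
#' (resting extension, resting stiffness, surface tension) recovers the
#' material's `gamma` exactly: `chi0 = pi gamma / (-ln theta0 + 0.68)`
#' and `F0 = chi0 A / (1 - chi0 (1/k1 + 1/k2))`. Peak forces use the
#' instantaneous (high-frequency) droplet stiffness
#' `chi_inf = E R P(theta0) + prefactor gamma`, and the relaxation time
#' is the Maxwell time `eta / E`.
#'
#' @param material a [material_truth()].
#' @param traps a [trap_truth()].
#' @return list with `F0_1`, `Fp_1`, `F0_2`, `Fp_2` (pN), `tau` (s) and
#'   the implied `chi0` (pN/um), suitable for
#'   [simulate_step_relaxation()].
#' @export
consistent_step_forces <- function(material, traps) {
  A <- traps$step_amplitude_nm / 1000
  chi0 <- pi * material$gamma / (-log(material$theta0) + 0.68)
  F0 <- chi0 * A / (1 - chi0 * (1 / traps$k1 + 1 / traps$k2))
  geom <- contact_geometry(material$theta0)
  chi_inf <- material$E * material$radius * geom$geometry_poly +
    geom$tension_prefactor * material$gamma
  Fp <- chi_inf * A / (1 + chi_inf * (1 / traps$k1 + 1 / traps$k2))
  list(F0_1 = F0, Fp_1 = Fp, F0_2 = -F0, Fp_2 = -Fp,
       tau = material$eta_dashpot / material$E, chi0 = chi0)
}
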