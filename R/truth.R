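#' Ground-truth material parameters of a viscoelastic droplet
#'
#' Bundles the parameters describing a Maxwell-type protein droplet
#' (a spring of plateau modulus `E` in series with a dashpot of viscosity
#' `eta_dashpot`) with surface tension `gamma`, held in a medium of
#' viscosity `medium_viscosity`. These are the quantities the rheology
#' chain is supposed to recover, so they serve as ground truth for the
#' synthetic generators.
#'
#' @param E plateau (spring) modulus, Pa.
#' @param eta_dashpot dashpot viscosity, Pa s.
#' @param gamma surface tension, pN/um.
#' @param theta0 normalized bead-droplet contact parameter, in (0, 1).
#' @param diameter droplet diameter D, um (radius R = D/2).
#' @param medium_viscosity viscosity of the surrounding medium, Pa s.
#'   The droplet drag entering the two-trap coupling is
#'   `xi = 3 * pi * medium_viscosity * D` (pN s/um once units are resolved).
#'
#' @return An object of class `material_truth`. The analytic crossover
#'   frequency `f_c = E / (2 * pi * eta_dashpot)` (Hz) is attached as
#'   field `crossover_hz`.
#' @export
#' @examples
#' m <- material_truth(E = 2, eta_dashpot = 0.1)
#' m$crossover_hz  # 3.1831 Hz
material_truth <- function(E, eta_dashpot, gamma = 1, theta0 = 0.5,
                           diameter = 5, medium_viscosity = 1e-3) {
  stopifnot(
    is.numeric(E), length(E) == 1L, E > 0,
    is.numeric(eta_dashpot), eta_dashpot > 0,
    is.numeric(gamma), gamma >= 0,
    is.numeric(theta0), theta0 > 0, theta0 < 1,
    is.numeric(diameter), diameter > 0,
    is.numeric(medium_viscosity), medium_viscosity > 0
  )
  out <- list(
    E = E, eta_dashpot = eta_dashpot, gamma = gamma, theta0 = theta0,
    diameter = diameter, radius = diameter / 2,
    medium_viscosity = medium_viscosity,
    crossover_hz = E / (2 * pi * eta_dashpot)
  )
  class(out) <- "material_truth"
  out
}

#' Ground-truth dual-trap acquisition parameters
#'
#' @param k1,k2 trap stiffnesses, pN/um.
#' @param sampling_rate acquisition rate, Hz. Must be at least 20x the
#'   highest drive frequency.
#' @param step_amplitude_nm drive amplitude A for both the step
#'   indentations and the sinusoidal sweep, nm.
#' @param drive_frequencies sinusoidal drive frequencies, Hz. Default is
#'   the octave sweep 0.5, 1, 2, ..., 64 Hz.
#' @param cycles_per_frequency integer drive cycles recorded per
#'   frequency (integer cycles avoid spectral leakage in the single-bin
#'   lock-in). Must be >= 4.
#' @param noise_sd_force additive Gaussian force noise, pN (per sample).
#' @param noise_frac_force multiplicative Gaussian force noise (relative
#'   sd; 0.05 means 5 percent).
#' @param seed integer seed for the generator.
#'
#' @return An object of class `trap_truth`.
#' @export
trap_truth <- function(k1 = 50, k2 = 50, sampling_rate = 5000,
                       step_amplitude_nm = 100,
                       drive_frequencies = 2^seq(-1, 6),
                       cycles_per_frequency = 10L,
                       noise_sd_force = 0, noise_frac_force = 0,
                       seed = 1L) {
  stopifnot(
    k1 > 0, k2 > 0, sampling_rate > 0,
    step_amplitude_nm >= 0,
    all(drive_frequencies > 0), !is.unsorted(drive_frequencies),
    cycles_per_frequency >= 4,
    noise_sd_force >= 0, noise_frac_force >= 0
  )
  if (sampling_rate < 20 * max(drive_frequencies)) {
    stop("sampling_rate must be at least 20x the highest drive frequency (",
         max(drive_frequencies), " Hz); got ", sampling_rate, " Hz")
  }
  out <- list(
    k1 = k1, k2 = k2, sampling_rate = sampling_rate,
    step_amplitude_nm = step_amplitude_nm,
    drive_frequencies = drive_frequencies,
    cycles_per_frequency = as.integer(cycles_per_frequency),
    noise_sd_force = noise_sd_force,
    noise_frac_force = noise_frac_force,
    seed = as.integer(seed)
  )
  class(out) <- "trap_truth"
  out
}

#' @export
print.material_truth <- function(x, ...) {
  cat("Maxwell droplet truth:\n")
  cat(sprintf("  E = %g Pa, dashpot eta = %g Pa s  (f_c = %.4f Hz)\n",
              x$E, x$eta_dashpot, x$crossover_hz))
  cat(sprintf("  gamma = %g pN/um, theta0 = %g, D = %g um, medium eta = %g Pa s\n",
              x$gamma, x$theta0, x$diameter, x$medium_viscosity))
  invisible(x)
}

#' @export
print.trap_truth <- function(x, ...) {
  cat(sprintf("Dual-trap protocol: k1 = %g, k2 = %g pN/um, fs = %g Hz, A = %g nm\n",
              x$k1, x$k2, x$sampling_rate, x$step_amplitude_nm))
  cat(sprintf("  drive: %s Hz, %d cycles each\n",
              paste(x$drive_frequencies, collapse = ", "),
              x$cycles_per_frequency))
  invisible(x)
}

# Viscous drag of a droplet of diameter D in a medium of viscosity eta.
# With eta in Pa s and D in um: Pa s um = pN s/um, so xi * omega (rad/s)
# has units pN/um, i.e. stiffness.
droplet_drag <- function(medium_viscosity, diameter) {
  3 * pi * medium_viscosity * diameter
}
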