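# ---- contact geometry -------------------------------------------------------

#' Contact-geometry factors for a trapped bead on a droplet surface
#'
#' The conversion from droplet spring constant to shear modulus depends on
#' the normalized bead-droplet contact parameter `theta0` through two
#' polynomial factors: the tension prefactor `1.25 + 4.36 theta0^2`
#' multiplying the capillary contribution, and the geometry polynomial
#' `5.47 t^5 - 29.28 t^4 + 23.29 t^3 - 5.08 t^2 + 3.79 t - 0.02`
#' multiplying `R G*`.
#'
#' @param theta0 contact parameter in (0, 1).
#' @return list with `tension_prefactor` and `geometry_poly`.
#' @export
#' @examples
#' contact_geometry(0.5)  # poly = 1.8571875, prefactor = 2.34
contact_geometry <- function(theta0) {
  stopifnot(is.numeric(theta0), theta0 > 0, theta0 < 1)
  poly <- 5.47 * theta0^5 - 29.28 * theta0^4 + 23.29 * theta0^3 -
    5.08 * theta0^2 + 3.79 * theta0 - 0.02
  list(
    tension_prefactor = 1.25 + 4.36 * theta0^2,
    geometry_poly = poly
  )
}

# ---- trap calibration -------------------------------------------------------

#' Calibrate trap stiffness from a force-displacement profile
#'
#' Fits a line through the linear regime of an optical force profile,
#' `F = k x`, restricted to a symmetric window around zero (default
#' +/- 100 nm), and reports the slope as the trap stiffness.
#'
#' @param profile data.frame with columns `x_um` (displacement, um) and
#'   `f_pN` (force, pN).
#' @param window_nm half-width of the fit window, nm.
#' @return list of class `trap_calibration` with `k` (pN/um),
#'   `r_squared`, `n_points`, `window_nm` and a `degenerate` flag set
#'   when the forces carry no signal.
#' @export
calibrate_trap_stiffness <- function(profile, window_nm = 100) {
  stopifnot(is.data.frame(profile), all(c("x_um", "f_pN") %in% names(profile)))
  w <- window_nm / 1000
  sel <- abs(profile$x_um) <= w
  if (sum(sel) < 3) {
    stop("fewer than 3 profile points inside the +/-", window_nm, " nm window")
  }
  x <- profile$x_um[sel]
  f <- profile$f_pN[sel]
  degenerate <- all(f == 0)
  if (degenerate) {
    warning("all forces zero inside the calibration window; k = 0")
    out <- list(k = 0, r_squared = NA_real_, n_points = sum(sel),
                window_nm = window_nm, degenerate = TRUE)
  } else {
    fit <- stats::lm(f ~ x)
    out <- list(
      k = unname(stats::coef(fit)[["x"]]),
      r_squared = suppressWarnings(summary(fit)$r.squared),
      n_points = sum(sel), window_nm = window_nm, degenerate = FALSE
    )
  }
  class(out) <- "trap_calibration"
  out
}

# ---- step relaxation --------------------------------------------------------

#' Fit exponential force relaxation after step indentation
#'
#' Each relaxation segment follows
#' `F(t) = F0 + (Fp - F0) exp(-t / tau)` with peak force `Fp` just after
#' the step and resting force `F0` at long times. Segments (one per step
#' onset) are aligned to their onset and averaged before fitting.
#'
#' @param time time stamps, s.
#' @param force force trace for one trap, pN.
#' @param step_onsets times (s) at which steps were applied; each segment
#'   runs to the next onset (or trace end).
#' @return list of class `step_relaxation_fit` with `F0`, `Fp`, `tau`
#'   (their point estimates), standard errors, the averaged segment and a
#'   `degenerate` flag for constant traces where `tau` is unidentifiable.
#' @export
fit_step_relaxation <- function(time, force, step_onsets) {
  stopifnot(length(time) == length(force), length(step_onsets) >= 1)
  segs <- lapply(seq_along(step_onsets), function(i) {
    t0 <- step_onsets[i]
    t1 <- if (i < length(step_onsets)) step_onsets[i + 1] else max(time) + 1
    sel <- time >= t0 & time < t1
    data.frame(t = time[sel] - t0, f = force[sel])
  })
  if (any(vapply(segs, nrow, 1L) < 10)) {
    stop("each relaxation segment needs >= 10 samples")
  }
  # align on the common time grid of the shortest segment, then average
  n_min <- min(vapply(segs, nrow, 1L))
  f_avg <- rowMeans(vapply(segs, function(s) s$f[seq_len(n_min)],
                           numeric(n_min)))
  t_avg <- segs[[1]]$t[seq_len(n_min)]

  if (stats::sd(f_avg) < 1e-12 * (abs(mean(f_avg)) + 1e-12)) {
    out <- list(F0 = mean(f_avg), Fp = mean(f_avg), tau = NA_real_,
                se = c(F0 = NA, Fp = NA, tau = NA), degenerate = TRUE,
                segment = data.frame(t = t_avg, f = f_avg))
    class(out) <- "step_relaxation_fit"
    return(out)
  }

  # starting values: F0 from tail, Fp from head, tau from 1/e crossing
  F0_0 <- mean(utils::tail(f_avg, max(3L, n_min %/% 10)))
  Fp_0 <- f_avg[1]
  target <- F0_0 + (Fp_0 - F0_0) * exp(-1)
  idx <- which(abs(f_avg - target) == min(abs(f_avg - target)))[1]
  tau_0 <- max(t_avg[idx], diff(t_avg[1:2]))

  fit <- minpack.lm::nlsLM(
    f ~ F0 + (Fp - F0) * exp(-t / tau),
    data = data.frame(t = t_avg, f = f_avg),
    start = list(F0 = F0_0, Fp = Fp_0, tau = tau_0),
    lower = c(-Inf, -Inf, 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(F0 = NA, Fp = NA, tau = NA))
  out <- list(F0 = unname(co[["F0"]]), Fp = unname(co[["Fp"]]),
              tau = unname(co[["tau"]]), se = se, degenerate = FALSE,
              segment = data.frame(t = t_avg, f = f_avg))
  class(out) <- "step_relaxation_fit"
  out
}

# ---- resting stiffness and surface tension ----------------------------------

#' Resting droplet spring constant and surface tension
#'
#' From the resting forces of the two traps after step relaxation, the
#' resting droplet extension is `dx0 = A + F0_1/k1 - F0_2/k2`, the resting
#' spring constant `chi0 = (F0_1 - F0_2) / (2 dx0)`, and the surface
#' tension `gamma = (chi0 / pi) (-ln theta0 + 0.68)`.
#'
#' @param F0_1,F0_2 resting forces on traps 1 and 2, pN.
#' @param k1,k2 trap stiffnesses, pN/um.
#' @param A step amplitude, um.
#' @param theta0 contact parameter in (0, 1).
#' @return list of class `tension_estimate` with `delta_x0` (um),
#'   `chi0` (pN/um), `gamma` (pN/um) and `theta0`.
#' @export
#' @examples
#' # A = 0.1 um, k = 50 pN/um, F0 = +/-1 pN, theta0 = 0.5
#' resting_stiffness_and_tension(1, -1, 50, 50, 0.1, 0.5)
resting_stiffness_and_tension <- function(F0_1, F0_2, k1, k2, A, theta0) {
  stopifnot(A > 0, k1 > 0, k2 > 0, theta0 > 0, theta0 < 1)
  delta_x0 <- A + F0_1 / k1 - F0_2 / k2
  if (delta_x0 <= 0) {
    stop("non-physical geometry: resting extension delta_x0 <= 0")
  }
  chi0 <- (F0_1 - F0_2) / (2 * delta_x0)
  gamma <- (chi0 / pi) * (-log(theta0) + 0.68)
  out <- list(delta_x0 = delta_x0, chi0 = chi0, gamma = gamma,
              theta0 = theta0)
  class(out) <- "tension_estimate"
  out
}

# ---- lock-in spectrum -------------------------------------------------------

# Exact-frequency quadrature projection of one segment: least-squares fit
# of a*sin(wt) + b*cos(wt) + c. Returns the complex amplitude a + ib.
# Identical to the single-bin DFT for an integer number of cycles, exact
# for a pure tone regardless.
quadrature_amplitude <- function(t, s, f_hz) {
  w <- 2 * pi * f_hz
  X <- cbind(sin(w * t), cos(w * t), 1)
  cf <- stats::lm.fit(X, s)$coefficients
  complex(real = cf[1], imaginary = cf[2])
}

#' Per-frequency complex amplitudes of a dual-trap sweep
#'
#' Projects each frequency segment of the recording onto the drive tone
#' (quadrature lock-in at the exact drive frequency) to obtain the complex
#' amplitudes of the two trap forces and of the system extension
#' `x_sys = x_trap2 - x_trap1` (trap 2 is stationary, so `x_sys` is the
#' negated commanded trap-1 trajectory). Phases are relative to the drive
#' sine.
#'
#' @param sweep a `force_sweep` object (see [simulate_dual_trap_sweep()]
#'   or [read_force_sweep()]).
#' @return data.frame with columns `freq_hz`, `n_samples`, and complex
#'   columns `F1`, `F2` (pN) and `x_sys` (um).
#' @export
lockin_spectrum <- function(sweep) {
  stopifnot(inherits(sweep, "force_sweep"))
  d <- sweep$data
  freqs <- sweep$drive_frequencies
  res <- lapply(freqs, function(f) {
    sel <- d$freq_hz == f
    n <- sum(sel)
    if (n < 2 * 10) stop("segment at ", f, " Hz too short to resolve the drive")
    t_rel <- d$time_s[sel] - d$time_s[sel][1]
    if (n / (sweep$sampling_rate / f) < 1) {
      stop("fewer than one drive cycle at ", f, " Hz")
    }
    data.frame(
      freq_hz = f, n_samples = n,
      F1 = quadrature_amplitude(t_rel, d$f1_pN[sel], f),
      F2 = quadrature_amplitude(t_rel, d$f2_pN[sel], f),
      x_sys = -quadrature_amplitude(t_rel, d$x_trap1_um[sel], f)
    )
  })
  do.call(rbind, res)
}

# ---- system and droplet spring constants ------------------------------------

#' Coupled spring constant of the two-trap-droplet system
#'
#' `chi_sys(omega) = (F1(omega) - F2(omega)) / (2 x_sys(omega))`, from the
#' complex lock-in amplitudes. Frequencies with vanishing drive amplitude
#' are dropped with a warning.
#'
#' @param amps data.frame from [lockin_spectrum()].
#' @return data.frame with `freq_hz` and complex `chi_sys` (pN/um).
#' @export
system_spring_constant <- function(amps) {
  stopifnot(all(c("freq_hz", "F1", "F2", "x_sys") %in% names(amps)))
  ok <- Mod(amps$x_sys) > 1e-12
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " frequencies with zero drive amplitude")
  }
  a <- amps[ok, , drop = FALSE]
  data.frame(
    freq_hz = a$freq_hz,
    chi_sys = (a$F1 - a$F2) / (2 * a$x_sys)
  )
}

#' Complex spring constant of the droplet alone
#'
#' Corrects the coupled system stiffness for the finite trap stiffnesses
#' and the viscous drag `xi = 3 pi eta_medium D` of the droplet:
#' `chi = chi_sys (4 k1 k2 + i xi w (k1 + k2)) /
#'        (2 k1 (2 k2 + i xi w) - 4 chi_sys (k1 + k2 + i xi w))`
#' with `w = 2 pi f` in rad/s so that `xi w` carries stiffness units.
#'
#' @param chi_sys data.frame with `freq_hz` and complex `chi_sys`.
#' @param k1,k2 trap stiffnesses, pN/um.
#' @param xi droplet drag, pN s/um.
#' @return data.frame with `freq_hz`, complex `chi` (pN/um) and a logical
#'   `recoverable` column (FALSE where the denominator is near-singular).
#' @export
droplet_spring_constant <- function(chi_sys, k1, k2, xi) {
  stopifnot(k1 > 0, k2 > 0, xi >= 0)
  w <- 2 * pi * chi_sys$freq_hz
  cs <- chi_sys$chi_sys
  num <- cs * (4 * k1 * k2 + 1i * xi * w * (k1 + k2))
  den <- 2 * k1 * (2 * k2 + 1i * xi * w) - 4 * cs * (k1 + k2 + 1i * xi * w)
  recoverable <- Mod(den) > 1e-9 * (4 * k1 * k2)
  if (!all(recoverable)) {
    warning("near-singular trap coupling at ", sum(!recoverable),
            " frequencies; flagged unrecoverable")
  }
  chi <- ifelse(recoverable, num / den, NA_complex_)
  data.frame(freq_hz = chi_sys$freq_hz, chi = chi, recoverable = recoverable)
}

# ---- shear modulus ----------------------------------------------------------

#' Complex shear modulus from the droplet spring constant
#'
#' Subtracts the capillary (surface-tension) contribution and divides by
#' the contact-geometry factor:
#' `G*(w) = (chi(w) - (1.25 + 4.36 theta0^2) gamma) / (R P(theta0))`
#' with `P` the geometry polynomial of [contact_geometry()]. With `chi`
#' and `gamma` in pN/um and `R` in um, `G*` is in Pa.
#'
#' @param chi data.frame with `freq_hz` and complex `chi`.
#' @param gamma surface tension, pN/um.
#' @param theta0 contact parameter in (0, 1).
#' @param radius droplet radius R, um.
#' @return object of class `modulus_spectrum`: data.frame with `freq_hz`,
#'   complex `G_star`, `G_prime` (storage, Pa) and `G_doubleprime`
#'   (loss, Pa).
#' @export
shear_modulus <- function(chi, gamma, theta0, radius) {
  stopifnot(radius > 0, gamma >= 0)
  geom <- contact_geometry(theta0)
  if (geom$geometry_poly <= 0) {
    stop("geometry polynomial non-positive at theta0 = ", theta0,
         "; valid contact parameters require P(theta0) > 0 ",
         "(P > 0 holds for theta0 in about (0.006, 1))")
  }
  ok <- if ("recoverable" %in% names(chi)) chi$recoverable else TRUE
  g <- (chi$chi - geom$tension_prefactor * gamma) /
    (radius * geom$geometry_poly)
  out <- data.frame(
    freq_hz = chi$freq_hz,
    G_star = g,
    G_prime = Re(g),
    G_doubleprime = Im(g)
  )[ok, , drop = FALSE]
  class(out) <- c("modulus_spectrum", "data.frame")
  out
}

# ---- Maxwell fit ------------------------------------------------------------

#' Maxwell-model storage and loss moduli
#'
#' For a spring `E` in series with a dashpot `eta` (relaxation time
#' `tau_r = eta / E`), at drive frequency `f` (Hz, `w = 2 pi f` rad/s):
#' `G' = E (w tau_r)^2 / (1 + (w tau_r)^2)` and
#' `G'' = E w tau_r / (1 + (w tau_r)^2)`.
#'
#' @param f_hz frequencies, Hz.
#' @param E plateau modulus, Pa.
#' @param eta dashpot viscosity, Pa s.
#' @return data.frame `freq_hz`, `G_prime`, `G_doubleprime`.
#' @export
maxwell_modulus <- function(f_hz, E, eta) {
  wt <- 2 * pi * f_hz * eta / E
  data.frame(
    freq_hz = f_hz,
    G_prime = E * wt^2 / (1 + wt^2),
    G_doubleprime = E * wt / (1 + wt^2)
  )
}

#' Fit a Maxwell element to a modulus spectrum
#'
#' Joint nonlinear regression of storage and loss moduli against the
#' Maxwell model, with relative (log-residual) weighting because the
#' moduli span decades across the sweep. Parameters are fitted on the log
#' scale to enforce positivity. Reports the crossover frequency
#' `omega_c = E / (2 pi eta)` in Hz with a 95 percent confidence interval
#' from first-order propagation of the parameter covariance, and the
#' characteristic time `tau_char = 1 / omega_c`.
#'
#' @param spectrum a `modulus_spectrum` (or data.frame with `freq_hz`,
#'   `G_prime`, `G_doubleprime`).
#' @return list of class `maxwell_fit` with `E` (Pa), `eta` (Pa s),
#'   `omega_c` (Hz), `omega_c_ci` (95 percent CI, Hz), `tau_char` (s),
#'   `residuals` (log scale), and `extrapolated` (TRUE when the fitted
#'   crossover lies outside the measured band).
#' @export
fit_maxwell <- function(spectrum) {
  stopifnot(all(c("freq_hz", "G_prime", "G_doubleprime") %in% names(spectrum)))
  sp <- spectrum[is.finite(spectrum$G_prime) &
                   is.finite(spectrum$G_doubleprime), , drop = FALSE]
  pos <- sp$G_prime > 0 & sp$G_doubleprime > 0
  if (any(!pos)) {
    warning("excluding ", sum(!pos), " frequencies with non-positive moduli")
    sp <- sp[pos, , drop = FALSE]
  }
  if (nrow(sp) < 4) stop("need >= 4 frequencies to fit the Maxwell element")

  resid_fun <- function(p) {
    m <- maxwell_modulus(sp$freq_hz, exp(p[1]), exp(p[2]))
    c(log(m$G_prime) - log(sp$G_prime),
      log(m$G_doubleprime) - log(sp$G_doubleprime))
  }
  # initial guess: E from the high-frequency plateau of G', crossover
  # from where G' and G'' are closest
  E0 <- max(sp$G_prime)
  i_c <- which.min(abs(log(sp$G_prime) - log(sp$G_doubleprime)))
  f_c0 <- sp$freq_hz[i_c]
  eta0 <- E0 / (2 * pi * f_c0)
  fit <- minpack.lm::nls.lm(
    par = c(log(E0), log(eta0)), fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- fit$par
  E <- exp(p[1]); eta <- exp(p[2])
  omega_c <- E / (2 * pi * eta)

  n <- length(fit$fvec)
  sigma2 <- sum(fit$fvec^2) / max(n - 2, 1)
  vc <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) {
    matrix(NA_real_, 2, 2)
  })
  # log omega_c = log E - log eta - log 2pi
  var_lwc <- vc[1, 1] + vc[2, 2] - 2 * vc[1, 2]
  ci <- if (is.finite(var_lwc) && var_lwc >= 0) {
    omega_c * exp(c(-1, 1) * 1.96 * sqrt(var_lwc))
  } else c(NA_real_, NA_real_)

  out <- list(
    E = E, eta = eta, omega_c = omega_c, omega_c_ci = ci,
    tau_char = 1 / omega_c, residuals = fit$fvec,
    vcov_log = vc,
    extrapolated = omega_c < min(sp$freq_hz) | omega_c > max(sp$freq_hz)
  )
  class(out) <- "maxwell_fit"
  out
}

#' @export
print.maxwell_fit <- function(x, ...) {
  cat(sprintf("Maxwell fit: E = %.4g Pa, eta = %.4g Pa s\n", x$E, x$eta))
  cat(sprintf("  crossover omega_c = %.4g Hz (95%% CI %.4g-%.4g), tau = %.4g s%s\n",
              x$omega_c, x$omega_c_ci[1], x$omega_c_ci[2], x$tau_char,
              if (isTRUE(x$extrapolated)) "  [extrapolated]" else ""))
  invisible(x)
}

# ---- full chain -------------------------------------------------------------

#' Full droplet microrheology chain
#'
#' Convenience wrapper running lock-in projection, system and droplet
#' spring constants, shear modulus and Maxwell fit on one recorded sweep.
#'
#' @param sweep a `force_sweep`.
#' @param k1,k2 trap stiffnesses, pN/um.
#' @param gamma surface tension, pN/um (from
#'   [resting_stiffness_and_tension()] on the same droplet).
#' @param theta0 contact parameter.
#' @return list with `spectrum` (the `modulus_spectrum`), `chi_sys`,
#'   `chi`, and `maxwell` (the `maxwell_fit`).
#' @export
droplet_rheology <- function(sweep, k1, k2, gamma, theta0) {
  amps <- lockin_spectrum(sweep)
  chi_sys <- system_spring_constant(amps)
  xi <- droplet_drag(sweep$medium_viscosity, sweep$diameter)
  chi <- droplet_spring_constant(chi_sys, k1, k2, xi)
  spectrum <- shear_modulus(chi, gamma, theta0, sweep$diameter / 2)
  list(
    spectrum = spectrum, chi_sys = chi_sys, chi = chi,
    maxwell = fit_maxwell(spectrum)
  )
}
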