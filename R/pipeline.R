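# ---- pipeline orchestration -------------------------------------------------

#' Run the analysis pipeline described by a config
#'
#' Executes the requested stages in a fixed dependency order (rheology,
#' frap, msd, coloc, fret, calcium), reading the declared inputs,
#' writing tidy CSV/JSON outputs into the output directory together
#' with a config echo and a run log (package version, config hash,
#' seed). A stage error aborts with the stage name; results of earlier
#' stages are preserved on disk.
#'
#' @param config a `run_config` from [load_config()], or a path to one.
#' @return named list of per-stage results, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  cfg_plain <- unclass(config)
  cfg_hash <- digest::digest(cfg_plain)
  jsonlite::write_json(cfg_plain, file.path(outdir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(c(
    paste0("condensateR ", as.character(utils::packageVersion("condensateR"))),
    paste0("config_hash: ", cfg_hash),
    paste0("seed: ", config$seed),
    paste0("started: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  ), file.path(outdir, "run_log.txt"))

  order <- c("rheology", "frap", "msd", "coloc", "fret", "calcium")
  stages <- order[order %in% config$stages]
  results <- list()
  for (st in stages) {
    results[[st]] <- tryCatch(
      switch(st,
        rheology = stage_rheology(config, outdir),
        frap = stage_frap(config, outdir),
        msd = stage_msd(config, outdir),
        coloc = stage_coloc(config, outdir),
        fret = stage_fret(config, outdir),
        calcium = stage_calcium(config, outdir)
      ),
      error = function(e) {
        stop("stage '", st, "' failed: ", conditionMessage(e), call. = FALSE)
      }
    )
  }
  invisible(results)
}

stage_rheology <- function(config, outdir) {
  p <- config$rheology
  sweep <- read_force_sweep(p$sweep_path,
                            diameter = p$droplet_diameter_um,
                            medium_viscosity = p$medium_viscosity_pa_s)
  gamma <- p$gamma_pn_um
  tension <- NULL
  if (!is.null(p$steps_path)) {
    # steps table: t_s, f1_pN, f2_pN, step (integer step index)
    steps <- utils::read.csv(p$steps_path)
    if (!all(c("t_s", "f1_pN", "f2_pN", "step") %in% names(steps))) {
      stop("steps table needs columns t_s, f1_pN, f2_pN, step")
    }
    onsets <- vapply(split(steps$t_s, steps$step), min, numeric(1))
    f1 <- fit_step_relaxation(steps$t_s, steps$f1_pN, onsets)
    f2 <- fit_step_relaxation(steps$t_s, steps$f2_pN, onsets)
    tension <- resting_stiffness_and_tension(
      f1$F0, f2$F0, p$k1, p$k2, p$step_amplitude_nm / 1000, p$theta0)
    gamma <- tension$gamma
  }
  if (is.null(gamma)) {
    stop("rheology needs either gamma_pn_um or a steps_path to measure it")
  }
  res <- droplet_rheology(sweep, p$k1, p$k2, gamma, p$theta0)
  utils::write.csv(
    data.frame(f_Hz = res$spectrum$freq_hz,
               G_prime_Pa = res$spectrum$G_prime,
               G_doubleprime_Pa = res$spectrum$G_doubleprime),
    file.path(outdir, "modulus_spectrum.csv"), row.names = FALSE)
  mx <- res$maxwell
  jsonlite::write_json(
    list(E_Pa = mx$E, eta_Pa_s = mx$eta, omega_c_Hz = mx$omega_c,
         omega_c_ci_Hz = mx$omega_c_ci, tau_char_s = mx$tau_char,
         gamma_pN_um = gamma, extrapolated = mx$extrapolated),
    file.path(outdir, "maxwell_fit.json"), auto_unbox = TRUE, digits = NA)
  c(res, list(tension = tension, sweep = sweep))
}

stage_frap <- function(config, outdir) {
  p <- config$frap
  raw <- utils::read.csv(p$curve_path)
  curve <- normalize_frap(raw,
                          bleach_rate_correction = isTRUE(p$bleach_rate_correction))
  fit <- fit_frap(curve)
  D <- if (!is.null(p$bleach_radius_um)) {
    soumpasis_diffusion(fit$t_half, p$bleach_radius_um)
  } else NA_real_
  jsonlite::write_json(
    list(Mf = fit$Mf, tau_per_s = fit$tau, t_half_s = fit$t_half,
         D_um2_s = D, flag = fit$flag),
    file.path(outdir, "frap_fit.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(curve, file.path(outdir, "frap_normalized.csv"),
                   row.names = FALSE)
  list(curve = curve, fit = fit, D = D)
}

stage_msd <- function(config, outdir) {
  p <- config$msd
  tracks <- read_tracks(p$tracks_path)
  msd <- mean_squared_displacement(tracks, p$max_lag_fraction)
  pl <- fit_powerlaw(msd)
  cls <- classify_mobility(tracks, p$min_net_displacement_um,
                           p$min_mean_speed_um_s)
  utils::write.csv(msd, file.path(outdir, "msd.csv"), row.names = FALSE)
  utils::write.csv(cls$labels, file.path(outdir, "mobility_labels.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(exponent = pl$exponent, prefactor = pl$prefactor,
         frac_mobile = mean(cls$labels$mobile)),
    file.path(outdir, "msd_summary.json"), auto_unbox = TRUE, digits = NA)
  list(msd = msd, powerlaw = pl, mobility = cls)
}

stage_coloc <- function(config, outdir) {
  p <- config$coloc
  ch1 <- read_image_stack(p$ch1_path)[[1]]
  ch2 <- read_image_stack(p$ch2_path)[[1]]
  res <- scramble_null(ch1, ch2, block_length = p$block_length_px,
                       n_perm = p$n_perm, seed = config$seed)
  jsonlite::write_json(
    list(rho = res$rho_obs, p_empirical = res$p_empirical,
         p_parametric = res$p_parametric, n_perm = res$n_perm,
         block_length_px = res$block_length, seed = res$seed),
    file.path(outdir, "coloc_result.json"), auto_unbox = TRUE, digits = NA)
  res
}

stage_fret <- function(config, outdir) {
  p <- config$fret
  dd <- read_image_stack(p$dd_path)[[1]]
  da <- read_image_stack(p$da_path)[[1]]
  aa <- read_image_stack(p$aa_path)[[1]]
  fs <- fret_index_map(dd, da, aa, d = p$donor_bleed_d, a = p$crossex_a,
                       background = p$background)
  write_image_stack(ifelse(is.na(fs$index_map), 0, fs$index_map),
                    file.path(outdir, "fret_index_map.tif"))
  jsonlite::write_json(
    list(mean_index = fs$mean_index, clip_fraction = fs$clip_fraction,
         n_excluded = fs$n_excluded),
    file.path(outdir, "fret_summary.json"), auto_unbox = TRUE, digits = NA)
  fs
}

stage_calcium <- function(config, outdir) {
  p <- config$calcium
  trace <- utils::read.csv(p$trace_path)$intensity
  ct <- delta_f_over_f(trace, p$n_baseline, p$smooth_window)
  utils::write.csv(data.frame(frame = seq_along(ct$dff), dff = ct$dff),
                   file.path(outdir, "calcium_dff.csv"), row.names = FALSE)
  ct
}

# ---- reporting --------------------------------------------------------------

#' Force-displacement (Lissajous) data per drive frequency
#'
#' For each frequency segment, pairs the system extension with the
#' differential force `(F1 - F2)/2`; under sinusoidal drive this traces
#' an ellipse whose slope reflects stiffness and whose enclosed area
#' (shoelace formula over one cycle) reflects dissipation per cycle.
#'
#' @param sweep a `force_sweep`.
#' @return data.frame `freq_hz`, `x_um`, `force_pN` plus an `area`
#'   attribute: named vector of per-frequency ellipse areas (pN um).
#' @export
lissajous_data <- function(sweep) {
  d <- sweep$data
  out <- data.frame(freq_hz = d$freq_hz, x_um = -d$x_trap1_um,
                    force_pN = (d$f1_pN - d$f2_pN) / 2)
  areas <- vapply(sweep$drive_frequencies, function(f) {
    sel <- out$freq_hz == f
    n_cycle <- round(sweep$sampling_rate / f)
    idx <- which(sel)[seq_len(min(n_cycle, sum(sel)))]
    x <- out$x_um[idx]; y <- out$force_pN[idx]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }, numeric(1))
  names(areas) <- sweep$drive_frequencies
  attr(out, "area") <- areas
  out
}

#' Render standard figures from a pipeline result bundle
#'
#' Best-effort rendering: each available result contributes a figure
#' (modulus spectrum with Maxwell overlay and crossover marker,
#' Lissajous ellipses, FRAP recovery, MSD in log-log coordinates);
#' missing results are skipped with a log message rather than an error.
#'
#' @param results list as returned by [run_pipeline()].
#' @param outdir directory for PDF output (NULL = do not write).
#' @return named list of ggplot objects, invisibly.
#' @export
write_report <- function(results, outdir = NULL) {
  plots <- list()
  if (!is.null(results$rheology)) {
    sp <- results$rheology$spectrum
    mx <- results$rheology$maxwell
    curve <- maxwell_modulus(
      exp(seq(log(min(sp$freq_hz)), log(max(sp$freq_hz)), length.out = 100)),
      mx$E, mx$eta)
    long <- rbind(
      data.frame(freq_hz = sp$freq_hz, modulus = sp$G_prime,
                 which = "G' (storage)", src = "data"),
      data.frame(freq_hz = sp$freq_hz, modulus = sp$G_doubleprime,
                 which = "G'' (loss)", src = "data"),
      data.frame(freq_hz = curve$freq_hz, modulus = curve$G_prime,
                 which = "G' (storage)", src = "fit"),
      data.frame(freq_hz = curve$freq_hz, modulus = curve$G_doubleprime,
                 which = "G'' (loss)", src = "fit")
    )
    plots$spectrum <- ggplot2::ggplot(
      long, ggplot2::aes(x = freq_hz, y = modulus, colour = which)) +
      ggplot2::geom_point(data = long[long$src == "data", ]) +
      ggplot2::geom_line(data = long[long$src == "fit", ]) +
      ggplot2::geom_vline(xintercept = mx$omega_c, linetype = "dashed") +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::labs(x = "frequency (Hz)", y = "modulus (Pa)",
                    title = sprintf("Maxwell fit: E = %.3g Pa, eta = %.3g Pa s, omega_c = %.3g Hz",
                                    mx$E, mx$eta, mx$omega_c))
    if (!is.null(results$rheology$sweep)) {
      ld <- lissajous_data(results$rheology$sweep)
      plots$lissajous <- ggplot2::ggplot(
        ld, ggplot2::aes(x = x_um, y = force_pN)) +
        ggplot2::geom_path(linewidth = 0.2) +
        ggplot2::facet_wrap(~freq_hz, scales = "free") +
        ggplot2::labs(x = "extension (um)", y = "force (pN)")
    }
  }
  if (!is.null(results$frap)) {
    cv <- results$frap$curve
    ft <- results$frap$fit
    post <- cv[cv$t_s >= 0, ]
    fitline <- data.frame(
      t_s = seq(0, max(post$t_s), length.out = 200))
    fitline$intensity <- ft$Mf * (1 - exp(-ft$tau * fitline$t_s))
    plots$frap <- ggplot2::ggplot(post, ggplot2::aes(t_s, intensity)) +
      ggplot2::geom_point() +
      ggplot2::geom_line(data = fitline, colour = "red") +
      ggplot2::labs(x = "time after bleach (s)", y = "normalized intensity",
                    title = sprintf("Mf = %.2f, t_half = %.2f s", ft$Mf,
                                    ft$t_half))
  }
  if (!is.null(results$msd)) {
    m <- results$msd$msd
    plots$msd <- ggplot2::ggplot(m, ggplot2::aes(lag_s, msd_um2)) +
      ggplot2::geom_point() + ggplot2::scale_x_log10() +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "lag (s)", y = "MSD (um^2)",
                    title = sprintf("power-law exponent n = %.2f",
                                    results$msd$powerlaw$exponent))
  }
  if (!is.null(outdir) && length(plots)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(plots)) {
      ggplot2::ggsave(file.path(outdir, paste0("report_", nm, ".pdf")),
                      plots[[nm]], width = 7, height = 5)
    }
  }
  if (!length(plots)) message("empty result list; nothing to report")
  invisible(plots)
}
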