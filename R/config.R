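# ---- run configuration ------------------------------------------------------

config_defaults <- function() {
  list(
    seed = 1L,
    outdir = "results",
    stages = character(0),
    rheology = list(
      sweep_path = NULL, steps_path = NULL,
      k1 = NULL, k2 = NULL, theta0 = NULL,
      droplet_diameter_um = NULL, medium_viscosity_pa_s = 1e-3,
      step_amplitude_nm = 100, gamma_pn_um = NULL
    ),
    frap = list(
      curve_path = NULL, bleach_radius_um = NULL,
      bleach_rate_correction = FALSE
    ),
    msd = list(
      tracks_path = NULL, max_lag_fraction = 0.25,
      min_net_displacement_um = 2, min_mean_speed_um_s = 0.2
    ),
    coloc = list(
      ch1_path = NULL, ch2_path = NULL,
      block_length_px = 25, n_perm = 199
    ),
    fret = list(
      dd_path = NULL, da_path = NULL, aa_path = NULL,
      donor_bleed_d = 0, crossex_a = 0, background = 0,
      pressure_table_path = NULL, pressures_kPa = NULL
    ),
    calcium = list(
      trace_path = NULL, n_baseline = 100, smooth_window = 5
    )
  )
}

required_keys <- list(
  rheology = c("sweep_path", "k1", "k2", "theta0", "droplet_diameter_um"),
  frap = "curve_path",
  msd = "tracks_path",
  coloc = c("ch1_path", "ch2_path"),
  fret = c("dd_path", "da_path", "aa_path"),
  calcium = "trace_path"
)

#' Load and validate a pipeline configuration
#'
#' Reads a YAML or JSON config, rejects unknown keys (typos refuse
#' loudly rather than silently using a default), fills defaults, and
#' checks that every requested stage has its required calibration and
#' input keys.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json: ", path)
  }
  defaults <- config_defaults()
  unknown_top <- setdiff(names(raw), names(defaults))
  if (length(unknown_top)) {
    stop("unknown config key(s): ", paste(unknown_top, collapse = ", "))
  }
  cfg <- defaults
  for (k in names(raw)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      unknown <- setdiff(names(raw[[k]]), names(defaults[[k]]))
      if (length(unknown)) {
        stop("unknown config key(s) in '", k, "': ",
             paste(unknown, collapse = ", "))
      }
      cfg[[k]][names(raw[[k]])] <- raw[[k]]
    } else {
      cfg[[k]] <- raw[[k]]
    }
  }
  cfg$stages <- as.character(cfg$stages)
  bad_stages <- setdiff(cfg$stages, names(required_keys))
  if (length(bad_stages)) {
    stop("unknown stage(s): ", paste(bad_stages, collapse = ", "))
  }
  for (st in cfg$stages) {
    for (key in required_keys[[st]]) {
      if (is.null(cfg[[st]][[key]])) {
        stop("stage '", st, "' requires config key '", st, ".", key, "'")
      }
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}
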