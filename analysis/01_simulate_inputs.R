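#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input consumed by the downstream
# analysis scripts, from known ground truth, into scratch/data/.
# Ground-truth parameters are echoed to JSON sidecars so later stages
# can score parameter recovery.

suppressPackageStartupMessages(library(condensateR))
seed <- 1L
data_dir <- "scratch/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

## Reference droplet: fluid-like condensate (Maxwell element)
mat <- material_truth(E = 2, eta_dashpot = 0.1, gamma = 1, theta0 = 0.5,
                      diameter = 5)
tr <- trap_truth(k1 = 50, k2 = 50, seed = seed)
cat("Droplet truth: E = 2 Pa, eta = 0.1 Pa s -> analytic crossover",
    sprintf("%.4f Hz\n", mat$crossover_hz))

sweep <- simulate_dual_trap_sweep(mat, tr)
write_force_sweep(sweep, file.path(data_dir, "sweep.csv"))

sf <- consistent_step_forces(mat, tr)
st <- simulate_step_relaxation(tr, sf$F0_1, sf$Fp_1, sf$F0_2, sf$Fp_2,
                               sf$tau)
write.csv(data.frame(t_s = st$time, f1_pN = st$f1, f2_pN = st$f2,
                     step = findInterval(st$time, st$step_onsets)),
          file.path(data_dir, "steps.csv"), row.names = FALSE)

## FRAP: mobile fraction 0.6, half-time 5 s (plus noisy replicates later)
write.csv(simulate_frap(Mf = 0.6, t_half = 5, noise_sd = 0, seed = seed),
          file.path(data_dir, "frap.csv"), row.names = FALSE)

## Tracks: the three transport regimes and a 30/70 mobile/immobile mix
for (mode in c("directed", "brownian", "stationary")) {
  n <- if (mode == "brownian") 100 else 20
  write_tracks(simulate_tracks(mode, n_tracks = n, speed = 1,
                               D_coef = 0.05, loc_noise_sd = 0.02,
                               seed = seed),
               file.path(data_dir, paste0("tracks_", mode, ".csv")))
}
mix <- simulate_track_mixture(100, mobile_fraction = 0.3,
                              loc_noise_sd = 0.05, seed = seed)
write_tracks(mix$tracks, file.path(data_dir, "tracks_mixture.csv"))
write.csv(mix$truth_labels, file.path(data_dir, "tracks_mixture_truth.csv"),
          row.names = FALSE)

## Colocalization: fully colocalized and independent channel pairs
for (cf in c(1, 0)) {
  ci <- simulate_coloc_images(coloc_fraction = cf, noise_sd = 2,
                              seed = seed + cf)
  tag <- if (cf == 1) "coloc" else "indep"
  write_image_stack(ci$ch1, file.path(data_dir, paste0(tag, "_ch1.tif")))
  write_image_stack(ci$ch2, file.path(data_dir, paste0(tag, "_ch2.tif")))
}

## FRET: smooth index gradient along the neurite, in [0.05, 0.6]
idx <- matrix(rep(seq(0.05, 0.6, length.out = 250), 20), 250, 20)
stk <- simulate_fret_stacks(idx, donor_bleed_d = 0.5, crossex_a = 0.2,
                            background = 5, noise_sd = 0, seed = seed)
write_image_stack(stk$I_DD, file.path(data_dir, "fret_dd.tif"))
write_image_stack(stk$I_DA, file.path(data_dir, "fret_da.tif"))
write_image_stack(stk$I_AA, file.path(data_dir, "fret_aa.tif"))
write_image_stack(idx, file.path(data_dir, "fret_truth_index.tif"))

## Calcium: 20 s baseline, 2 s stimulus bump, 10 Hz sampling
set.seed(seed)
n_base <- 200
resp <- c(rep(0, n_base), 100 * exp(-(0:399) / 80))
trace <- 50 + resp + rnorm(n_base + 400, 0, 2)
write.csv(data.frame(frame = seq_along(trace), intensity = trace),
          file.path(data_dir, "calcium.csv"), row.names = FALSE)

jsonlite::write_json(
  list(seed = seed, E_pa = 2, eta_pa_s = 0.1, gamma_pn_um = 1,
       theta0 = 0.5, diameter_um = 5, frap_mf = 0.6, frap_t_half_s = 5,
       brownian_D_um2_s = 0.05, mobile_fraction = 0.3,
       fret_index_range = c(0.05, 0.6)),
  file.path(data_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
cat("Wrote synthetic inputs to", data_dir, "\n")
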