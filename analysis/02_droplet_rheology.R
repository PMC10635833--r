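#!/usr/bin/env Rscript
# Stage 2: dual-trap microrheology of the synthetic droplet. Runs the
# full chain (step relaxation -> surface tension; lock-in -> coupled and
# droplet stiffness -> shear modulus -> Maxwell fit) through the
# config-driven pipeline and scores recovery against the echoed truth.

suppressPackageStartupMessages(library(condensateR))
truth <- jsonlite::read_json("scratch/data/truth.json")
dir.create("results", showWarnings = FALSE)

cfg_path <- "scratch/rheology_config.yaml"
yaml::write_yaml(list(
  seed = truth$seed, outdir = "results/rheology",
  stages = "rheology",
  rheology = list(sweep_path = "scratch/data/sweep.csv",
                  steps_path = "scratch/data/steps.csv",
                  k1 = 50, k2 = 50, theta0 = truth$theta0,
                  droplet_diameter_um = truth$diameter_um)
), cfg_path)

res <- run_pipeline(cfg_path)
mx <- res$rheology$maxwell
te <- res$rheology$tension

cat(sprintf("Surface tension: gamma = %.4f pN/um (truth %.1f)\n",
            te$gamma, truth$gamma_pn_um))
cat(sprintf("Maxwell fit:     E = %.4f Pa (truth %.1f), eta = %.4f Pa s (truth %.1f)\n",
            mx$E, truth$E_pa, mx$eta, truth$eta_pa_s))
f_c <- truth$E_pa / (2 * pi * truth$eta_pa_s)
cat(sprintf("Crossover:       omega_c = %.4f Hz (analytic %.4f), tau = %.3f s\n",
            mx$omega_c, f_c, mx$tau_char))
cat(sprintf("Recovery errors: E %.2e, eta %.2e, omega_c %.2e (relative)\n",
            abs(mx$E - truth$E_pa) / truth$E_pa,
            abs(mx$eta - truth$eta_pa_s) / truth$eta_pa_s,
            abs(mx$omega_c - f_c) / f_c))

write_report(res, outdir = "results/figures")
cat("Spectrum + Lissajous figures in results/figures/\n")

# robustness: the same droplet under 5% multiplicative force noise
mat <- material_truth(truth$E_pa, truth$eta_pa_s, truth$gamma_pn_um,
                      truth$theta0, truth$diameter_um)
wcs <- vapply(1:20, function(i) {
  trn <- trap_truth(k1 = 50, k2 = 50, noise_frac_force = 0.05,
                    seed = truth$seed + i)
  swn <- simulate_dual_trap_sweep(mat, trn)
  droplet_rheology(swn, 50, 50, truth$gamma_pn_um,
                   truth$theta0)$maxwell$omega_c
}, numeric(1))
cat(sprintf("Noise robustness: median omega_c over 20 droplets = %.3f Hz (%.1f%% off truth)\n",
            median(wcs), 100 * abs(median(wcs) - f_c) / f_c))
write.csv(data.frame(replicate = 1:20, omega_c_hz = wcs),
          "results/rheology/omega_c_noise_replicates.csv", row.names = FALSE)
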