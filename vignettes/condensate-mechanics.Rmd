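---
title: "Measuring the material state of biomolecular condensates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the material state of biomolecular condensates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensateR)
```

Biomolecular condensates formed by liquid–liquid phase separation can
mature from viscous droplets into elastic solids. `condensateR`
implements the quantitative assays that establish such a rigidity
transition — droplet microrheology, FRAP, particle-track statistics,
FRET tension indexing and colocalization — each paired with a
synthetic-data generator, so every stage can be validated by recovering
known parameters. This vignette is the package's account of the
underlying models, the tunable parameters, and the design decisions a
maintainer should know about.

## Dual-trap droplet microrheology

### The measurement chain

A droplet of diameter $D$ (radius $R = D/2$) is held between two
optically trapped beads of stiffness $k_1, k_2$ (pN/µm). Two in-series
measurements are made on the same droplet:

1. **Step relaxations.** Trap 1 applies square steps of amplitude $A$
   (100 nm by default, 0.2 Hz). Each force trace relaxes as
   $F(t) = F_0 + (F_p - F_0)e^{-t/\tau}$; segments are aligned to their
   onsets and averaged before a nonlinear least-squares fit
   (`fit_step_relaxation()`). From the resting forces,
   $\Delta x_0 = A + F_0^{(1)}/k_1 - F_0^{(2)}/k_2$,
   $\chi_0 = (F_0^{(1)} - F_0^{(2)})/(2\Delta x_0)$, and the surface
   tension $\gamma \approx (\chi_0/\pi)(-\ln\theta_0 + 0.68)$, where
   $\theta_0 \in (0,1)$ is the normalized bead–droplet contact
   parameter. $\theta_0$ is a config input: its independent measurement
   requires a contact-geometry analysis that this package does not
   reimplement.

2. **Sinusoidal sweep.** Trap 1 drives the droplet at octave-spaced
   frequencies $f = 0.5, 1, \dots, 64$ Hz (the conventional reading of
   a rheology sweep "0.5, 1, …, 64"; the list is configurable). A
   quadrature lock-in (`lockin_spectrum()`) extracts complex force and
   extension amplitudes per frequency; then
   $\chi^*_{sys} = (\tilde F_1 - \tilde F_2)/(2\tilde x_{sys})$, the
   trap-and-drag correction gives the droplet stiffness $\chi^*(\omega)$,
   and
   $G^*(\omega) = [\chi^* - (1.25 + 4.36\theta_0^2)\gamma]/[R\,P(\theta_0)]$
   with $P$ a fifth-order polynomial in $\theta_0$. With $\chi$, $\gamma$
   in pN/µm and $R$ in µm, $G^*$ comes out in Pa.

**Angular-frequency convention.** Drive frequencies are stated in Hz
throughout the interface. Inside the coupling correction, products
$\xi\omega$ use $\omega = 2\pi f$ rad/s, so that $\xi\omega$ carries
stiffness units ($\xi = 3\pi\eta_{med}D$ is in pN·s/µm). The crossover
frequency is reported in Hz as $\omega_c = E/(2\pi\eta)$. This is the
only convention under which both expressions are dimensionally
consistent.

**Lock-in as exact-frequency projection.** The per-segment amplitudes
are obtained by least-squares projection onto
$\{\sin\omega t, \cos\omega t, 1\}$ at the exact drive frequency. For an
integer number of cycles this equals the single-bin DFT; for non-integer
cycle counts (which arise when the sampling rate is not a multiple of
the drive frequency) it remains exact for a pure tone, avoiding
spectral-leakage bias. Segments must still contain at least one full
cycle, and the generator refuses sampling rates below 20× the highest
drive frequency.

### The Maxwell fit

Storage and loss moduli of a Maxwell element (spring $E$ in series with
dashpot $\eta$, relaxation time $\tau_r = \eta/E$) are
$G' = E(\omega\tau_r)^2/(1+(\omega\tau_r)^2)$ and
$G'' = E\,\omega\tau_r/(1+(\omega\tau_r)^2)$. `fit_maxwell()` fits both
curves jointly on **log residuals**, because the moduli span decades
across the sweep and absolute weighting would let the high-frequency
plateau dominate. Parameters are fitted as $(\log E, \log\eta)$ to
enforce positivity; starting values come from the high-frequency
$G'$ plateau and the frequency where $G'$ and $G''$ are closest. The
95% CI of $\omega_c$ is propagated to first order from the
log-parameter covariance ($\mathrm{var}\,\log\omega_c =
\Sigma_{11} + \Sigma_{22} - 2\Sigma_{12}$); a crossover outside the
measured band is reported with an `extrapolated` flag rather than
suppressed.

### The synthetic sweep generator

`simulate_dual_trap_sweep()` is constructed as the **exact algebraic
inverse of the analysis chain**: the Maxwell modulus is converted to
$\chi^*$ (inverse of the shear-modulus step), then to $\chi^*_{sys}$
(inverse of the coupling correction), and forces are synthesized as
$\tilde F_1 = +\chi^*_{sys}\tilde x_{sys}$,
$\tilde F_2 = -\chi^*_{sys}\tilde x_{sys}$. The antisymmetric split is
a free choice — the analysis uses only $\tilde F_1 - \tilde F_2$, so
the split is unobservable. This construction deliberately trades
physical realism (no Langevin dynamics of the bead–droplet circuit,
no thermal force spectrum) for a machine-precision round-trip oracle:
at zero noise the full chain recovers $(E, \eta, \gamma)$ to better
than $10^{-6}$ relative, so any regression in the analysis code is
caught exactly. Where the mechanical circuit justifying the coupling
correction places the drag is taken from the published two-trap
framework and not re-derived here. Noise is additive and/or
multiplicative Gaussian on the force channels, from one seeded
generator per call.

Defaults: 5 kHz sampling, 10 drive cycles per frequency (integer cycle
counts keep the lock-in leakage-free), 100 nm drive amplitude,
$k_1 = k_2 = 50$ pN/µm, droplet $D = 5$ µm (the typical selected
droplet size), medium viscosity 1 mPa·s. The reference material used
throughout the tests — $E = 2$ Pa, $\eta = 0.1$ Pa·s,
$\gamma = 1$ pN/µm, $\theta_0 = 0.5$ — places the analytic crossover at
$3.1831$ Hz, mid-band in the sweep, which is the regime where the fit
is best conditioned.

**Stiff-trap behaviour.** With $\xi = 0$ the relative difference
between $\chi^*$ and $\chi^*_{sys}$ is exactly
$|\chi|(k_1+k_2)/(k_1k_2)$ to first order — about 2% when both traps
are 100× stiffer than the droplet and below 0.5% beyond ~400×. The
tests pin both numbers; treating the coupled stiffness as the droplet
stiffness is only safe for very stiff traps.

## FRAP

Raw ROI series (bleached region, whole condensate, background, and
optionally an unbleached reference condensate) are double-normalized,

$$I_{dn}(t) = \frac{\overline{(T - bg)}_{pre}}{T(t) - bg}\cdot
             \frac{B(t) - bg}{\overline{(B - bg)}_{pre}},$$

then full-scale normalized so the first post-bleach point is 0 and the
pre-bleach level 1, which removes curve-to-curve differences in
starting intensity and bleach depth. When a sub-region of a condensate
is bleached, the whole condensate dims and cannot serve as its own
acquisition-bleaching reference; setting `bleach_rate_correction = TRUE`
substitutes the reference ROI. Recovery is fitted as
$I(t) = M_f(1 - e^{-\tau t})$ in **real time units** (the post-bleach
schedule is deliberately uneven: 10 fast frames every 0.371 s, then 10
slow frames every 20 s), with $t_{1/2} = \ln 2/\tau$ and the Soumpasis
diffusion coefficient $D = 0.224\,r^2/t_{1/2}$ for bleach-spot radius
$r$. Because $t_{1/2}$ depends on the user-chosen spot size, only $D$
is comparable across datasets; the package records $r$ per curve and
`soumpasis_diffusion()` refuses $r \le 0$. Bleach-phase frames are
excluded and the time origin sits at the first post-bleach frame
(standard practice; the normalization scheme does not define it).
Curves may be averaged after normalization when they share a schedule,
with per-curve fits reported alongside.

The generator applies a single multiplicative exponential
(`acq_bleach_rate`, default 0.002 s⁻¹) to all signal ROIs so the
renormalization step has something to correct, and encodes the target
recovery exactly before noise; `bleach_depth = 0` is refused because
full-scale normalization would divide by zero. Mf confidence intervals
are clipped to $[0,1]$ for reporting, with the raw interval retained.

## Particle tracks and transport regimes

`mean_squared_displacement()` implements the combined time-and-ensemble
average: per track over all overlapping pairs at each lag, then across
tracks weighted by pair counts, with lags capped at a quarter of the
track length (long-lag estimates average too few pairs to be stable).
Power-law exponents come from OLS on $\log \mathrm{MSD}$ vs
$\log\tau$: ballistic motion gives 2, free diffusion 1 (prefactor
$4D$ in 2-D), confinement ~0.

**Mobility classification** operationalizes what is visually evident in
kymographs: a track is mobile if its net end-to-end displacement
reaches 2 µm or its drift speed reaches 0.2 µm/s. Drift speed is net
displacement over duration, *not* path length over duration — at video
frame rates, localization jitter of 0.05 µm per frame would give a
stationary punctum an apparent path-length speed near 1 µm/s and
misclassify everything. Both thresholds are config-exposed; raising
them can only demote tracks from mobile to immobile (monotonicity is
tested). Per-distance-bin fractions and the mobile/immobile ratio $r$
are reported, with an explicit infinite-ratio flag when a bin has no
immobile tracks.

Interpunctum intervals use greedy local-maximum peak finding (strongest
peaks first, minimum separation enforced) on background-subtracted
intensity profiles; both the median and the mean interval are reported
because summaries of skewed spacing distributions differ. Puncta
morphology uses connected components of a thresholded mask
(`EBImage::bwlabel`); the perimeter is measured as the length of the
8-connected boundary contour (Euclidean steps between successive
contour pixels) rather than a boundary-pixel count, which would bias
roundness $4\pi A/P^2$ above 1 for disks. Machine-learning
segmentation is out of scope; thresholding is plumbing here.

## FRET index and load correlation

Three-cube FRET images (donor excitation/donor emission $I_{DD}$,
donor excitation/acceptor emission $I_{DA}$, acceptor
excitation/acceptor emission $I_{AA}$) are linearly unmixed with two
factors measured from single-fluorophore controls: donor bleedthrough
$d$ and acceptor cross-excitation $a$ (either may be 0). The corrected
FRET signal is $cF = I_{DA} - d\,I_{DD} - a\,I_{AA}$ (all
background-subtracted) and the index $cF/(I_{DD} + cF)$, clipped to
$[0,1]$ with the clipped fraction reported and non-positive
denominators excluded and counted. The index is evaluated inside a
mask on the acceptor channel (Otsu by default, fixed threshold
optional) to exclude autofluorescence. In a tension-sensor module,
higher tension separates the fluorophores, so the index *decreases*
with load. `estimate_bleedthrough()` uses the median of pixelwise
ratios on bright pixels — exact on clean controls and robust to
outliers.

For load series, pressure is converted to cuticle displacement by
linear interpolation in a device-specific calibration table (always a
config file, never hard-coded; a synthetic example table ships in
`inst/extdata/`). The correlation between mean index and displacement
is reported two ways: the ratio statistic $t = \rho/r_\omega$ with
$r_\omega$ the half-width of the 95% CI of $\rho$ — implemented
literally as specified even though its sampling distribution is
non-standard — and, alongside, the usual Pearson $t$-test, so the two
can be compared. Reversibility compares resting indices before and
after loading within a stated tolerance.

## Colocalization and its permutation null

Pearson correlation over masked pixels, plus a scramble null: channel 1
is chopped into blocks **along the neurite axis** (1-D blocks of a
straightened neurite, 5 µm by default — 25 px at 0.2 µm/px) and the
blocks are permuted; the correlation with the intact channel 2 is
recomputed per permutation and
$p = (1 + \#\{|\rho_{null}| \ge |\rho_{obs}|\})/(n_{perm}+1)$.
Block-wise scrambling preserves the punctate local structure, so the
null asks "would random punctum placement produce this overlap?", not
"would white noise?". Scrambling 2-D patches was the alternative; 1-D
blocks match the straightened-neurite geometry of the input. Each
permutation preserves the channel-1 histogram exactly (asserted in
tests), and under generated channel independence the rejection rate at
$\alpha = 0.05$ is calibrated to $[0.03, 0.07]$ over 1000 seeded runs.
Fewer than 4 blocks is refused as too coarse a null.

## Calcium traces

$\Delta F/F_0$ with $F_0$ the mean of the first `n_baseline` frames
(default 100, i.e. 10 s at 10 fps) after a centered moving-average
filter whose edge frames use shrinking windows; window 1 is the
identity.

## Orchestration and reproducibility

`load_config()` reads YAML/JSON, fills defaults, and rejects unknown
keys by name (so a typo like `thetaO` fails loudly instead of silently
using a default). `run_pipeline()` executes stages in dependency order,
writes tidy CSV/JSON outputs, a config echo, and a run log with package
version, config hash and seed; identical config + seed gives
byte-identical outputs (hash-compared in tests). All interfaces are
SI-anchored — seconds, µm, pN, Pa — and column names carry units,
because unit slips between nm/µm and Hz/rad·s⁻¹ are the main practical
risk in this chain. Force sweeps travel as delimited tables with a JSON
metadata sidecar; image stacks as 32-bit TIFF with a per-stack scale
sidecar (TIFF samples live in $[0,1]$). An HDF5 container would be a
natural alternative for sweeps; the delimited format was chosen so
fixtures stay plain text.

## Problem sizes, tolerances and degenerate inputs

The test and acceptance workloads use one droplet sweep of ~200k
samples (8 frequencies × 10 cycles at 5 kHz), 20 noisy sweep
replicates, 100 step-relaxation replicates at 1 kHz, 50 FRAP
replicates, 100-track ensembles, 250×20 px images, and 1000 runs of
the permutation-null calibration at 99 permutations each — sizes chosen
so the full suite completes in a few minutes while Monte-Carlo medians
are stable. Degenerate inputs are flagged, not guessed at: constant
step traces (τ unidentifiable), flat FRAP curves, zero-variance
channels, zero drive amplitudes, non-physical resting extensions and
out-of-range contact parameters all refuse or flag explicitly.

## What the synthetic tests do and do not show

The generators emulate the *structure* of the real data — the coupled
trap equations, the normalization pathways, punctate image statistics,
uneven FRAP schedules — with additive/multiplicative Gaussian noise.
They do not emulate thermal bead dynamics, detector shot noise,
photobleaching nonlinearity, drift, or segmentation ambiguity in dense
puncta fields. Passing the recovery tests therefore certifies that the
analysis chain is a correct inverse of its stated forward model and is
numerically robust at realistic noise levels; it does not certify
instrument calibration or biological interpretation. The printed
experimental values of the original study (specific crossover
frequencies per condensate composition, in-vivo FRET–load correlations,
behavioural scores) derive from recordings that are not publicly
deposited and are not reproduction targets here.
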