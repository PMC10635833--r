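# ---- FRET index -------------------------------------------------------------

#' Estimate bleedthrough factors from single-fluorophore controls
#'
#' The sensitized-emission channel is contaminated by donor bleedthrough
#' (`d`, seen with donor-only samples) and acceptor cross-excitation
#' (`a`, seen with acceptor-only samples). Each factor is the robust
#' slope (median of pixelwise ratios) of the FRET channel against the
#' corresponding direct channel on background-corrected bright pixels.
#'
#' @param I_DA_donor_only,I_DD_donor_only FRET and donor channels of a
#'   donor-only sample (matrices, background-corrected).
#' @param I_DA_acceptor_only,I_AA_acceptor_only FRET and acceptor
#'   channels of an acceptor-only sample.
#' @param min_signal pixels with direct-channel signal above this level
#'   enter the slope estimate.
#' @param min_pixels required number of such pixels.
#' @return list with factors `d` and `a` and the pixel counts used.
#' @export
estimate_bleedthrough <- function(I_DA_donor_only, I_DD_donor_only,
                                  I_DA_acceptor_only, I_AA_acceptor_only,
                                  min_signal = 1, min_pixels = 100) {
  robust_slope <- function(y, x) {
    sel <- x > min_signal
    if (sum(sel) < min_pixels) {
      stop("fewer than ", min_pixels, " pixels above background in the ",
           "single-fluorophore control")
    }
    stats::median(y[sel] / x[sel])
  }
  list(
    d = robust_slope(I_DA_donor_only, I_DD_donor_only),
    a = robust_slope(I_DA_acceptor_only, I_AA_acceptor_only),
    n_donor_px = sum(I_DD_donor_only > min_signal),
    n_acceptor_px = sum(I_AA_acceptor_only > min_signal)
  )
}

#' Pixelwise FRET index by linear unmixing
#'
#' The corrected FRET signal is
#' `cF = (I_DA - bg) - d (I_DD - bg) - a (I_AA - bg)` and the index is
#' `cF / ((I_DD - bg) + cF)`, clipped to `[0, 1]` (the clipped fraction
#' is reported). Pixels whose denominator is non-positive are excluded
#' and counted. The index is evaluated inside a mask derived from the
#' acceptor channel (Otsu threshold by default, or a fixed threshold)
#' to exclude background and autofluorescence.
#'
#' @param I_DD,I_DA,I_AA donor, sensitized-emission and acceptor images
#'   (matrices of equal shape).
#' @param d,a bleedthrough factors (>= 0), see [estimate_bleedthrough()].
#' @param background per-channel background, length 3 (DD, DA, AA) or
#'   scalar.
#' @param mask optional logical matrix; when NULL a threshold on the
#'   background-corrected acceptor channel is used.
#' @param mask_threshold `"otsu"` or a numeric threshold.
#' @return list of class `fret_set` with `index_map` (NA outside mask),
#'   `mean_index`, `mask`, `n_excluded`, `clip_fraction`, `d`, `a`.
#' @export
fret_index_map <- function(I_DD, I_DA, I_AA, d, a, background = 0,
                           mask = NULL, mask_threshold = "otsu") {
  stopifnot(is.matrix(I_DD), all(dim(I_DD) == dim(I_DA)),
            all(dim(I_DD) == dim(I_AA)))
  if (d < 0 || a < 0) stop("bleedthrough factors must be non-negative")
  bg <- rep(background, length.out = 3)
  dd <- I_DD - bg[1]; da <- I_DA - bg[2]; aa <- I_AA - bg[3]

  if (is.null(mask)) {
    thr <- if (identical(mask_threshold, "otsu")) {
      rng <- range(aa)
      if (diff(rng) <= 0) stop("acceptor channel is constant; cannot mask")
      EBImage::otsu(EBImage::Image((aa - rng[1]) / diff(rng))) *
        diff(rng) + rng[1]
    } else mask_threshold
    mask <- aa > thr
  }
  stopifnot(is.logical(mask), all(dim(mask) == dim(I_DD)))

  cF <- da - d * dd - a * aa
  denom <- dd + cF
  valid <- mask & denom > 0
  n_excluded <- sum(mask & denom <= 0)
  idx <- cF / denom
  clip_fraction <- sum(valid & (idx < 0 | idx > 1)) / max(sum(valid), 1)
  idx <- pmin(pmax(idx, 0), 1)
  idx[!valid] <- NA_real_
  out <- list(index_map = idx, mean_index = mean(idx[valid]),
              mask = mask, n_excluded = n_excluded,
              clip_fraction = clip_fraction, d = d, a = a)
  class(out) <- "fret_set"
  out
}

#' Correlate FRET index with mechanical load
#'
#' Pearson correlation of the mean FRET index per load step against the
#' cuticle displacement, reporting both the ratio statistic
#' `t = rho / r_omega` (with `r_omega` the half-width of the 95 percent
#' CI of `rho`) and the standard two-sided Pearson test. In a tension
#' sensor, increasing load should lower the index, so a strongly
#' negative `rho` indicates load transmission; reversibility compares
#' the resting index before and after loading.
#'
#' @param displacement_um cuticle displacement per load step (um); see
#'   [pressure_to_displacement()].
#' @param fret_index mean FRET index per step.
#' @param resting_before,resting_after optional resting indices around
#'   the load series.
#' @param reversibility_tol absolute tolerance on the resting-index
#'   difference.
#' @return list with `rho`, `rho_ci`, `t_ratio` (rho / CI half-width),
#'   `t_standard`, `p_value` (standard test), `reversible` (logical or
#'   NA) and `n`.
#' @export
fret_vs_load <- function(displacement_um, fret_index,
                         resting_before = NULL, resting_after = NULL,
                         reversibility_tol = 0.05) {
  stopifnot(length(displacement_um) == length(fret_index))
  n <- length(fret_index)
  if (n < 3) stop("need >= 3 load steps")
  if (stats::sd(displacement_um) == 0 || stats::sd(fret_index) == 0) {
    stop("constant displacement or FRET index; correlation undefined")
  }
  ct <- stats::cor.test(displacement_um, fret_index)
  rho <- unname(ct$estimate)
  ci <- ct$conf.int
  r_omega <- diff(ci) / 2
  reversible <- if (!is.null(resting_before) && !is.null(resting_after)) {
    abs(resting_after - resting_before) <= reversibility_tol
  } else NA
  list(
    rho = rho, rho_ci = ci,
    t_ratio = rho / r_omega,
    t_standard = unname(ct$statistic),
    p_value = ct$p.value,
    reversible = reversible, n = n
  )
}

#' Convert applied pressure to cuticle displacement
#'
#' Linear interpolation in a calibration table (pressure_kPa,
#' displacement_um) supplied as a config file; the table is device- and
#' PDMS-mixture-specific and is never hard-coded.
#'
#' @param pressure_kPa pressures to convert.
#' @param table data.frame with `pressure_kPa`, `displacement_um`,
#'   monotone in pressure.
#' @return displacement, um.
#' @export
pressure_to_displacement <- function(pressure_kPa, table) {
  stopifnot(all(c("pressure_kPa", "displacement_um") %in% names(table)))
  if (is.unsorted(table$pressure_kPa, strictly = TRUE)) {
    stop("calibration table must be strictly increasing in pressure")
  }
  if (is.unsorted(table$displacement_um)) {
    stop("calibration displacement must be monotone in pressure")
  }
  stats::approx(table$pressure_kPa, table$displacement_um,
                xout = pressure_kPa, rule = 2)$y
}

# ---- colocalization ---------------------------------------------------------

#' Pearson colocalization of two channels
#'
#' Standard Pearson correlation of pixel intensities over a mask, with
#' the parametric two-sided p-value.
#'
#' @param ch1,ch2 matrices of equal shape.
#' @param mask logical matrix (default: all pixels).
#' @return list with `rho`, `p_value`, `n_pixels`.
#' @export
pearson_colocalization <- function(ch1, ch2, mask = NULL) {
  stopifnot(is.matrix(ch1), all(dim(ch1) == dim(ch2)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ch1), ncol(ch1))
  stopifnot(all(dim(mask) == dim(ch1)), sum(mask) >= 3)
  x <- ch1[mask]; y <- ch2[mask]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance channel inside the mask; correlation undefined")
  }
  ct <- stats::cor.test(x, y)
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_pixels = length(x))
}

#' Block-scramble permutation null for colocalization
#'
#' Chops channel 1 into blocks along the neurite (row) axis, permutes
#' the blocks (seeded), and recomputes the Pearson correlation with the
#' intact channel 2 for each permutation. Block-wise (rather than
#' pixelwise) scrambling preserves the punctate local structure so the
#' null reflects random punctum placement, not white noise. The
#' empirical p-value is `(1 + #{|rho_null| >= |rho_obs|}) / (n_perm + 1)`.
#'
#' @param ch1,ch2 matrices; rows index position along the neurite.
#' @param mask logical matrix or NULL.
#' @param block_length block height in pixels along the neurite axis; a
#'   remainder shorter than a block is kept as its own block.
#' @param n_perm number of permutations (>= 1; >= 100 recommended).
#' @param seed integer seed.
#' @return list of class `coloc_result` with `rho_obs`, `null_rho`
#'   (length `n_perm`), `p_empirical`, `p_parametric`, `block_length`,
#'   `n_blocks`, `n_perm`, `seed`.
#' @export
scramble_null <- function(ch1, ch2, mask = NULL, block_length = 25,
                          n_perm = 199, seed = 1L) {
  stopifnot(is.matrix(ch1), all(dim(ch1) == dim(ch2)))
  if (n_perm < 1) stop("n_perm must be >= 1")
  n_rows <- nrow(ch1)
  starts <- seq(1, n_rows, by = block_length)
  blocks <- lapply(starts, function(s) s:min(s + block_length - 1, n_rows))
  if (length(blocks) < 4) {
    stop("fewer than 4 blocks; scramble null too coarse ",
         "(reduce block_length)")
  }
  obs <- pearson_colocalization(ch1, ch2, mask)
  set.seed(seed)
  null_rho <- vapply(seq_len(n_perm), function(i) {
    perm_rows <- unlist(blocks[sample(length(blocks))])
    pearson_colocalization(ch1[perm_rows, , drop = FALSE], ch2, mask)$rho
  }, numeric(1))
  out <- list(
    rho_obs = obs$rho,
    null_rho = null_rho,
    p_empirical = (1 + sum(abs(null_rho) >= abs(obs$rho))) / (n_perm + 1),
    p_parametric = obs$p_value,
    block_length = block_length, n_blocks = length(blocks),
    n_perm = n_perm, seed = seed
  )
  class(out) <- "coloc_result"
  out
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization: rho = %.3f, empirical p = %.4g (%d block permutations, %d blocks)\n",
              x$rho_obs, x$p_empirical, x$n_perm, x$n_blocks))
  invisible(x)
}

# ---- calcium ----------------------------------------------------------------

#' Baseline-normalized calcium trace
#'
#' Applies a centered moving-average filter, then normalizes to the mean
#' of the first `n_baseline` pre-stimulation frames:
#' `(F - F0) / F0`.
#'
#' @param trace fluorescence intensity per frame, a.u.
#' @param n_baseline number of baseline frames (default 100).
#' @param smooth_window moving-average window (odd; 1 = no smoothing).
#' @return list of class `calcium_trace` with `dff` (normalized trace),
#'   `F0`, `smoothed` (the filtered raw trace), `n_baseline`,
#'   `smooth_window`.
#' @export
delta_f_over_f <- function(trace, n_baseline = 100, smooth_window = 1) {
  stopifnot(is.numeric(trace), smooth_window >= 1)
  if (length(trace) <= n_baseline) {
    stop("trace must be longer than the baseline window")
  }
  sm <- if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    out <- stats::filter(trace, k, sides = 2)
    # fill the filter's edge NAs with shrinking centered windows
    half <- (smooth_window - 1) %/% 2
    n <- length(trace)
    for (i in which(is.na(out))) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      out[i] <- mean(trace[lo:hi])
    }
    as.numeric(out)
  } else trace
  F0 <- mean(sm[seq_len(n_baseline)])
  if (F0 <= 0) stop("baseline F0 must be positive")
  out <- list(dff = (sm - F0) / F0, F0 = F0, smoothed = sm,
              n_baseline = n_baseline, smooth_window = smooth_window)
  class(out) <- "calcium_trace"
  out
}
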