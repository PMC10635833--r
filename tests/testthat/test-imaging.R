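test_that("bleedthrough factors come out of single-label controls", {
  dd <- matrix(runif(400, 10, 200), 20, 20)
  aa <- matrix(runif(400, 10, 200), 20, 20)
  bt <- estimate_bleedthrough(0.6 * dd, dd, 0 * aa, aa)
  expect_equal(bt$d, 0.6, tolerance = 1e-12)
  expect_equal(bt$a, 0, tolerance = 1e-12)

  # 5% noise: median-ratio slope within 2% of truth (median of 20 seeds)
  ds <- vapply(1:20, function(seed) {
    set.seed(seed)
    noisy_da <- 0.6 * dd * (1 + rnorm(400, 0, 0.05))
    estimate_bleedthrough(noisy_da, dd, 0 * aa, aa)$d
  }, numeric(1))
  expect_lt(abs(median(ds) - 0.6) / 0.6, 0.02)

  expect_error(estimate_bleedthrough(matrix(1, 5, 5), matrix(0, 5, 5),
                                     matrix(1, 5, 5), matrix(2, 5, 5)),
               "fewer than")
})

test_that("FRET index map matches hand-unmixed values and is gain-invariant", {
  dd <- matrix(100, 6, 6); aa <- matrix(50, 6, 6); da <- matrix(80, 6, 6)
  mask <- matrix(TRUE, 6, 6)
  fm <- fret_index_map(dd, da, aa, d = 0.5, a = 0.2, mask = mask)
  # cF = 80 - 50 - 10 = 20; index = 20 / 120
  expect_equal(fm$mean_index, 20 / 120, tolerance = 1e-12)
  expect_equal(fm$mean_index, 0.1667, tolerance = 1e-3)

  # common gain after background subtraction leaves the index unchanged
  fm_g <- fret_index_map(3 * dd, 3 * da, 3 * aa, 0.5, 0.2, mask = mask)
  expect_equal(fm_g$index_map, fm$index_map, tolerance = 1e-12)

  # with per-channel backgrounds subtracted first
  fm_bg <- fret_index_map(dd + 7, da + 7, aa + 7, 0.5, 0.2,
                          background = 7, mask = mask)
  expect_equal(fm_bg$index_map, fm$index_map, tolerance = 1e-12)

  expect_error(fret_index_map(dd, da, aa, d = -0.1, a = 0, mask = mask),
               "non-negative")
})

test_that("acceptor-channel Otsu mask separates puncta from background", {
  set.seed(1)
  aa <- matrix(5 + rnorm(250 * 20, 0, 0.5), 250, 20)
  ci <- simulate_coloc_images(n_puncta = 20, coloc_fraction = 1, seed = 2)
  aa_p <- aa + ci$ch1
  dd <- matrix(100, 250, 20)
  da <- 0.5 * dd + 0.1 * aa_p + 30  # uniform true FRET on top of bleed
  fm <- fret_index_map(dd, da, aa_p, d = 0.5, a = 0.1)
  expect_gt(sum(fm$mask), 0)
  expect_lt(sum(fm$mask), length(aa) / 2)
  expect_equal(fm$mean_index, 30 / 130, tolerance = 1e-6)
})

test_that("FRET-load correlation reports rho, ratio statistic and reversibility", {
  disp <- c(0, 2, 4, 6, 8)
  fret <- 0.5 - 0.03 * disp
  res <- fret_vs_load(disp, fret, resting_before = 0.5,
                      resting_after = 0.52)
  expect_equal(res$rho, -1, tolerance = 1e-9)
  expect_true(res$reversible)

  # ratio statistic uses the CI half-width
  set.seed(2)
  fret_n <- fret + rnorm(5, 0, 0.01)
  rn <- fret_vs_load(disp, fret_n)
  expect_equal(rn$t_ratio, rn$rho / (diff(rn$rho_ci) / 2), tolerance = 1e-12)

  expect_error(fret_vs_load(disp, rep(0.5, 5)), "constant")
  expect_error(fret_vs_load(disp[1:2], fret[1:2]), ">= 3")
})

test_that("load-free FRET rejects at the nominal rate (type-I calibration)", {
  rej <- vapply(1:500, function(seed) {
    set.seed(seed)
    disp <- c(0, 2, 4, 6, 8, 10)
    fret <- 0.5 + rnorm(6, 0, 0.05)
    fret_vs_load(disp, fret)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("pressure-displacement lookup interpolates the calibration table", {
  tab <- data.frame(pressure_kPa = c(0, 50, 100, 150),
                    displacement_um = c(0, 2, 5, 9))
  expect_equal(pressure_to_displacement(75, tab), 3.5)
  expect_equal(pressure_to_displacement(c(0, 150), tab), c(0, 9))
  bad <- tab; bad$displacement_um <- c(0, 5, 2, 9)
  expect_error(pressure_to_displacement(10, bad), "monotone")
})

test_that("Pearson colocalization matches exact linear relations", {
  ch1 <- matrix(runif(100), 10, 10)
  expect_equal(pearson_colocalization(ch1, 2 * ch1)$rho, 1, tolerance = 1e-12)

  m1 <- matrix(c(1, 2, 3, 4), 2, 2)
  m2 <- matrix(c(8, 6, 4, 2), 2, 2)
  expect_equal(pearson_colocalization(m1, m2)$rho, -1, tolerance = 1e-12)

  # independent images decorrelate at 256 x 64
  rhos <- vapply(1:50, function(seed) {
    set.seed(seed)
    a <- matrix(rnorm(256 * 64), 256, 64)
    b <- matrix(rnorm(256 * 64), 256, 64)
    pearson_colocalization(a, b)$rho
  }, numeric(1))
  expect_lt(median(abs(rhos)), 0.05)

  expect_error(pearson_colocalization(matrix(1, 5, 5), matrix(runif(25), 5, 5)),
               "zero-variance")
})

test_that("block scramble preserves the channel-1 histogram", {
  ci <- simulate_coloc_images(coloc_fraction = 0.5, noise_sd = 1, seed = 3)
  n_rows <- nrow(ci$ch1)
  blocks <- split(1:n_rows, ceiling(seq_len(n_rows) / 25))
  set.seed(1)
  for (i in 1:5) {
    perm_rows <- unlist(blocks[sample(length(blocks))])
    expect_equal(sort(ci$ch1[perm_rows, ]), sort(ci$ch1))
  }
})

test_that("scramble null separates colocalized from independent channels", {
  ci <- simulate_coloc_images(coloc_fraction = 1, seed = 5)
  sn <- scramble_null(ci$ch1, ci$ch2, n_perm = 199, seed = 6)
  expect_gt(sn$rho_obs, quantile(sn$null_rho, 0.95))
  expect_lt(sn$p_empirical, 0.05)

  # for a single independent pair the empirical p should at least not be
  # an extreme false positive (its full uniformity is checked over 1000
  # runs in the calibration test)
  ci0 <- simulate_coloc_images(coloc_fraction = 0, seed = 5)
  sn0 <- scramble_null(ci0$ch1, ci0$ch2, n_perm = 199, seed = 6)
  expect_gt(sn0$p_empirical, 0.01)

  expect_error(scramble_null(ci$ch1, ci$ch2, n_perm = 0), "n_perm")
  expect_error(scramble_null(ci$ch1, ci$ch2, block_length = 200), "4 blocks")
})

test_that("calcium normalization follows (F - F0) / F0 after smoothing", {
  trace <- c(rep(50, 120), rep(150, 30))
  ct <- delta_f_over_f(trace, n_baseline = 100, smooth_window = 1)
  expect_equal(ct$F0, 50)
  expect_equal(max(ct$dff), 2.0)
  expect_equal(mean(ct$dff[1:100]), 0, tolerance = 1e-12)

  # constant trace: dF/F identically zero
  expect_true(all(delta_f_over_f(rep(7, 150))$dff == 0))

  # window 1 is the identity on the normalized trace
  set.seed(1)
  tr2 <- 50 + rnorm(150)
  ct2 <- delta_f_over_f(tr2, 100, smooth_window = 1)
  expect_equal(ct2$dff, (tr2 - mean(tr2[1:100])) / mean(tr2[1:100]))

  expect_error(delta_f_over_f(rep(1, 50), n_baseline = 100), "longer")
  expect_error(delta_f_over_f(rep(-1, 150)), "positive")
})
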