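# render a 2-D Gaussian spot into an image matrix (in place helper)
add_spot <- function(img, cx, cy, sigma, amplitude) {
  r <- ceiling(4 * sigma)
  xs <- max(1, round(cx) - r):min(nrow(img), round(cx) + r)
  ys <- max(1, round(cy) - r):min(ncol(img), round(cy) + r)
  patch <- amplitude * exp(-(outer((xs - cx)^2, (ys - cy)^2, "+")) /
                             (2 * sigma^2))
  img[xs, ys] <- img[xs, ys] + patch
  img
}

#' Simulate three-cube FRET image stacks with a known index map
#'
#' Builds donor (`I_DD`), sensitized-emission (`I_DA`) and acceptor
#' (`I_AA`) images such that linear unmixing with the stated factors
#' recovers `true_index_map` exactly before noise: the corrected FRET
#' signal is `cF = index / (1 - index) * I_DD_corr` and
#' `I_DA = cF + d I_DD_corr + a I_AA_corr + background`.
#'
#' @param true_index_map matrix with values in `[0, 1)`.
#' @param donor_bleed_d donor bleedthrough factor (>= 0).
#' @param crossex_a acceptor cross-excitation factor (>= 0).
#' @param donor_signal,acceptor_signal signal amplitude of the donor and
#'   acceptor channels (scalar or matrix).
#' @param background added to all channels, a.u.
#' @param noise_sd additive Gaussian noise per channel, a.u.
#' @param seed integer seed.
#' @return list with matrices `I_DD`, `I_DA`, `I_AA`, the factors, the
#'   background and `truth` (the index map).
#' @export
simulate_fret_stacks <- function(true_index_map, donor_bleed_d = 0.5,
                                 crossex_a = 0.2, donor_signal = 100,
                                 acceptor_signal = 50, background = 0,
                                 noise_sd = 0, seed = 1L) {
  stopifnot(is.matrix(true_index_map))
  if (any(true_index_map < 0 | true_index_map >= 1)) {
    stop("true_index_map must lie in [0, 1)")
  }
  if (donor_bleed_d < 0 || crossex_a < 0) {
    stop("bleedthrough factors must be non-negative")
  }
  dd <- matrix(donor_signal, nrow(true_index_map), ncol(true_index_map))
  aa <- matrix(acceptor_signal, nrow(true_index_map), ncol(true_index_map))
  cF <- true_index_map / (1 - true_index_map) * dd
  da <- cF + donor_bleed_d * dd + crossex_a * aa
  set.seed(seed)
  noisy <- function(m) {
    if (noise_sd > 0) m + matrix(stats::rnorm(length(m), 0, noise_sd),
                                 nrow(m)) else m
  }
  list(
    I_DD = noisy(dd + background),
    I_DA = noisy(da + background),
    I_AA = noisy(aa + background),
    d = donor_bleed_d, a = crossex_a, background = background,
    truth = list(index_map = true_index_map, seed = seed)
  )
}

#' Simulate two punctate channels with controlled co-occurrence
#'
#' Places `n_puncta` Gaussian puncta at uniform positions in channel 1;
#' each channel-2 punctum shares its channel-1 position with probability
#' `coloc_fraction` and otherwise gets an independent uniform position.
#' Rows index position along the (straightened) neurite.
#'
#' @param n_puncta puncta per channel.
#' @param coloc_fraction probability in `[0, 1]` that a channel-2
#'   punctum sits on a channel-1 punctum.
#' @param psf_sigma_px Gaussian spot sigma, px.
#' @param image_shape `c(n_rows, n_cols)` (neurite axis first).
#' @param amplitude peak intensity per punctum.
#' @param noise_sd additive Gaussian noise, a.u.
#' @param seed integer seed.
#' @return list with matrices `ch1`, `ch2` and `truth` (positions,
#'   shared flags, seed).
#' @export
simulate_coloc_images <- function(n_puncta = 40, coloc_fraction = 0.5,
                                  psf_sigma_px = 2,
                                  image_shape = c(250, 20),
                                  amplitude = 100, noise_sd = 0,
                                  seed = 1L) {
  if (coloc_fraction < 0 || coloc_fraction > 1) {
    stop("coloc_fraction must lie in [0, 1]")
  }
  # each punctum occupies roughly a (4 sigma)^2 footprint; refuse images
  # that cannot hold the requested count without near-total overlap
  if (n_puncta * (4 * psf_sigma_px)^2 > 2 * prod(image_shape)) {
    stop("puncta denser than the image can hold")
  }
  set.seed(seed)
  nr <- image_shape[1]; nc <- image_shape[2]
  ch1 <- matrix(0, nr, nc); ch2 <- matrix(0, nr, nc)
  x1 <- stats::runif(n_puncta, 1, nr); y1 <- stats::runif(n_puncta, 1, nc)
  shared <- stats::runif(n_puncta) < coloc_fraction
  x2 <- ifelse(shared, x1, stats::runif(n_puncta, 1, nr))
  y2 <- ifelse(shared, y1, stats::runif(n_puncta, 1, nc))
  for (i in seq_len(n_puncta)) {
    ch1 <- add_spot(ch1, x1[i], y1[i], psf_sigma_px, amplitude)
    ch2 <- add_spot(ch2, x2[i], y2[i], psf_sigma_px, amplitude)
  }
  if (noise_sd > 0) {
    ch1 <- ch1 + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr)
    ch2 <- ch2 + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr)
  }
  list(ch1 = ch1, ch2 = ch2,
       truth = list(x1 = x1, y1 = y1, x2 = x2, y2 = y2, shared = shared,
                    coloc_fraction = coloc_fraction, seed = seed))
}
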