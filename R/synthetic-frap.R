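#' Default FRAP acquisition schedule
#'
#' Frame timing mirroring a standard confocal FRAP protocol: 5 pre-bleach
#' frames (every 0.371 s), 5 bleach frames (every 0.344 s), 10 fast
#' post-bleach frames (every 0.371 s) and 10 slow post-bleach frames
#' (every 20 s).
#'
#' @return data.frame with `t_s` and `phase`.
#' @export
frap_schedule <- function() {
  t_pre <- (0:4) * 0.371
  t_bleach <- max(t_pre) + (1:5) * 0.344
  t_post1 <- max(t_bleach) + (1:10) * 0.371
  t_post2 <- max(t_post1) + (1:10) * 20
  data.frame(
    t_s = c(t_pre, t_bleach, t_post1, t_post2),
    phase = rep(c("prebleach", "bleach", "postbleach1", "postbleach2"),
                c(5, 5, 10, 10))
  )
}

#' Simulate raw FRAP ROI intensity series with known kinetics
#'
#' Emits raw bleached-ROI, whole-condensate, background and unbleached
#' reference ROI traces such that the full-scale-normalized recovery
#' equals `Mf (1 - exp(-tau t))` with `tau = ln(2) / t_half` before
#' noise. A single-exponential acquisition-bleaching decay is applied
#' multiplicatively to all signal ROIs so the bleach-rate renormalization
#' step has something to correct.
#'
#' @param Mf mobile fraction in `[0, 1]`.
#' @param t_half recovery half-time, s.
#' @param schedule frame timing data.frame (`t_s`, `phase`); default
#'   [frap_schedule()].
#' @param noise_sd additive Gaussian noise on each raw ROI, a.u.
#' @param bleach_depth fraction of the bleached-ROI intensity removed by
#'   the bleach, in (0, 1]; 0 is refused (nothing to normalize).
#' @param acq_bleach_rate acquisition-bleaching rate, 1/s (all ROIs decay
#'   as `exp(-rate t)`).
#' @param seed integer seed.
#' @return data.frame with `t_s`, `phase`, `roi_bleached`, `roi_total`,
#'   `roi_background`, `roi_reference`; ground truth attached as
#'   attribute `truth`.
#' @export
simulate_frap <- function(Mf, t_half, schedule = frap_schedule(),
                          noise_sd = 0, bleach_depth = 0.8,
                          acq_bleach_rate = 0.002, seed = 1L) {
  if (Mf < 0 || Mf > 1) stop("Mf must lie in [0, 1]")
  if (t_half <= 0) stop("t_half must be positive")
  if (bleach_depth <= 0 || bleach_depth > 1) {
    stop("bleach_depth must lie in (0, 1]: a zero-depth bleach leaves ",
         "nothing to normalize")
  }
  tau <- log(2) / t_half
  bg <- 10
  S_pre <- 100    # pre-bleach bleached-ROI signal above background
  T_pre <- 400    # whole-condensate signal
  R_pre <- 150    # reference condensate signal

  ph <- schedule$phase
  t <- schedule$t_s
  t0 <- t[ph == "postbleach1"][1]
  decay <- exp(-acq_bleach_rate * t)

  # target double-normalized curve: I_dn = (1-depth) + depth*Mf*(1-e^-tau t')
  i_dn <- rep(1, nrow(schedule))
  post <- ph %in% c("postbleach1", "postbleach2")
  i_dn[post] <- (1 - bleach_depth) +
    bleach_depth * Mf * (1 - exp(-tau * (t[post] - t0)))
  # bleach frames ramp down linearly to the post-bleach start
  blch <- ph == "bleach"
  i_dn[blch] <- seq(1, 1 - bleach_depth, length.out = sum(blch) + 1)[-1]

  set.seed(seed)
  noise <- function(n) if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  n <- nrow(schedule)
  out <- data.frame(
    t_s = t, phase = ph,
    roi_bleached = bg + S_pre * decay * i_dn + noise(n),
    roi_total = bg + T_pre * decay + noise(n),
    roi_reference = bg + R_pre * decay + noise(n),
    roi_background = bg + noise(n)
  )
  attr(out, "truth") <- list(Mf = Mf, t_half = t_half, tau = tau,
                             bleach_depth = bleach_depth,
                             acq_bleach_rate = acq_bleach_rate, seed = seed)
  out
}
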