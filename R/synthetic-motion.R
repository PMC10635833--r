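#' Simulate 2-D particle tracks with known transport mode
#'
#' Three motion regimes covering the mobility dichotomy of condensate
#' transport: `directed` (constant speed along a random direction, with
#' optional stochastic reversals, MSD ~ tau^2), `brownian` (Gaussian
#' steps with MSD = 4 D tau) and `stationary` (pure localization noise,
#' MSD ~ 0). Localization noise is added to all modes.
#'
#' @param mode one of `"directed"`, `"brownian"`, `"stationary"`.
#' @param n_tracks number of tracks.
#' @param speed directed speed, um/s.
#' @param D_coef Brownian diffusion coefficient, um^2/s.
#' @param frame_dt frame interval, s.
#' @param n_frames frames per track (>= 10).
#' @param loc_noise_sd localization noise sd per coordinate, um.
#' @param reversal_prob per-frame probability of reversing the directed
#'   velocity.
#' @param seed integer seed.
#' @param bin optional distance-bin label stored with every track.
#' @return data.frame (`track_id`, `frame`, `t_s`, `x_um`, `y_um`
#'   [, `bin`]) with the generating parameters in attribute `truth`.
#' @export
simulate_tracks <- function(mode = c("directed", "brownian", "stationary"),
                            n_tracks = 10, speed = 1, D_coef = 0.05,
                            frame_dt = 0.1, n_frames = 100,
                            loc_noise_sd = 0.02, reversal_prob = 0,
                            seed = 1L, bin = NULL) {
  mode <- match.arg(mode)
  if (n_frames < 10) stop("n_frames must be >= 10")
  set.seed(seed)
  tracks <- lapply(seq_len(n_tracks), function(id) {
    t <- (seq_len(n_frames) - 1) * frame_dt
    if (mode == "directed") {
      phi <- stats::runif(1, 0, 2 * pi)
      sgn <- cumprod(c(1, ifelse(stats::runif(n_frames - 1) < reversal_prob,
                                 -1, 1)))
      dx <- c(0, sgn[-1] * speed * frame_dt * cos(phi))
      dy <- c(0, sgn[-1] * speed * frame_dt * sin(phi))
      x <- cumsum(dx); y <- cumsum(dy)
    } else if (mode == "brownian") {
      sd_step <- sqrt(2 * D_coef * frame_dt)
      x <- cumsum(c(0, stats::rnorm(n_frames - 1, 0, sd_step)))
      y <- cumsum(c(0, stats::rnorm(n_frames - 1, 0, sd_step)))
    } else {
      x <- rep(0, n_frames); y <- rep(0, n_frames)
    }
    if (loc_noise_sd > 0) {
      x <- x + stats::rnorm(n_frames, 0, loc_noise_sd)
      y <- y + stats::rnorm(n_frames, 0, loc_noise_sd)
    }
    out <- data.frame(track_id = id, frame = seq_len(n_frames), t_s = t,
                      x_um = x, y_um = y)
    if (!is.null(bin)) out$bin <- bin
    out
  })
  out <- do.call(rbind, tracks)
  attr(out, "truth") <- list(mode = mode, n_tracks = n_tracks, speed = speed,
                             D_coef = D_coef, frame_dt = frame_dt,
                             n_frames = n_frames,
                             loc_noise_sd = loc_noise_sd, seed = seed)
  out
}

#' Simulate a mobile/immobile track mixture with ground-truth labels
#'
#' Combines directed (mobile) and stationary (immobile) tracks in a
#' stated proportion, relabeling track ids, for benchmarking
#' [classify_mobility()].
#'
#' @param n_tracks total number of tracks.
#' @param mobile_fraction fraction of directed tracks.
#' @param speed directed speed, um/s.
#' @param loc_noise_sd localization noise, um.
#' @param frame_dt,n_frames acquisition parameters.
#' @param seed integer seed.
#' @param bin optional bin label.
#' @return list with `tracks` (data.frame) and `truth_labels`
#'   (data.frame `track_id`, `mobile`).
#' @export
simulate_track_mixture <- function(n_tracks = 100, mobile_fraction = 0.3,
                                   speed = 1, loc_noise_sd = 0.05,
                                   frame_dt = 0.1, n_frames = 100,
                                   seed = 1L, bin = NULL) {
  n_mob <- round(n_tracks * mobile_fraction)
  mob <- simulate_tracks("directed", n_tracks = n_mob, speed = speed,
                         frame_dt = frame_dt, n_frames = n_frames,
                         loc_noise_sd = loc_noise_sd, seed = seed, bin = bin)
  imm <- simulate_tracks("stationary", n_tracks = n_tracks - n_mob,
                         frame_dt = frame_dt, n_frames = n_frames,
                         loc_noise_sd = loc_noise_sd, seed = seed + 1L,
                         bin = bin)
  imm$track_id <- imm$track_id + n_mob
  tracks <- rbind(mob, imm)
  list(
    tracks = tracks,
    truth_labels = data.frame(track_id = seq_len(n_tracks),
                              mobile = seq_len(n_tracks) <= n_mob)
  )
}
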