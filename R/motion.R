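# ---- particle-track mobility statistics -------------------------------------

#' Time-and-ensemble-averaged mean squared displacement
#'
#' For each track, the time-averaged MSD over all overlapping pairs at
#' lag `tau`: `MSD(tau) = <(x(t) - x(t + tau))^2>`, then the ensemble
#' average across tracks at each lag. Lags are limited to a fraction of
#' the track length because long-lag estimates average few pairs.
#'
#' @param tracks data.frame with columns `track_id`, `frame`, `t_s`,
#'   `x_um`, `y_um`.
#' @param max_lag_fraction largest lag as a fraction of the shortest
#'   track's duration (default 1/4).
#' @return object of class `msd_curve`: data.frame with `lag_s`,
#'   `msd_um2` and `n_pairs`.
#' @export
mean_squared_displacement <- function(tracks, max_lag_fraction = 0.25) {
  need <- c("track_id", "frame", "t_s", "x_um", "y_um")
  stopifnot(is.data.frame(tracks), all(need %in% names(tracks)))
  if (nrow(tracks) == 0) stop("empty track table")
  split_tracks <- split(tracks, tracks$track_id)
  lens <- vapply(split_tracks, nrow, 1L)
  if (max(lens) < 10) stop("need at least one track with >= 10 frames")
  split_tracks <- split_tracks[lens >= 10]

  per_track <- lapply(split_tracks, function(tr) {
    tr <- tr[order(tr$frame), ]
    if (is.unsorted(tr$frame, strictly = TRUE)) {
      stop("frames must be strictly increasing within a track")
    }
    n <- nrow(tr)
    dt <- stats::median(diff(tr$t_s))
    max_lag <- max(1L, floor(n * max_lag_fraction))
    lags <- seq_len(max_lag)
    msd <- vapply(lags, function(k) {
      dx <- tr$x_um[(1 + k):n] - tr$x_um[1:(n - k)]
      dy <- tr$y_um[(1 + k):n] - tr$y_um[1:(n - k)]
      mean(dx^2 + dy^2)
    }, numeric(1))
    data.frame(lag_s = lags * dt, msd_um2 = msd, n_pairs = n - lags)
  })
  all <- do.call(rbind, per_track)
  # ensemble average on the common lag grid (tracks share frame interval)
  agg <- stats::aggregate(cbind(msd_w = msd_um2 * n_pairs, n_pairs) ~ lag_s,
                          data = all, FUN = sum)
  out <- data.frame(lag_s = agg$lag_s, msd_um2 = agg$msd_w / agg$n_pairs,
                    n_pairs = agg$n_pairs)
  out <- out[order(out$lag_s), ]
  rownames(out) <- NULL
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Power-law exponent of an MSD curve
#'
#' Ordinary least squares of `log(MSD)` on `log(lag)` within a lag
#' window: `MSD = prefactor * lag^n`. An exponent near 2 indicates
#' directed transport, near 1 free diffusion, near 0 confinement.
#'
#' @param msd an `msd_curve` (or data.frame with `lag_s`, `msd_um2`).
#' @param lag_window optional `c(min, max)` lag range (s) to fit within.
#' @return list with `exponent`, `exponent_ci` (95 percent), `prefactor`
#'   and `n_lags` used.
#' @export
fit_powerlaw <- function(msd, lag_window = NULL) {
  stopifnot(all(c("lag_s", "msd_um2") %in% names(msd)))
  d <- msd
  if (!is.null(lag_window)) {
    d <- d[d$lag_s >= lag_window[1] & d$lag_s <= lag_window[2], , drop = FALSE]
  }
  bad <- d$msd_um2 <= 0
  if (any(bad)) {
    warning("excluding ", sum(bad), " lags with non-positive MSD")
    d <- d[!bad, , drop = FALSE]
  }
  if (nrow(d) < 4) stop("need >= 4 positive MSD values in the fit window")
  fit <- stats::lm(log(msd_um2) ~ log(lag_s), data = d)
  co <- stats::coef(fit)
  # exact-law fixtures fit perfectly; the resulting summary warning is
  # expected, not a data problem
  ci <- tryCatch(suppressWarnings(stats::confint(fit)["log(lag_s)", ]),
                 error = function(e) c(NA, NA))
  list(exponent = unname(co[2]), exponent_ci = unname(ci),
       prefactor = exp(unname(co[1])), n_lags = nrow(d))
}

#' Classify tracks as mobile or immobile
#'
#' A track is called mobile when its net end-to-end displacement reaches
#' `min_net_displacement` or its mean drift speed (net displacement over
#' track duration, robust to localization jitter) reaches
#' `min_mean_speed`; otherwise immobile. Raising either threshold never
#' converts an immobile track to mobile. When a distance-bin column is
#' present, per-bin mobile/immobile fractions and their ratio
#' `r = mobile / immobile` are reported; a bin with no immobile tracks
#' gets `r = NA` with an `r_infinite` flag instead of a number.
#'
#' @param tracks data.frame as in [mean_squared_displacement()], with an
#'   optional `bin` column (e.g. distance to the cell body).
#' @param min_net_displacement um, default 2.
#' @param min_mean_speed um/s, default 0.2.
#' @return list with `labels` (data.frame `track_id`, `net_displacement`,
#'   `mean_speed`, `mobile`) and `by_bin` (data.frame of fractions and
#'   `r`, or NULL without bins).
#' @export
classify_mobility <- function(tracks, min_net_displacement = 2,
                              min_mean_speed = 0.2) {
  per <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    net <- sqrt((tr$x_um[nrow(tr)] - tr$x_um[1])^2 +
                  (tr$y_um[nrow(tr)] - tr$y_um[1])^2)
    # drift (net-over-duration) speed: path-length speed would be
    # dominated by localization jitter at video frame rates
    spd <- net / (tr$t_s[nrow(tr)] - tr$t_s[1])
    data.frame(track_id = tr$track_id[1], net_displacement = net,
               mean_speed = spd,
               bin = if ("bin" %in% names(tr)) tr$bin[1] else NA)
  })
  labels <- do.call(rbind, per)
  labels$mobile <- labels$net_displacement >= min_net_displacement |
    labels$mean_speed >= min_mean_speed
  by_bin <- NULL
  if (!all(is.na(labels$bin))) {
    by_bin <- do.call(rbind, lapply(split(labels, labels$bin), function(b) {
      n_mob <- sum(b$mobile); n_imm <- sum(!b$mobile)
      data.frame(
        bin = b$bin[1], n = nrow(b),
        frac_mobile = n_mob / nrow(b), frac_immobile = n_imm / nrow(b),
        r = if (n_imm > 0) n_mob / n_imm else NA_real_,
        r_infinite = n_imm == 0
      )
    }))
    rownames(by_bin) <- NULL
  }
  rownames(labels) <- NULL
  list(labels = labels[, c("track_id", "net_displacement", "mean_speed",
                           "bin", "mobile")],
       by_bin = by_bin)
}

#' Interpunctum intervals along a neurite
#'
#' Finds punctum positions either directly (`positions` given) or as
#' local maxima of a background-subtracted intensity profile above a
#' threshold, enforcing a minimum peak separation, then reports the
#' successive position differences.
#'
#' @param positions punctum positions, um (sorted or not), or NULL.
#' @param profile data.frame `position_um`, `intensity` (used when
#'   `positions` is NULL).
#' @param threshold intensity threshold applied after background
#'   subtraction.
#' @param background constant background subtracted from the profile.
#' @param min_separation minimum distance between accepted peaks, um.
#' @return list with `positions`, `intervals`, `median_ipi`, `mean_ipi`.
#'   Fewer than 2 peaks yields an empty interval list with a warning.
#' @export
interpunctum_intervals <- function(positions = NULL, profile = NULL,
                                   threshold = 0, background = 0,
                                   min_separation = 0.5) {
  if (is.null(positions)) {
    stopifnot(is.data.frame(profile),
              all(c("position_um", "intensity") %in% names(profile)))
    y <- profile$intensity - background
    x <- profile$position_um
    n <- length(y)
    is_peak <- y > threshold &
      y >= c(-Inf, y[-n]) & y >= c(y[-1], -Inf)
    cand <- which(is_peak)
    cand <- cand[order(-y[cand])]   # greedy: strongest peaks first
    keep <- integer(0)
    for (i in cand) {
      if (all(abs(x[i] - x[keep]) >= min_separation)) keep <- c(keep, i)
    }
    positions <- sort(x[keep])
  } else {
    positions <- sort(positions)
  }
  if (length(positions) < 2) {
    warning("fewer than 2 puncta; no intervals")
    return(list(positions = positions, intervals = numeric(0),
                median_ipi = NA_real_, mean_ipi = NA_real_))
  }
  intervals <- diff(positions)
  list(positions = positions, intervals = intervals,
       median_ipi = stats::median(intervals), mean_ipi = mean(intervals))
}

#' Morphology of segmented puncta
#'
#' Per-object area, perimeter and roundness `4 pi A / P^2` from a labeled
#' mask (connected components of a thresholded image), converted to
#' physical units with the pixel size.
#'
#' @param label_image integer matrix of object labels (0 = background),
#'   e.g. from [EBImage::bwlabel()].
#' @param pixel_size pixel edge length, um.
#' @return data.frame with `label`, `area_um2`, `perimeter_um`,
#'   `roundness` and attribute `n_objects`; empty mask gives an empty
#'   set.
#' @export
puncta_morphology <- function(label_image, pixel_size = 1) {
  stopifnot(is.matrix(label_image) || inherits(label_image, "Image"),
            pixel_size > 0)
  li <- EBImage::Image(label_image)
  n_obj <- max(label_image)
  if (n_obj == 0) {
    out <- data.frame(label = integer(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), roundness = numeric(0))
    attr(out, "n_objects") <- 0L
    return(out)
  }
  # perimeter as the length of the 8-connected boundary contour (sum of
  # Euclidean steps between successive contour pixels); this tracks the
  # true contour length much better than counting boundary pixels
  contours <- EBImage::ocontour(li)
  out <- do.call(rbind, lapply(seq_len(n_obj), function(lab) {
    area_px <- sum(label_image == lab)
    oc <- contours[[lab]]
    per_px <- if (nrow(oc) < 2) 4 else {
      nxt <- rbind(oc[-1, , drop = FALSE], oc[1, , drop = FALSE])
      sum(sqrt(rowSums((oc - nxt)^2)))
    }
    area <- area_px * pixel_size^2
    per <- per_px * pixel_size
    data.frame(label = lab, area_um2 = area, perimeter_um = per,
               roundness = 4 * pi * area / per^2)
  }))
  attr(out, "n_objects") <- n_obj
  out
}
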