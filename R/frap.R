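# ---- FRAP analysis ----------------------------------------------------------

#' Normalize a raw FRAP ROI series
#'
#' Double normalization corrects the bleached-ROI trace for acquisition
#' bleaching using the whole-condensate ROI:
#' `I_dn(t) = [mean_pre(total - bg) / (total(t) - bg)] *
#'            [(bleached(t) - bg) / mean_pre(bleached - bg)]`.
#' Full-scale normalization then rescales so that the first post-bleach
#' point is 0 and the pre-bleach level is 1:
#' `I_fs = (I_dn - I_dn(t0+)) / (1 - I_dn(t0+))`, which corrects for
#' differences in starting intensity and bleach depth between curves.
#'
#' When a sub-region of a condensate is bleached, the whole condensate
#' dims and its ROI cannot serve as the bleaching reference; with
#' `bleach_rate_correction = TRUE` the reference ROI (an unbleached
#' condensate) replaces the total ROI in the correction factor.
#'
#' @param raw data.frame with columns `t_s`, `phase` (one of
#'   `"prebleach"`, `"bleach"`, `"postbleach1"`, `"postbleach2"`),
#'   `roi_bleached`, `roi_total`, `roi_background`, and optionally
#'   `roi_reference`.
#' @param scheme `"full_scale"` (default) or `"double"` (stop at I_dn).
#' @param bleach_rate_correction use `roi_reference` instead of
#'   `roi_total` for the acquisition-bleaching correction.
#' @return data.frame with `t_s` (re-origined to the first post-bleach
#'   frame), `phase` and `intensity` (normalized), restricted to
#'   pre- and post-bleach frames; pre-bleach frames carry negative time.
#' @export
normalize_frap <- function(raw, scheme = c("full_scale", "double"),
                           bleach_rate_correction = FALSE) {
  scheme <- match.arg(scheme)
  need <- c("t_s", "phase", "roi_bleached", "roi_total", "roi_background")
  stopifnot(is.data.frame(raw), all(need %in% names(raw)))
  pre <- raw$phase == "prebleach"
  post <- raw$phase %in% c("postbleach1", "postbleach2")
  if (sum(pre) < 2) stop("need >= 2 pre-bleach frames")

  bg <- raw$roi_background
  roi <- raw$roi_bleached - bg
  tot_col <- if (bleach_rate_correction) {
    if (is.null(raw$roi_reference)) {
      stop("bleach_rate_correction requires a roi_reference column")
    }
    raw$roi_reference
  } else raw$roi_total
  tot <- tot_col - bg

  if (any(tot[pre] <= 0) || any(roi[pre] <= 0)) {
    stop("background exceeds signal in pre-bleach frames")
  }
  bad <- roi < 0 | tot <= 0
  if (any(bad & (pre | post))) {
    warning("excluding ", sum(bad & (pre | post)),
            " frames with negative background-corrected intensity")
  }

  i_dn <- (mean(tot[pre]) / tot) * (roi / mean(roi[pre]))
  keep <- (pre | post) & !bad
  t0_idx <- which(post & !bad)[1]
  if (is.na(t0_idx)) stop("no usable post-bleach frames")
  out <- data.frame(
    t_s = raw$t_s[keep] - raw$t_s[t0_idx],
    phase = raw$phase[keep],
    intensity = i_dn[keep]
  )
  if (scheme == "full_scale") {
    i0 <- i_dn[t0_idx]
    if (abs(1 - i0) < 1e-9) {
      stop("no detectable bleach (first post-bleach intensity equals ",
           "pre-bleach level); full-scale normalization undefined")
    }
    out$intensity <- (out$intensity - i0) / (1 - i0)
  }
  out
}

#' Fit FRAP recovery kinetics
#'
#' Fits the post-bleach recovery to `I(t) = Mf (1 - exp(-tau t))` by
#' nonlinear least squares in real time units (the post-bleach schedule
#' is typically unevenly spaced), with the time origin at the first
#' post-bleach frame. The half-time is `t_half = ln(2) / tau`.
#'
#' @param curve data.frame from [normalize_frap()] (`t_s`, `phase`,
#'   `intensity`).
#' @param fit_phases phases included in the fit.
#' @return list of class `frap_fit` with `Mf` (mobile fraction, and
#'   `Mf_ci` clipped to `[0, 1]` for reporting alongside the raw CI),
#'   `tau` (1/s), `t_half` (s), standard errors and a `flag`
#'   (`"ok"`, `"flat"` for unidentifiable flat curves, `"Mf_gt_1.1"`).
#' @export
fit_frap <- function(curve, fit_phases = c("postbleach1", "postbleach2")) {
  stopifnot(all(c("t_s", "intensity") %in% names(curve)))
  d <- curve[curve$phase %in% fit_phases, , drop = FALSE]
  if (nrow(d) < 6) stop("need >= 6 post-bleach points to fit recovery")
  if (stats::sd(d$intensity) < 1e-12) {
    out <- list(Mf = mean(d$intensity), Mf_ci = c(NA, NA), tau = NA_real_,
                t_half = NA_real_, se = c(Mf = NA, tau = NA), flag = "flat")
    class(out) <- "frap_fit"
    return(out)
  }
  Mf0 <- max(min(max(d$intensity), 1), 0.05)
  i_half <- which(d$intensity >= Mf0 / 2)[1]
  tau0 <- if (is.na(i_half) || d$t_s[i_half] <= 0) 1 else log(2) / d$t_s[i_half]
  fit <- minpack.lm::nlsLM(
    intensity ~ Mf * (1 - exp(-tau * t_s)), data = d,
    start = list(Mf = Mf0, tau = tau0),
    lower = c(0, 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Mf = NA, tau = NA))
  Mf <- unname(co[["Mf"]]); tau <- unname(co[["tau"]])
  ci_raw <- Mf + c(-1.96, 1.96) * se[["Mf"]]
  out <- list(
    Mf = Mf, Mf_ci_raw = ci_raw,
    Mf_ci = pmin(pmax(ci_raw, 0), 1),
    tau = tau, t_half = log(2) / tau, se = se,
    flag = if (Mf > 1.1) "Mf_gt_1.1" else "ok"
  )
  class(out) <- "frap_fit"
  out
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("FRAP fit: Mf = %.3f, tau = %.4g 1/s, t_half = %.4g s [%s]\n",
              x$Mf, x$tau, x$t_half, x$flag))
  invisible(x)
}

#' Soumpasis diffusion coefficient from FRAP half-time
#'
#' `D = 0.224 r^2 / t_half` for a circular bleach spot of radius `r`.
#' The half-time itself depends on the user-chosen bleach-spot size and
#' is not comparable across studies; `D` removes that dependence.
#'
#' @param t_half recovery half-time, s.
#' @param r bleach-spot radius, um.
#' @return diffusion coefficient, um^2/s.
#' @export
#' @examples
#' soumpasis_diffusion(2, 1)  # 0.112 um^2/s
soumpasis_diffusion <- function(t_half, r) {
  if (!is.numeric(t_half) || any(t_half <= 0)) stop("t_half must be > 0")
  if (!is.numeric(r) || any(r <= 0)) stop("bleach radius r must be > 0")
  0.224 * r^2 / t_half
}

#' Average several normalized FRAP curves
#'
#' Curves from different condensates are averaged frame-by-frame after
#' normalization (they must share an acquisition schedule); per-curve
#' fits should be reported alongside the pooled fit.
#'
#' @param curves list of data.frames from [normalize_frap()].
#' @return single averaged curve (data.frame `t_s`, `phase`,
#'   `intensity`).
#' @export
average_frap_curves <- function(curves) {
  stopifnot(length(curves) >= 1)
  n <- vapply(curves, nrow, 1L)
  if (length(unique(n)) != 1) {
    stop("curves must share the same acquisition schedule to be averaged")
  }
  out <- curves[[1]]
  out$intensity <- rowMeans(vapply(curves, `[[`, numeric(n[1]), "intensity"))
  out
}
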