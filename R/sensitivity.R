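# In-situ Ca2+ sensitivity of SK channels: the Ca2+ transient decay is used
# as a slow intracellular [Ca2+] ramp while I_SK is recorded, the
# (ca, I/Imax) pairs are fitted with a Hill activation curve, and timing
# metrics (time to peak of I_SK vs submembrane Ca2+) quantify the biphasic
# gating signature.

#' Extract (calcium, normalized current) pairs from a transient decay ramp
#'
#' Pairs are taken from the later of the I_SK peak and the calcium peak
#' through to `t_end` — the decaying phase of the transient, where bulk
#' calcium matches submembrane calcium and the subtraction current is no
#' longer contaminated by I_Ca gating. Small non-monotone calcium jitter is
#' removed by keeping only samples that fall below the running minimum
#' (rises are dropped, never smoothed, preserving the measured pairing).
#'
#' @param isk [time_series()] of the isolated SK current (pA).
#' @param ca [time_series()] of calcium (uM), same time base.
#' @param imax normalization reference (pA), > 0. Convention: the peak I_SK
#'   of the same cell under ISO; when that is unavailable the sweep's own
#'   peak may be used (flag it in downstream reporting).
#' @param t_end end of the ramp (ms); default end of trace, typically set to
#'   the end of the voltage step.
#' @return object of class `ramp_pairs`: `ca` (uM, decreasing), `i_norm`
#'   (I/Imax), `t` (ms), `imax`, `n_dropped`.
#' @export
extract_ramp <- function(isk, ca, imax, t_end = NULL) {
  stopifnot(inherits(isk, "time_series"), inherits(ca, "time_series"))
  if (!same_time_base(isk, ca))
    stop("isk and ca must share the same time base")
  if (!is.finite(imax) || imax <= 0) stop("`imax` must be > 0")
  tt <- ts_time(isk)
  last <- if (is.null(t_end)) length(tt) else {
    k <- which(tt <= t_end + 1e-9)
    if (!length(k)) stop("`t_end` precedes the trace")
    max(k)
  }
  start <- max(which.max(isk$values[1:last]), which.max(ca$values[1:last]))
  if (start >= last)
    stop("peak at trace end: no decay phase to extract")
  idx <- start:last
  keep <- idx[1L]
  run_min <- ca$values[idx[1L]]
  for (j in idx[-1L]) {
    if (ca$values[j] < run_min) {
      keep <- c(keep, j)
      run_min <- ca$values[j]
    }
  }
  if (length(keep) < 2L)
    stop("calcium does not decay within the window; no ramp to extract")
  structure(list(ca = ca$values[keep], i_norm = isk$values[keep] / imax,
                 t = tt[keep], imax = imax,
                 n_dropped = length(idx) - length(keep)),
            class = "ramp_pairs")
}

#' @export
print.ramp_pairs <- function(x, ...) {
  cat(sprintf("<ramp_pairs> %d points, ca %.3g..%.3g uM, %d dropped\n",
              length(x$ca), max(x$ca), min(x$ca), x$n_dropped))
  invisible(x)
}

#' Fit the Hill activation curve to a calcium ramp
#'
#' Unweighted least-squares fit of `I/Imax = 1 / (1 + (EC50/ca)^h)` in
#' linear concentration space, with multistart initialization over
#' `EC50 in {0.2, 0.5, 1.0} uM x h in {1, 2, 4}`; the start reaching the
#' lowest RMSE wins. The model is activation-only: decay-phase data are
#' fitted under the assumption that the Ca2+/voltage-dependent inhibition
#' arm is negligible over the ramp's concentration range.
#'
#' @param pairs [extract_ramp()] output (or any list with numeric `ca`,
#'   `i_norm`, `imax`).
#' @param min_points minimum number of pairs (default 8); the calcium range
#'   must additionally span at least 3-fold.
#' @param fit_amplitude when `FALSE` (default) the plateau is fixed at 1,
#'   the convention when data are pre-normalized to Imax. When `TRUE` a
#'   free plateau `A / (1 + (EC50/ca)^h)` is fitted instead, which makes
#'   the recovered `ec50` and `h` insensitive to errors in the Imax
#'   estimate (the ramp rarely contains the true current peak, so the top
#'   of the measured curve sits below 1).
#' @return object of class `hill_fit`: `ec50` (uM), `h`, `amplitude`
#'   (fitted plateau; 1 when fixed), `imax_used` (pA), `rmse`, `n_points`,
#'   `reliable` (FALSE when EC50 leaves `[1e-3, 1e3]` uM).
#' @export
fit_hill <- function(pairs, min_points = 8, fit_amplitude = FALSE) {
  ca <- pairs$ca
  y <- pairs$i_norm
  stopifnot(length(ca) == length(y))
  if (length(ca) < min_points)
    stop("need at least ", min_points, " ramp points")
  if (max(ca) / max(min(ca), .Machine$double.eps) < 3)
    stop("calcium ramp must span at least a 3-fold range")
  starts <- expand.grid(ec50 = c(0.2, 0.5, 1.0), h = c(1, 2, 4))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch({
      if (fit_amplitude)
        minpack.lm::nlsLM(y ~ A / (1 + (ec50 / ca)^h),
                          start = c(list(A = max(y)), as.list(starts[i, ])),
                          lower = c(A = 1e-6, ec50 = 1e-6, h = 0.05),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      else
        minpack.lm::nlsLM(y ~ 1 / (1 + (ec50 / ca)^h),
                          start = as.list(starts[i, ]),
                          lower = c(ec50 = 1e-6, h = 0.05),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rmse <- sqrt(mean(stats::resid(fit)^2))
    if (is.null(best) || rmse < best$rmse)
      best <- list(fit = fit, rmse = rmse)
  }
  if (is.null(best))
    stop("Hill fit failed to converge from all ",
         nrow(starts), " multistart initializations")
  cf <- stats::coef(best$fit)
  ec50 <- unname(cf["ec50"]); h <- unname(cf["h"])
  structure(list(ec50 = ec50, h = h,
                 amplitude = if (fit_amplitude) unname(cf["A"]) else 1,
                 imax_used = if (is.null(pairs$imax)) NA_real_ else pairs$imax,
                 rmse = best$rmse, n_points = length(ca),
                 reliable = ec50 >= 1e-3 && ec50 <= 1e3),
            class = "hill_fit")
}

#' In-situ Ca2+-sensitivity assay on a pre/post-blocker sweep pair
#'
#' Runs the complete decay-ramp assay: isolates the blocker-sensitive
#' current, calibrates the fluorescence of the pre-blocker sweep to
#' [Ca2+]i, smooths both with a short Savitzky-Golay filter (the same
#' 5-point smoothing applied to calibrated calcium throughout the
#' package's workflow), takes the step-window peak of the smoothed I_SK as
#' Imax, extracts the decay-phase ramp and fits the Hill activation curve.
#'
#' The fit frees the plateau by default (see [fit_hill()]): the ramp
#' starts only once bulk calcium matches submembrane calcium, after the
#' current peak, so the measured top sits below Imax and a fixed unit
#' plateau would bias the recovered parameters.
#'
#' @param pre,post pre- and post-blocker [vc_sweep()]s (same cell and
#'   protocol).
#' @param kd indicator Kd, uM.
#' @param sg_window Savitzky-Golay window (samples) for the smoothing of
#'   calcium and current before ramp extraction.
#' @param imax optional external normalization reference (pA), e.g. the
#'   ISO-condition peak when fitting a baseline sweep; default: the
#'   smoothed peak of this pair's own I_SK (flagged in the result).
#' @param fit_amplitude passed to [fit_hill()]; default `TRUE`.
#' @return list of class `ramp_assay`: `fit` ([fit_hill()] result), `ramp`
#'   ([extract_ramp()] pairs), `imax`, `imax_source` (`"self"` or
#'   `"external"`), `isolated` (the [isolate_isk()] output).
#' @export
isk_ramp_assay <- function(pre, post, kd = 1.58, sg_window = 5,
                           imax = NULL, fit_amplitude = TRUE) {
  iso <- isolate_isk(pre, post)
  if (is.null(pre$fluorescence) || !is.finite(pre$fmax))
    stop("pre-blocker sweep needs fluorescence and fmax for calibration")
  ca <- calibrate_fluorescence(pre$fluorescence,
                               calibration_params(fmax = pre$fmax, kd = kd))
  sg <- function(x, unit) time_series(
    signal::sgolayfilt(x$values, p = 2, n = sg_window), x$dt, x$t0, unit)
  ca_s <- sg(ca, "uM")
  ik_s <- sg(iso$i_sk, "pA")
  w <- c(pre$protocol$step_onset,
         pre$protocol$step_onset + pre$protocol$step_duration)
  imax_source <- if (is.null(imax)) "self" else "external"
  if (is.null(imax))
    imax <- peak_in_window(ik_s, w, "outward")$amplitude
  ramp <- extract_ramp(ik_s, ca_s, imax, t_end = w[2])
  fit <- fit_hill(ramp, fit_amplitude = fit_amplitude)
  structure(list(fit = fit, ramp = ramp, imax = imax,
                 imax_source = imax_source, isolated = iso),
            class = "ramp_assay")
}

#' @export
print.ramp_assay <- function(x, ...) {
  cat(sprintf("<ramp_assay> Imax %.4g pA (%s); ", x$imax, x$imax_source))
  print(x$fit)
  invisible(x)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> EC50 = %.4g uM, h = %.3g, rmse = %.3g, n = %d%s\n",
              x$ec50, x$h, x$rmse, x$n_points,
              if (x$reliable) "" else " [flagged unreliable]"))
  invisible(x)
}

#' Fit the inhibitory (descending) arm of the biphasic Po curve
#'
#' Least-squares fit of `Po = amplitude / (1 + (ca/IC50)^h)` to descending-
#' limb data, i.e. open probabilities sampled at calcium concentrations
#' above the activation range, where the activation gate is saturated and
#' only the Ca2+/voltage-dependent inhibition shapes the curve.
#'
#' @param ca calcium concentrations (uM), descending-limb samples.
#' @param po open probabilities (or currents proportional to them).
#' @return list of class `inhibition_fit`: `ic50` (uM), `h_inh`,
#'   `amplitude`, `rmse`.
#' @export
fit_inhibition <- function(ca, po) {
  stopifnot(length(ca) == length(po), length(ca) >= 5)
  a0 <- max(po)
  starts <- expand.grid(ic50 = c(5, 20, 80), h = c(1, 2, 4))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(po ~ a / (1 + (ca / ic50)^h),
                        start = c(list(a = a0), as.list(starts[i, ])),
                        lower = c(a = 1e-6, ic50 = 1e-3, h = 0.05),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rmse <- sqrt(mean(stats::resid(fit)^2))
    if (is.null(best) || rmse < best$rmse) best <- list(fit = fit, rmse = rmse)
  }
  if (is.null(best)) stop("inhibition fit failed from all starts")
  cf <- stats::coef(best$fit)
  structure(list(ic50 = unname(cf["ic50"]), h_inh = unname(cf["h"]),
                 amplitude = unname(cf["a"]), rmse = best$rmse),
            class = "inhibition_fit")
}

#' Timing metrics of I_SK relative to submembrane calcium
#'
#' Times to peak are measured from the step onset; `ca_sm_at_peak_isk` reads
#' the submembrane calcium at the sample where I_SK peaks. In biphasically
#' gated cells I_SK peaks while submembrane calcium is still rising, so
#' `ttp_isk < ttp_casm` and `ca_sm_at_peak_isk < ca_sm_peak`.
#'
#' @param isk [time_series()] of the isolated SK current (pA).
#' @param ca_sm [time_series()] of submembrane calcium (uM), same time base.
#' @param onset step onset (ms), inside both traces.
#' @return list of class `timing_metrics`: `ttp_isk`, `ttp_casm` (ms),
#'   `ca_sm_at_peak_isk`, `ca_sm_peak` (uM).
#' @export
timing_metrics <- function(isk, ca_sm, onset) {
  stopifnot(inherits(isk, "time_series"), inherits(ca_sm, "time_series"))
  if (!same_time_base(isk, ca_sm))
    stop("isk and ca_sm must share the same time base")
  tt <- ts_time(isk)
  if (onset < tt[1] - 1e-9 || onset > tt[length(tt)] + 1e-9)
    stop("onset outside the trace span")
  idx <- which(tt >= onset - 1e-9)
  k_isk <- idx[which.max(isk$values[idx])]
  k_ca <- idx[which.max(ca_sm$values[idx])]
  structure(list(ttp_isk = tt[k_isk] - onset,
                 ttp_casm = tt[k_ca] - onset,
                 ca_sm_at_peak_isk = ca_sm$values[k_isk],
                 ca_sm_peak = ca_sm$values[k_ca]),
            class = "timing_metrics")
}

#' @export
print.timing_metrics <- function(x, ...) {
  cat(sprintf(paste0("<timing_metrics> ttp I_SK %.3g ms, ttp [Ca]sm %.3g ms; ",
                     "[Ca]sm at peak I_SK %.3g uM (peak %.3g uM)\n"),
              x$ttp_isk, x$ttp_casm, x$ca_sm_at_peak_isk, x$ca_sm_peak))
  invisible(x)
}
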