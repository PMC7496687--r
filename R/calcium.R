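# Fluorescence -> [Ca2+]i calibration and submembrane [Ca2+] reconstruction.
#
# Single-wavelength (Rhod-2) calibration:
#   [Ca2+]i = Kd * (F - Fmin) / (Fmax - F),  Kd = 1.58 uM, Fmin = Fmax/15.
# Submembrane reconstruction: [Ca2+]sm = [Ca2+]i + gamma * d[Ca2+]i/dt with
# gamma = 110 ms, the derivative taken on a Savitzky-Golay-smoothed trace;
# after the reconstructed peak the decay is continued with the single
# exponential fitted to the bulk [Ca2+]i decay.

#' Calibration parameters for a single-wavelength Ca2+ indicator
#'
#' @param fmax saturating fluorescence (a.u.), measured e.g. by exposing the
#'   dye to the bath Ca2+ after breaking the pipette. When `mode =
#'   "F_over_F0"` this is Fmax/F0, on the same normalized scale as the data.
#' @param kd indicator dissociation constant, uM. Default 1.58 uM (Rhod-2,
#'   in-cell).
#' @param fmin fluorescence at zero Ca2+ (a.u.). Default `fmax/15`.
#' @param mode `"absolute_F"` if traces are raw fluorescence, `"F_over_F0"`
#'   if they were pre-normalized to resting fluorescence (used when the
#'   baseline drifted during an experiment). The algebra is identical; the
#'   tag records which scale `fmax` lives on.
#' @return object of class `calibration_params`.
#' @export
calibration_params <- function(fmax, kd = 1.58, fmin = fmax / 15,
                               mode = c("absolute_F", "F_over_F0")) {
  mode <- match.arg(mode)
  if (!is.finite(kd) || kd <= 0) stop("`kd` must be > 0")
  if (!is.finite(fmax) || !is.finite(fmin) || !(fmax > fmin && fmin > 0))
    stop("need fmax > fmin > 0")
  structure(list(kd = kd, fmax = fmax, fmin = fmin, mode = mode),
            class = "calibration_params")
}

#' Convert indicator fluorescence to [Ca2+]i
#'
#' Applies `[Ca2+] = kd * (F - fmin) / (fmax - F)`. Samples below `fmin`
#' (noise excursions) are clipped to 0 uM with a warning reporting how many;
#' samples at or above `fmax` are a hard error since the hyperbola diverges
#' there.
#'
#' @param f [time_series()] of fluorescence (a.u.).
#' @param p [calibration_params()].
#' @return [time_series()] of calcium (uM).
#' @seealso [inverse_calibrate()] for the algebraic inverse.
#' @export
calibrate_fluorescence <- function(f, p) {
  stopifnot(inherits(f, "time_series"), inherits(p, "calibration_params"))
  hi <- which(f$values >= p$fmax)
  if (length(hi))
    stop(sprintf("fluorescence at/above Fmax at index %d (F=%g, Fmax=%g)",
                 hi[1L], f$values[hi[1L]], p$fmax))
  ca <- p$kd * (f$values - p$fmin) / (p$fmax - f$values)
  n_clip <- sum(ca < -1e-12 * p$kd)   # round-off at F == Fmin clips silently
  if (n_clip > 0)
    warning(sprintf("%d sample(s) below Fmin clipped to 0 uM", n_clip))
  ca[ca < 0] <- 0
  time_series(ca, dt = f$dt, t0 = f$t0, unit = "uM")
}

#' Convert [Ca2+] back to indicator fluorescence
#'
#' Algebraic inverse of [calibrate_fluorescence()]:
#' `F = (fmax * ca + kd * fmin) / (ca + kd)`, which maps `[0, Inf)` uM into
#' `[fmin, fmax)`. Used by the simulator to synthesize fluorescence.
#'
#' @param ca [time_series()] of calcium (uM), non-negative.
#' @param p [calibration_params()].
#' @return [time_series()] of fluorescence (a.u.).
#' @export
inverse_calibrate <- function(ca, p) {
  stopifnot(inherits(ca, "time_series"), inherits(p, "calibration_params"))
  if (any(ca$values < 0)) stop("calcium must be non-negative")
  f <- (p$fmax * ca$values + p$kd * p$fmin) / (ca$values + p$kd)
  time_series(f, dt = ca$dt, t0 = ca$t0, unit = "a.u.")
}

#' Fit a single exponential decay
#'
#' Least-squares fit of `baseline + amplitude * exp(-(t - t_start) / tau)`
#' over `[t_start, end]`, as used for Ca2+ transient decays.
#'
#' @param x [time_series()] containing the decay.
#' @param t_start start of the fitted window (ms); at least 10 samples must
#'   follow it and the signal must actually decay (last-quartile mean below
#'   first-quartile mean).
#' @return object of class `exp_decay_fit`: `amplitude` (signal units),
#'   `tau` (ms), `baseline`, `t_start`, `rmse`.
#' @export
fit_single_exponential <- function(x, t_start) {
  stopifnot(inherits(x, "time_series"))
  tt <- ts_time(x)
  idx <- which(tt >= t_start - 1e-9)
  if (length(idx) < 10L)
    stop("need at least 10 samples after t_start")
  y <- x$values[idx]
  td <- tt[idx] - t_start
  n <- length(y)
  q <- max(2L, floor(n / 4))
  if (!(mean(y[(n - q + 1L):n]) < mean(y[1:q])))
    stop("signal does not decay after t_start (precondition violated)")
  b0 <- mean(y[max(1L, n - max(2L, floor(n / 10))):n])
  a0 <- y[1L] - b0
  # crude tau from the time to reach 1/e of the initial excess, fallback span/3
  tau0 <- {
    target <- b0 + a0 / exp(1)
    k <- if (a0 > 0) which(y <= target) else which(y >= target)
    if (length(k)) max(td[k[1L]], x$dt) else max(td) / 3
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ b + a * exp(-td / tau),
                      start = list(a = a0, b = b0, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(sprintf(paste0("single-exponential fit did not converge ",
                          "(initializer a=%g, b=%g, tau=%g): %s"),
                   a0, b0, tau0, conditionMessage(e)))
  )
  cf <- stats::coef(fit)
  structure(list(amplitude = unname(cf["a"]), tau = unname(cf["tau"]),
                 baseline = unname(cf["b"]), t_start = t_start,
                 rmse = sqrt(mean(stats::resid(fit)^2))),
            class = "exp_decay_fit")
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  cat(sprintf("<exp_decay_fit> amplitude %.4g, tau %.4g ms, baseline %.4g, rmse %.3g\n",
              x$amplitude, x$tau, x$baseline, x$rmse))
  invisible(x)
}

#' Parameters of the submembrane Ca2+ reconstruction
#'
#' @param gamma diffusion constant (ms) scaling the derivative term; default
#'   110 ms.
#' @param sg_window Savitzky-Golay window (samples, odd, >= 3); default 5.
#' @param sg_polyorder Savitzky-Golay polynomial order; default 2, the usual
#'   choice for a 5-point window.
#' @return object of class `submembrane_params`.
#' @export
submembrane_params <- function(gamma = 110, sg_window = 5, sg_polyorder = 2) {
  if (!is.finite(gamma) || gamma < 0) stop("`gamma` must be >= 0")
  if (sg_window < 3 || sg_window %% 2 == 0)
    stop("`sg_window` must be odd and >= 3")
  if (!(sg_polyorder > 0 && sg_polyorder < sg_window))
    stop("need 0 < sg_polyorder < sg_window")
  structure(list(gamma = gamma, sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder)),
            class = "submembrane_params")
}

# central-difference derivative, one-sided at the edges
central_diff <- function(y, dt) {
  n <- length(y)
  d <- numeric(n)
  d[1L] <- (y[2L] - y[1L]) / dt
  d[n] <- (y[n] - y[n - 1L]) / dt
  if (n > 2L) d[2:(n - 1L)] <- (y[3:n] - y[1:(n - 2L)]) / (2 * dt)
  d
}

#' Reconstruct submembrane [Ca2+] from the bulk transient
#'
#' The rise and peak of submembrane calcium are obtained as
#' `[Ca2+]i + gamma * d[Ca2+]i/dt`, with the derivative computed by central
#' differences on a Savitzky-Golay-smoothed copy of the bulk trace. Beyond
#' the reconstructed peak, where the derivative term no longer reflects a
#' standing gradient, the trace is continued as a single exponential that
#' follows the decay of the bulk transient: the tau and baseline come from
#' [fit_single_exponential()] applied to `ca_i` from its own peak, with the
#' amplitude anchored at the reconstructed peak for continuity.
#'
#' A constant input (zero derivative everywhere) is returned unchanged with
#' a `NULL` decay fit. A non-constant input without a detectable bulk decay
#' is an error.
#'
#' @param ca_i [time_series()] of bulk calcium (uM), uniformly sampled,
#'   longer than `sg_window`.
#' @param p [submembrane_params()].
#' @return object of class `ca_traces`: `ca_i`, `ca_sm` (spliced), `raw_sm`
#'   (pre-splice `ca_i + gamma*d/dt`), `decay_fit`, `params`.
#' @export
reconstruct_submembrane <- function(ca_i, p = submembrane_params()) {
  stopifnot(inherits(ca_i, "time_series"), inherits(p, "submembrane_params"))
  v <- ca_i$values
  if (length(v) <= p$sg_window)
    stop("trace must be longer than the Savitzky-Golay window")
  sm <- signal::sgolayfilt(v, p = p$sg_polyorder, n = p$sg_window)
  d <- central_diff(sm, ca_i$dt)
  raw <- v + p$gamma * d
  tt <- ts_time(ca_i)
  scale <- max(abs(v), 1e-12)
  if (max(abs(d)) * p$gamma <= 1e-10 * scale) {
    # derivative numerically zero everywhere: gamma term vanishes
    return(structure(list(ca_i = ca_i,
                          ca_sm = time_series(raw, ca_i$dt, ca_i$t0, "uM"),
                          raw_sm = time_series(raw, ca_i$dt, ca_i$t0, "uM"),
                          decay_fit = NULL, params = p),
                     class = "ca_traces"))
  }
  i_peak_raw <- which.max(raw)
  i_peak_bulk <- which.max(v)
  fit <- tryCatch(fit_single_exponential(ca_i, t_start = tt[i_peak_bulk]),
                  error = function(e)
                    stop("no decay phase detectable in ca_i: ",
                         conditionMessage(e)))
  ca_sm <- raw
  if (i_peak_raw < length(v)) {
    after <- (i_peak_raw + 1L):length(v)
    ca_sm[after] <- fit$baseline +
      (raw[i_peak_raw] - fit$baseline) *
      exp(-(tt[after] - tt[i_peak_raw]) / fit$tau)
  }
  n_neg <- sum(ca_sm < 0)
  if (n_neg > 0) {
    warning(sprintf("%d negative submembrane sample(s) clipped to 0 uM", n_neg))
    ca_sm[ca_sm < 0] <- 0
  }
  structure(list(ca_i = ca_i,
                 ca_sm = time_series(ca_sm, ca_i$dt, ca_i$t0, "uM"),
                 raw_sm = time_series(raw, ca_i$dt, ca_i$t0, "uM"),
                 decay_fit = fit, params = p),
            class = "ca_traces")
}

#' @export
print.ca_traces <- function(x, ...) {
  cat(sprintf("<ca_traces> %d samples; peak ca_i %.3g uM, peak ca_sm %.3g uM\n",
              length(x$ca_i$values), max(x$ca_i$values), max(x$ca_sm$values)))
  invisible(x)
}
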