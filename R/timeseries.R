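#' sksense: SK current and calcium-sensitivity analysis for cardiac myocytes
#'
#' Analysis of small-conductance Ca2+-activated K+ (SK) currents in
#' ventricular myocytes: fluorescence-to-calcium calibration, submembrane
#' calcium reconstruction, blocker-subtraction current isolation, in-situ
#' Hill Ca2+-sensitivity estimation, optical-map repolarization metrics, a
#' biphasic SK gating simulator, and a free-ion solver for pipette recipes.
#'
#' See `vignette("sk-biphasic-gating", package = "sksense")` for the
#' scientific background and the design choices behind each stage.
#'
#' @keywords internal
"_PACKAGE"

#' Uniformly sampled time series
#'
#' The basic container for every sampled signal in the package: membrane
#' current (pA), line-scan-averaged fluorescence (a.u.), calcium (uM) or
#' membrane potential (mV). Time is milliseconds throughout.
#'
#' @param values numeric vector of samples; must be finite, length >= 2.
#' @param dt sampling interval (ms), > 0.
#' @param t0 time of the first sample (ms).
#' @param unit unit tag carried with the signal, one of `"pA"`, `"a.u."`,
#'   `"uM"`, `"mV"`.
#' @return an object of class `time_series` with fields `t0`, `dt`,
#'   `values`, `unit`.
#' @examples
#' x <- time_series(sin(seq(0, 1, 0.01)), dt = 5, unit = "a.u.")
#' head(ts_time(x))
#' @export
time_series <- function(values, dt, t0 = 0, unit = c("pA", "a.u.", "uM", "mV")) {
  unit <- match.arg(unit)
  values <- as.numeric(values)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number (ms)")
  if (length(values) < 2L)
    stop("a time_series needs at least 2 samples")
  bad <- which(!is.finite(values))
  if (length(bad))
    stop(sprintf("non-finite sample at index %d", bad[1L]))
  structure(list(t0 = as.numeric(t0), dt = dt, values = values, unit = unit),
            class = "time_series")
}

#' Sample times of a time series
#' @param x a [time_series()]
#' @return numeric vector of times (ms), same length as `x$values`
#' @export
ts_time <- function(x) {
  stopifnot(inherits(x, "time_series"))
  x$t0 + (seq_along(x$values) - 1L) * x$dt
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d samples, dt = %g ms, t0 = %g ms, unit = %s\n",
              length(x$values), x$dt, x$t0, x$unit))
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$values)

# indices of samples falling inside [window[1], window[2]] (ms, inclusive)
ts_window_idx <- function(x, window) {
  stopifnot(length(window) == 2L, window[2] >= window[1])
  tt <- ts_time(x)
  if (window[1] < tt[1] - 1e-9 || window[2] > tt[length(tt)] + 1e-9)
    stop("window extends beyond the trace span")
  which(tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9)
}

# check two series share the same sampling grid
same_time_base <- function(a, b) {
  isTRUE(all.equal(a$t0, b$t0, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$dt, b$dt, tolerance = 1e-9)) &&
    length(a$values) == length(b$values)
}

#' Voltage-step protocol
#'
#' Describes one depolarizing-step episode: the cell is held at
#' `holding_potential`, stepped to `step_potential` at `step_onset` for
#' `step_duration`, with episodes repeated every `inter_sweep_interval`.
#'
#' @param step_potential step (test) potential, mV.
#' @param holding_potential holding potential, mV. Native myocytes were held
#'   at -40 mV; SK2-overexpressing cultured cells at -45 mV.
#' @param step_onset time of step onset from sweep start, ms (>= 0).
#' @param step_duration step length, ms (> 0).
#' @param inter_sweep_interval time between episodes, ms.
#' @return object of class `step_protocol`.
#' @export
step_protocol <- function(step_potential, holding_potential = -40,
                          step_onset = 20, step_duration = 400,
                          inter_sweep_interval = 2000) {
  if (step_onset < 0) stop("`step_onset` must be >= 0")
  if (step_duration <= 0) stop("`step_duration` must be > 0")
  structure(list(holding_potential = as.numeric(holding_potential),
                 step_potential = as.numeric(step_potential),
                 step_onset = as.numeric(step_onset),
                 step_duration = as.numeric(step_duration),
                 inter_sweep_interval = as.numeric(inter_sweep_interval)),
            class = "step_protocol")
}

protocols_equal <- function(a, b, tol = 1e-9) {
  all(abs(c(a$holding_potential - b$holding_potential,
            a$step_potential - b$step_potential,
            a$step_onset - b$step_onset,
            a$step_duration - b$step_duration)) <= tol)
}

#' One voltage-clamp sweep
#'
#' A sweep bundles the recorded membrane current, the simultaneous (optional)
#' line-scan-averaged fluorescence, the voltage protocol and the cell
#' metadata needed for density normalization and calcium calibration.
#'
#' @param current [time_series()] of membrane current (pA); outward positive.
#' @param protocol [step_protocol()].
#' @param capacitance cell capacitance, pF (> 0).
#' @param condition condition tag, e.g. `"baseline"`, `"ISO"`, `"APA"`,
#'   `"ISO+APA"`, `"PKI"`, `"UCL"`.
#' @param cell_id cell identifier.
#' @param fluorescence optional [time_series()] of indicator fluorescence
#'   (a.u.); if present it must cover the step window.
#' @param fmax,f0 optional calibration anchors (a.u.): saturating
#'   fluorescence, and the resting fluorescence used when working in F/F0.
#' @param truth optional list of ground-truth channels attached by the
#'   simulator (not serialized).
#' @return object of class `sweep`.
#' @export
vc_sweep <- function(current, protocol, capacitance, condition, cell_id,
                  fluorescence = NULL, fmax = NA_real_, f0 = NA_real_,
                  truth = NULL) {
  stopifnot(inherits(current, "time_series"), inherits(protocol, "step_protocol"))
  if (!is.numeric(capacitance) || length(capacitance) != 1L ||
      !is.finite(capacitance) || capacitance <= 0)
    stop(sprintf("capacitance missing for cell_id=%s (must be a positive number)",
                 as.character(cell_id)))
  if (!is.null(fluorescence)) {
    stopifnot(inherits(fluorescence, "time_series"))
    tt <- ts_time(fluorescence)
    w <- c(protocol$step_onset, protocol$step_onset + protocol$step_duration)
    if (tt[1] > w[1] + 1e-9 || tt[length(tt)] < w[2] - 1e-9)
      stop("fluorescence trace does not cover the step window")
  }
  structure(list(current = current, fluorescence = fluorescence,
                 protocol = protocol, capacitance = capacitance,
                 condition = as.character(condition),
                 cell_id = as.character(cell_id),
                 fmax = as.numeric(fmax), f0 = as.numeric(f0),
                 truth = truth),
            class = "sweep")
}

sweep_key <- function(s) {
  paste(s$cell_id, s$condition, format(s$protocol$step_potential), sep = "|")
}

#' A set of sweeps grouped by (cell, condition, step potential)
#'
#' @param sweeps list of [sweep()] objects. All sweeps of a cell must share
#'   its capacitance, and at most one sweep may exist per
#'   (cell, condition, voltage) combination.
#' @return object of class `experiment_set` (a list with element `sweeps`).
#' @export
experiment_set <- function(sweeps = list()) {
  stopifnot(is.list(sweeps))
  for (s in sweeps) stopifnot(inherits(s, "sweep"))
  keys <- vapply(sweeps, sweep_key, character(1))
  if (anyDuplicated(keys))
    stop("duplicate sweep for group: ", keys[duplicated(keys)][1L])
  caps <- split(vapply(sweeps, function(s) s$capacitance, numeric(1)),
                vapply(sweeps, function(s) s$cell_id, character(1)))
  for (cid in names(caps))
    if (length(unique(caps[[cid]])) > 1L)
      stop("sweeps of cell ", cid, " disagree on capacitance")
  structure(list(sweeps = sweeps), class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  cat(sprintf("<experiment_set> %d sweeps, %d cells, conditions: %s\n",
              length(x$sweeps),
              length(unique(vapply(x$sweeps, function(s) s$cell_id, character(1)))),
              paste(unique(vapply(x$sweeps, function(s) s$condition, character(1))),
                    collapse = ", ")))
  invisible(x)
}

#' @export
length.experiment_set <- function(x) length(x$sweeps)

# retrieve the unique sweep for a (cell, condition, voltage) group, or NULL
get_sweep <- function(set, cell_id, condition, step_potential) {
  for (s in set$sweeps)
    if (s$cell_id == cell_id && s$condition == condition &&
        abs(s$protocol$step_potential - step_potential) < 1e-9)
      return(s)
  NULL
}
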