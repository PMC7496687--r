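# Blocker-subtraction isolation of the SK current and I-V assembly.
#
# I_SK is defined operationally as the current sensitive to a selective SK
# blocker (apamin or UCL-1684): i_sk(t) = i_pre(t) - i_post(t). The residual
# post-blocker trace is interpreted as I_Ca plus leak. Densities are pA/pF.

#' Isolate the blocker-sensitive SK current from a sweep pair
#'
#' Subtracts the post-blocker current trace from the matching pre-blocker
#' trace, sample by sample. The two sweeps must come from the same cell with
#' identical protocol timing and sampling; no realignment or filtering is
#' performed (misaligned protocols should fail loudly, not produce silent
#' subtraction artefacts).
#'
#' @param pre [sweep()] recorded before blocker application.
#' @param post [sweep()] recorded after blocker application (condition tag
#'   carrying the blocker, e.g. `"APA"` or `"ISO+APA"`).
#' @return object of class `isolated_current`: `i_sk` ([time_series()], pA),
#'   `i_residual` (the post trace), `step_potential`, `capacitance`.
#' @export
isolate_isk <- function(pre, post) {
  stopifnot(inherits(pre, "sweep"), inherits(post, "sweep"))
  if (pre$cell_id != post$cell_id)
    stop("pre and post sweeps come from different cells (",
         pre$cell_id, " vs ", post$cell_id, ")")
  if (!protocols_equal(pre$protocol, post$protocol))
    stop("protocol mismatch between pre and post sweeps ",
         "(holding/step/onset/duration must be identical)")
  if (!same_time_base(pre$current, post$current))
    stop("protocol mismatch: current traces differ in dt, t0 or length")
  i_sk <- time_series(pre$current$values - post$current$values,
                      dt = pre$current$dt, t0 = pre$current$t0, unit = "pA")
  structure(list(i_sk = i_sk, i_residual = post$current,
                 step_potential = pre$protocol$step_potential,
                 capacitance = pre$capacitance),
            class = "isolated_current")
}

#' Peak of a trace within a time window
#'
#' @param x [time_series()].
#' @param window `c(start, end)` in ms, inside the trace span.
#' @param polarity `"outward"` (maximum) or `"inward"` (minimum, amplitude
#'   reported as magnitude).
#' @return list with `amplitude` (magnitude, >= 0 for inward), `value` (the
#'   signed sample), `t_peak` (ms; ties broken by the earliest sample) and
#'   `polarity`.
#' @export
peak_in_window <- function(x, window, polarity = c("outward", "inward")) {
  polarity <- match.arg(polarity)
  idx <- ts_window_idx(x, window)
  if (!length(idx)) stop("empty peak-search window")
  v <- x$values[idx]
  k <- if (polarity == "outward") which.max(v) else which.min(v)
  value <- v[k]
  list(amplitude = if (polarity == "inward") abs(value) else value,
       value = value,
       t_peak = ts_time(x)[idx[k]],
       polarity = polarity)
}

#' Build a pooled current-voltage summary from an experiment set
#'
#' For every cell and step potential with a matching (pre, post-blocker)
#' pair, isolates I_SK, measures the peak outward SK density and the peak
#' inward residual (I_Ca) density within the step window, and calibrates the
#' pre-blocker fluorescence to obtain the peak calcium. Per-voltage values
#' are pooled over cells as mean and SD.
#'
#' The post-blocker condition tag is `blocker` when `pre_condition` is
#' `"baseline"`, and `"<pre_condition>+<blocker>"` otherwise (e.g. `"ISO"`
#' pairs with `"ISO+APA"`).
#'
#' @param set [experiment_set()].
#' @param blocker blocker tag, `"APA"` or `"UCL"`.
#' @param pre_condition condition of the pre-blocker sweeps.
#' @param kd indicator Kd (uM) used for calcium calibration; the per-sweep
#'   `fmax` anchors the calibration (Fmin = Fmax/15).
#' @param window optional `c(start, end)` ms peak-search window; default is
#'   the step window `[onset, onset + duration]`.
#' @return data.frame of class `iv_curve` with columns `voltage_mV`,
#'   `isk_pApF_mean`, `isk_pApF_sd`, `ica_pApF_mean`, `ica_pApF_sd`,
#'   `peak_ca_uM_mean`, `peak_ca_uM_sd`, `n`. Per-cell values are attached
#'   as attribute `"per_cell"`.
#' @export
build_iv <- function(set, blocker = "APA", pre_condition = "baseline",
                     kd = 1.58, window = NULL) {
  stopifnot(inherits(set, "experiment_set"))
  post_condition <- if (pre_condition == "baseline") blocker else
    paste(pre_condition, blocker, sep = "+")
  pre_sweeps <- Filter(function(s) s$condition == pre_condition, set$sweeps)
  if (!length(pre_sweeps))
    stop("no sweeps with condition '", pre_condition, "' in the set")
  cells <- sort(unique(vapply(pre_sweeps, function(s) s$cell_id, character(1))))
  voltages <- sort(unique(vapply(pre_sweeps,
                                 function(s) s$protocol$step_potential,
                                 numeric(1))))
  unmatched <- character(0)
  rows <- list()
  for (cell in cells) {
    for (v in voltages) {
      pre <- get_sweep(set, cell, pre_condition, v)
      if (is.null(pre)) next
      post <- get_sweep(set, cell, post_condition, v)
      if (is.null(post)) {
        unmatched <- c(unmatched,
                       sprintf("%s @ %+g mV (missing '%s')", cell, v,
                               post_condition))
        next
      }
      iso <- isolate_isk(pre, post)
      w <- if (is.null(window))
        c(pre$protocol$step_onset,
          pre$protocol$step_onset + pre$protocol$step_duration) else window
      pk_sk <- peak_in_window(iso$i_sk, w, "outward")
      pk_ca_cur <- peak_in_window(iso$i_residual, w, "inward")
      peak_ca <- NA_real_
      if (!is.null(pre$fluorescence) && is.finite(pre$fmax)) {
        cal <- calibration_params(fmax = pre$fmax, kd = kd)
        ca <- calibrate_fluorescence(pre$fluorescence, cal)
        peak_ca <- peak_in_window(ca, w, "outward")$amplitude
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cell, voltage_mV = v,
        isk_pApF = pk_sk$amplitude / iso$capacitance,
        ica_pApF = pk_ca_cur$amplitude / iso$capacitance,
        peak_ca_uM = peak_ca)
    }
  }
  if (length(unmatched))
    stop("unmatched pre/post pairs:\n  ", paste(unmatched, collapse = "\n  "))
  per_cell <- do.call(rbind, rows)
  agg <- function(col) {
    m <- tapply(per_cell[[col]], per_cell$voltage_mV, mean)
    s <- tapply(per_cell[[col]], per_cell$voltage_mV, stats::sd)
    list(mean = as.numeric(m), sd = as.numeric(s))
  }
  sk <- agg("isk_pApF"); ca_c <- agg("ica_pApF"); pca <- agg("peak_ca_uM")
  out <- data.frame(
    voltage_mV = sort(unique(per_cell$voltage_mV)),
    isk_pApF_mean = sk$mean, isk_pApF_sd = sk$sd,
    ica_pApF_mean = ca_c$mean, ica_pApF_sd = ca_c$sd,
    peak_ca_uM_mean = pca$mean, peak_ca_uM_sd = pca$sd,
    n = as.numeric(tapply(per_cell$isk_pApF, per_cell$voltage_mV, length)))
  attr(out, "per_cell") <- per_cell
  attr(out, "blocker") <- blocker
  attr(out, "pre_condition") <- pre_condition
  class(out) <- c("iv_curve", "data.frame")
  out
}

#' @export
plot.iv_curve <- function(x, ...) {
  graphics::plot(x$voltage_mV, x$isk_pApF_mean, type = "b", pch = 16,
                 xlab = "step potential (mV)",
                 ylab = expression(I[SK] ~ "density (pA/pF)"), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Normalize a current-amplitude time course to a reference time point
#'
#' Rundown/run-up bookkeeping: expresses each amplitude as a percentage of
#' the amplitude measured at `reference_time` (e.g. the inward current 3 min
#' after ISO application taken as 100%).
#'
#' @param times measurement times, minutes.
#' @param amplitudes current amplitudes (pA), same length.
#' @param reference_time the time (must be present in `times`) whose
#'   amplitude defines 100%.
#' @return data.frame of class `rundown_series` with columns `time_min`,
#'   `normalized_pct`; the reference time is attached as an attribute.
#' @export
normalize_rundown <- function(times, amplitudes, reference_time) {
  stopifnot(length(times) == length(amplitudes))
  k <- which(abs(times - reference_time) <= 1e-9)
  if (!length(k))
    stop("reference_time ", reference_time, " not present in `times`")
  ref <- amplitudes[k[1L]]
  if (ref == 0) stop("reference amplitude is zero; cannot normalize")
  out <- data.frame(time_min = times,
                    normalized_pct = 100 * amplitudes / ref)
  attr(out, "reference_time") <- reference_time
  class(out) <- c("rundown_series", "data.frame")
  out
}
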