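# On-disk experiment layout: one JSON sidecar (experiment.json) describing
# every sweep, plus two-column CSV traces (time_ms,value) under traces/.
# Numeric text is written at 17 significant digits so that doubles
# round-trip exactly and a second write of a re-read set is byte-identical.

fmt_num <- function(x) sprintf("%.17g", x)

sanitize_tag <- function(x) gsub("[^A-Za-z0-9]+", "-", x)

trace_filename <- function(s, channel) {
  v <- s$protocol$step_potential
  vtag <- paste0(if (v < 0) "m" else "p", sanitize_tag(fmt_num(abs(v))))
  sprintf("%s_%s_%s_%s.csv", sanitize_tag(s$cell_id),
          sanitize_tag(s$condition), vtag, channel)
}

write_trace_csv <- function(x, path) {
  tt <- ts_time(x)
  con <- file(path, open = "wb")  # binary: LF endings on every platform
  on.exit(close(con))
  writeLines(c("time_ms,value",
               paste(fmt_num(tt), fmt_num(x$values), sep = ",")),
             con, sep = "\n")
  invisible(path)
}

read_trace_csv <- function(path, unit) {
  d <- utils::read.csv(path, colClasses = "numeric")
  if (!identical(names(d), c("time_ms", "value")))
    stop("trace file ", basename(path), " must have header 'time_ms,value'")
  bad <- which(!is.finite(d$value) | !is.finite(d$time_ms))
  if (length(bad))
    stop(sprintf("non-finite sample in %s at row %d", basename(path), bad[1L]))
  if (nrow(d) < 2L) stop("trace file ", basename(path), " has < 2 samples")
  dt <- d$time_ms[2L] - d$time_ms[1L]
  expected <- d$time_ms[1L] + (seq_len(nrow(d)) - 1L) * dt
  if (max(abs(d$time_ms - expected)) > 1e-6 * max(1, abs(dt)))
    stop("non-uniform sampling in ", basename(path),
         "; resample upstream, sksense does not resample silently")
  time_series(d$value, dt = dt, t0 = d$time_ms[1L], unit = unit)
}

sweep_meta <- function(s, i) {
  p <- s$protocol
  list(
    cell_id = s$cell_id,
    condition = s$condition,
    step_potential_mV = p$step_potential,
    holding_potential_mV = p$holding_potential,
    step_onset_ms = p$step_onset,
    step_duration_ms = p$step_duration,
    inter_sweep_interval_ms = p$inter_sweep_interval,
    capacitance_pF = s$capacitance,
    dt_ms = s$current$dt,
    t0_ms = s$current$t0,
    fmax = if (is.na(s$fmax)) NULL else s$fmax,
    f0 = if (is.na(s$f0)) NULL else s$f0,
    current_file = file.path("traces", trace_filename(s, "current")),
    fluorescence_file = if (is.null(s$fluorescence)) NULL else
      file.path("traces", trace_filename(s, "fluor"))
  )
}

#' Write an experiment set to a directory
#'
#' Produces a deterministic, diff-able layout: `experiment.json` (sweep
#' table and acquisition metadata) plus one or two CSV traces per sweep
#' under `traces/`. Numeric text is bit-stable: `read_experiment()` of the
#' result reproduces the set exactly, and writing a re-read set again is
#' byte-identical.
#'
#' @param set an [experiment_set()].
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @seealso [read_experiment()]
#' @export
write_experiment <- function(set, path) {
  stopifnot(inherits(set, "experiment_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory ", path)
  # deterministic order: cell, condition, voltage
  ord <- order(vapply(set$sweeps, function(s) s$cell_id, character(1)),
               vapply(set$sweeps, function(s) s$condition, character(1)),
               vapply(set$sweeps, function(s) s$protocol$step_potential, numeric(1)))
  sweeps <- set$sweeps[ord]
  if (length(sweeps)) {
    dir.create(file.path(path, "traces"), showWarnings = FALSE)
    for (s in sweeps) {
      write_trace_csv(s$current, file.path(path, "traces",
                                           trace_filename(s, "current")))
      if (!is.null(s$fluorescence))
        write_trace_csv(s$fluorescence, file.path(path, "traces",
                                                  trace_filename(s, "fluor")))
    }
  }
  meta <- list(format = "sksense-experiment",
               version = 1L,
               n_sweeps = length(sweeps),
               sweeps = lapply(seq_along(sweeps),
                               function(i) sweep_meta(sweeps[[i]], i)))
  json <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  con <- file(file.path(path, "experiment.json"), open = "wb")
  writeLines(json, con, sep = "\n")
  close(con)
  invisible(path)
}

req_field <- function(m, field, cell) {
  v <- m[[field]]
  if (is.null(v) || (is.numeric(v) && !is.finite(v)))
    stop(sprintf("%s missing for cell_id=%s",
                 sub("_(mV|ms|pF)$", "", field), cell))
  v
}

#' Read an experiment set from a directory
#'
#' Counterpart of [write_experiment()]. Validates metadata (sampling
#' interval, capacitance) and samples (finiteness, uniform sampling);
#' missing fluorescence is tolerated so current-only analyses remain
#' possible.
#'
#' @param path directory containing `experiment.json` and `traces/`.
#' @return an [experiment_set()].
#' @export
read_experiment <- function(path) {
  sidecar <- file.path(path, "experiment.json")
  if (!file.exists(sidecar)) stop("no experiment.json in ", path)
  meta <- jsonlite::fromJSON(sidecar, simplifyVector = FALSE)
  if (!identical(meta$format, "sksense-experiment"))
    stop("not an sksense experiment sidecar: ", sidecar)
  sweeps <- lapply(meta$sweeps, function(m) {
    cell <- if (is.null(m$cell_id)) "<unknown>" else m$cell_id
    cap <- req_field(m, "capacitance_pF", cell)
    dt <- req_field(m, "dt_ms", cell)
    proto <- step_protocol(
      step_potential = req_field(m, "step_potential_mV", cell),
      holding_potential = req_field(m, "holding_potential_mV", cell),
      step_onset = req_field(m, "step_onset_ms", cell),
      step_duration = req_field(m, "step_duration_ms", cell),
      inter_sweep_interval = req_field(m, "inter_sweep_interval_ms", cell))
    cur <- read_trace_csv(file.path(path, m$current_file), unit = "pA")
    if (abs(cur$dt - dt) > 1e-9 * max(1, dt))
      stop(sprintf("contradictory metadata: dt_ms=%g but trace %s sampled at %g ms",
                   dt, basename(m$current_file), cur$dt))
    fl <- if (!is.null(m$fluorescence_file))
      read_trace_csv(file.path(path, m$fluorescence_file), unit = "a.u.")
    vc_sweep(current = cur, fluorescence = fl, protocol = proto,
          capacitance = cap, condition = m$condition, cell_id = cell,
          fmax = if (is.null(m$fmax)) NA_real_ else m$fmax,
          f0 = if (is.null(m$f0)) NA_real_ else m$f0)
  })
  experiment_set(sweeps)
}
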