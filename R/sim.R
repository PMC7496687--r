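# Mechanistic simulator of biphasic SK gating and full synthetic
# voltage-clamp experiments.
#
# Open probability: a Hill activation arm (CaM-mediated, EC50 ~0.46 uM,
# h ~2.6) multiplied by a voltage-dependent inhibition arm with
# IC50(V) = phospho_factor * ic50_ref * exp(-(V - v_ref)/slope_mV),
# ic50_ref ~20 uM at the holding potential. PKA phosphorylation acts purely
# as multiplicative relief of inhibition (phospho_factor on the IC50), never
# on the activation arm. Within a simulated sweep the inhibition is
# absorbing: it is evaluated at the running peak of submembrane calcium, so
# the current inactivates during the transient and does not re-activate as
# calcium decays back through the activation optimum (matching recorded
# I_SK trace shapes).

#' Biphasic SK gating parameters
#'
#' @param ec50_act half-activation calcium, uM (default 0.46).
#' @param h_act activation Hill coefficient (default 2.6).
#' @param ic50_ref inhibition IC50 at `v_ref` for the unphosphorylated
#'   channel, uM (default 20).
#' @param v_ref reference potential of the inhibition arm, mV (default -40,
#'   the holding potential).
#' @param slope_mV e-fold IC50 decrease per mV of depolarization (default
#'   18 mV; chosen so that the simulated I-V rectifies with a peak near
#'   -10 mV and negligible current at +30..+40 mV despite similar
#'   submembrane calcium, the observed native pattern).
#' @param h_inh inhibition Hill coefficient (default 2).
#' @param g_total lumped maximal SK conductance N*g, nS (default 5).
#' @param e_k K+ reversal potential, mV (default -83.7, Nernst for 5.4 mM
#'   external / 140 mM internal K+).
#' @param phospho_factor multiplicative relief of inhibition, >= 1
#'   (1 = unphosphorylated; larger values emulate PKA phosphorylation /
#'   the S465D phosphomimetic).
#' @return object of class `gating_params`.
#' @export
gating_params <- function(ec50_act = 0.46, h_act = 2.6, ic50_ref = 20,
                          v_ref = -40, slope_mV = 18, h_inh = 2,
                          g_total = 5, e_k = -83.7, phospho_factor = 1) {
  stopifnot(ec50_act > 0, h_act > 0, ic50_ref > 0, slope_mV > 0,
            h_inh > 0, g_total >= 0, phospho_factor >= 1)
  structure(list(ec50_act = ec50_act, h_act = h_act, ic50_ref = ic50_ref,
                 v_ref = v_ref, slope_mV = slope_mV, h_inh = h_inh,
                 g_total = g_total, e_k = e_k,
                 phospho_factor = phospho_factor),
            class = "gating_params")
}

sk_activation <- function(ca, g) {
  ca^g$h_act / (ca^g$h_act + g$ec50_act^g$h_act)
}

sk_ic50 <- function(v, g) {
  g$phospho_factor * g$ic50_ref * exp(-(v - g$v_ref) / g$slope_mV)
}

sk_inhibition <- function(ca, v, g) {
  1 / (1 + (ca / sk_ic50(v, g))^g$h_inh)
}

#' Steady-state SK open probability (biphasic in calcium)
#'
#' `Po(ca, v) = [ca^h / (ca^h + EC50^h)] * [1 / (1 + (ca/IC50(v))^h_inh)]`
#' with `IC50(v) = phospho_factor * ic50_ref * exp(-(v - v_ref)/slope_mV)`.
#' Po is 0 at zero calcium, rises to a maximum in the low-micromolar range
#' and falls again at tens of micromolar, the more steeply the more
#' depolarized the membrane; phosphorylation shifts the descending limb to
#' higher calcium without touching the ascending one.
#'
#' @param ca calcium, uM (vectorized, >= 0).
#' @param v membrane potential, mV.
#' @param g [gating_params()].
#' @return open probability in `[0, 1]`.
#' @export
open_probability <- function(ca, v, g = gating_params()) {
  stopifnot(inherits(g, "gating_params"))
  if (any(ca < 0)) stop("calcium must be non-negative")
  sk_activation(ca, g) * sk_inhibition(ca, v, g)
}

#' Ca2+ transient parameters for the simulator
#'
#' The bulk transient is
#' `ca_i(t') = resting + A(V) * (1 - exp(-t'/tau_rise))^2 * exp(-t'/tau_decay)`
#' (t' from step onset); the squared-rise gives the sigmoidal upstroke of
#' CICR so the derivative (and hence submembrane calcium) peaks a few
#' milliseconds into the transient rather than instantaneously. The
#' voltage dependence of the amplitude is a bell centred near 0 mV,
#' mimicking the L-type Ca2+ current.
#'
#' @param resting_ca diastolic calcium, uM.
#' @param amp_max peak bulk amplitude at the bell centre, uM.
#' @param amp_center,amp_width bell centre and SD, mV.
#' @param tau_rise,tau_decay rise/decay time constants, ms.
#' @param gamma diffusion constant (ms) used for the ground-truth
#'   submembrane trace.
#' @param amp_of_v optional function(v) -> uM overriding the bell.
#' @return object of class `transient_params`.
#' @export
transient_params <- function(resting_ca = 0.1, amp_max = 1.2,
                             amp_center = 0, amp_width = 30,
                             tau_rise = 15, tau_decay = 200,
                             gamma = 110, amp_of_v = NULL) {
  stopifnot(resting_ca >= 0, amp_max >= 0, tau_rise > 0, tau_decay > 0,
            gamma >= 0)
  if (is.null(amp_of_v))
    amp_of_v <- function(v)
      amp_max * exp(-((v - amp_center)^2) / (2 * amp_width^2))
  structure(list(resting_ca = resting_ca, amp_max = amp_max,
                 amp_center = amp_center, amp_width = amp_width,
                 tau_rise = tau_rise, tau_decay = tau_decay, gamma = gamma,
                 amp_of_v = amp_of_v),
            class = "transient_params")
}

#' Phenomenological L-type Ca2+ current surrogate
#'
#' `I_Ca(t') = g_ca * act(V) * exp(-t'/tau_inact) * (V - e_ca)` during the
#' step, with a Boltzmann activation gate. Stands in for the residual
#' (post-blocker) inward current; no kinetic Ca-dependent inactivation.
#'
#' @param g_ca maximal conductance, nS.
#' @param e_ca apparent reversal potential, mV.
#' @param act_midpoint,act_slope Boltzmann activation midpoint and slope, mV.
#' @param tau_inact inactivation time constant, ms.
#' @return object of class `ica_params`.
#' @export
ica_params <- function(g_ca = 10, e_ca = 60, act_midpoint = -10,
                       act_slope = 6, tau_inact = 30) {
  stopifnot(tau_inact > 0, g_ca >= 0, act_slope > 0)
  structure(list(g_ca = g_ca, e_ca = e_ca, act_midpoint = act_midpoint,
                 act_slope = act_slope, tau_inact = tau_inact),
            class = "ica_params")
}

#' Measurement-noise parameters
#'
#' @param sigma_current additive Gaussian current noise SD, pA.
#' @param sigma_fluor_frac multiplicative Gaussian fluorescence noise SD
#'   (fraction of the signal).
#' @param seed integer seed for the sweep; `NULL` leaves the RNG state
#'   untouched.
#' @return object of class `noise_params`.
#' @export
noise_params <- function(sigma_current = 5, sigma_fluor_frac = 0.02,
                         seed = NULL) {
  stopifnot(sigma_current >= 0, sigma_fluor_frac >= 0)
  structure(list(sigma_current = sigma_current,
                 sigma_fluor_frac = sigma_fluor_frac, seed = seed),
            class = "noise_params")
}

# analytic transient and its time derivative (t' >= 0, from onset)
transient_ca <- function(tp_ms, A, p) {
  p$resting_ca + A * (1 - exp(-tp_ms / p$tau_rise))^2 * exp(-tp_ms / p$tau_decay)
}
transient_dca <- function(tp_ms, A, p) {
  e_r <- exp(-tp_ms / p$tau_rise)
  e_d <- exp(-tp_ms / p$tau_decay)
  A * (1 - e_r) * e_d * (2 * e_r / p$tau_rise - (1 - e_r) / p$tau_decay)
}

#' Simulate one voltage-clamp sweep
#'
#' Generates the bulk Ca2+ transient analytically, derives the ground-truth
#' submembrane calcium as `ca_i + gamma * max(0, d ca_i/dt)` (the gradient
#' term exists only while calcium flows in; during the decay submembrane
#' equals bulk), computes `I_SK = g_total * act(ca_sm) * inh(running max
#' ca_sm, V) * (V - e_k)` with absorbing inhibition, adds the I_Ca
#' surrogate, Gaussian current noise, and synthesizes fluorescence by
#' inverting the calibration with multiplicative noise. All ground-truth
#' channels are retained in the sweep's `truth` field.
#'
#' @param protocol [step_protocol()].
#' @param tp [transient_params()].
#' @param g [gating_params()].
#' @param ica [ica_params()].
#' @param noise [noise_params()]; its `seed` (if non-NULL) seeds the RNG.
#' @param with_sk include the SK conductance (FALSE emulates a
#'   fully-blocked, post-apamin sweep).
#' @param capacitance cell capacitance, pF.
#' @param cell_id,condition sweep metadata tags.
#' @param calib [calibration_params()] used to synthesize fluorescence.
#' @param dt sampling interval, ms (default 0.2 ms = 5 kHz).
#' @param tail_ms recording continued after the step end, ms.
#' @return a [sweep()] with `truth = list(i_sk, i_ca, ca_i, ca_sm)` (all
#'   [time_series()]).
#' @export
simulate_sweep <- function(protocol, tp = transient_params(),
                           g = gating_params(), ica = ica_params(),
                           noise = noise_params(), with_sk = TRUE,
                           capacitance = 100, cell_id = "cell01",
                           condition = "baseline",
                           calib = calibration_params(fmax = 10),
                           dt = 0.2, tail_ms = 80) {
  stopifnot(inherits(protocol, "step_protocol"),
            inherits(tp, "transient_params"), inherits(g, "gating_params"),
            inherits(ica, "ica_params"), inherits(noise, "noise_params"))
  if (!is.null(noise$seed)) set.seed(noise$seed)
  onset <- protocol$step_onset
  t_end_step <- onset + protocol$step_duration
  tt <- seq(0, t_end_step + tail_ms, by = dt)
  tp_ms <- pmax(0, tt - onset)
  A <- tp$amp_of_v(protocol$step_potential)
  in_step <- tt >= onset & tt < t_end_step
  v_t <- ifelse(in_step, protocol$step_potential, protocol$holding_potential)

  ca_i <- ifelse(tt >= onset, transient_ca(tp_ms, A, tp), tp$resting_ca)
  dca <- ifelse(tt >= onset, transient_dca(tp_ms, A, tp), 0)
  ca_sm <- ca_i + tp$gamma * pmax(0, dca)

  i_sk <- if (with_sk) {
    g$g_total * sk_activation(ca_sm, g) *
      sk_inhibition(cummax(ca_sm), v_t, g) * (v_t - g$e_k)
  } else rep(0, length(tt))
  act_gate <- 1 / (1 + exp(-(protocol$step_potential - ica$act_midpoint) /
                             ica$act_slope))
  i_ca <- ifelse(in_step,
                 ica$g_ca * act_gate * exp(-tp_ms / ica$tau_inact) *
                   (protocol$step_potential - ica$e_ca),
                 0)

  current <- i_sk + i_ca
  if (noise$sigma_current > 0)
    current <- current + stats::rnorm(length(tt), 0, noise$sigma_current)
  fl <- inverse_calibrate(time_series(ca_i, dt, 0, "uM"), calib)$values
  if (noise$sigma_fluor_frac > 0)
    fl <- fl * (1 + stats::rnorm(length(tt), 0, noise$sigma_fluor_frac))
  fl <- pmin(pmax(fl, calib$fmin * 1e-3), calib$fmax * (1 - 1e-9))

  vc_sweep(current = time_series(current, dt, 0, "pA"),
        fluorescence = time_series(fl, dt, 0, "a.u."),
        protocol = protocol, capacitance = capacitance,
        condition = condition, cell_id = cell_id,
        fmax = calib$fmax,
        f0 = (calib$fmax * tp$resting_ca + calib$kd * calib$fmin) /
          (tp$resting_ca + calib$kd),
        truth = list(i_sk = time_series(i_sk, dt, 0, "pA"),
                     i_ca = time_series(i_ca, dt, 0, "pA"),
                     ca_i = time_series(ca_i, dt, 0, "uM"),
                     ca_sm = time_series(ca_sm, dt, 0, "uM")))
}

#' Parameter presets for the simulated experimental groups
#'
#' * `"tab-baseline"`: hypertrophic (TAB) myocyte under basal conditions —
#'   full conductance with modest basal PKA phosphorylation
#'   (`phospho_factor` 1.3), giving a rectifying I-V with a peak near
#'   -10..0 mV.
#' * `"sham-baseline"`: healthy myocyte — tiny functional conductance
#'   (dormant channels), unphosphorylated.
#' * `"sham-iso"` / `"tab-iso"`: convenience presets with the ISO condition
#'   already applied (see [simulate_experiment()] conditions).
#' * `"overexpress"`: cultured myocyte overexpressing SK2 (holding -45 mV,
#'   large conductance); its ISO response models the complete relief of
#'   rectification seen with strong PKA activation (`iso_phospho = 100`).
#'
#' @param name preset name.
#' @return list with elements `gating`, `transient`, `ica`, `capacitance`,
#'   `holding`, `iso_phospho` (phospho_factor applied by the ISO
#'   condition), `iso_scale` (I_Ca / transient amplitude multiplier under
#'   ISO), `iso_g_total` (conductance under ISO, modelling functional
#'   recruitment).
#' @export
preset_params <- function(name = c("tab-baseline", "tab-iso",
                                   "sham-baseline", "sham-iso",
                                   "overexpress")) {
  name <- match.arg(name)
  base <- list(transient = transient_params(), ica = ica_params(),
               capacitance = 100, holding = -40,
               iso_phospho = 5, iso_scale = 1.5)
  out <- switch(name,
    "tab-baseline" = ,
    "tab-iso" = c(base, list(gating = gating_params(g_total = 5,
                                                    phospho_factor = 1.3),
                             iso_g_total = 5)),
    "sham-baseline" = ,
    "sham-iso" = c(base, list(gating = gating_params(g_total = 0.5),
                              iso_g_total = 5)),
    "overexpress" = {
      b <- base
      b$holding <- -45
      b$iso_phospho <- 100
      c(b, list(gating = gating_params(g_total = 25), iso_g_total = 25))
    })
  out$preset <- name
  if (name %in% c("tab-iso", "sham-iso")) out$force_condition <- "ISO"
  out
}

# apply a condition tag to a preset bundle
condition_params <- function(params, condition) {
  g <- params$gating
  tp <- params$transient
  ica <- params$ica
  if (condition == "ISO") {
    g$phospho_factor <- params$iso_phospho
    g$g_total <- params$iso_g_total
    amp_fun <- tp$amp_of_v
    scale <- params$iso_scale
    tp$amp_of_v <- function(v) scale * amp_fun(v)
    ica$g_ca <- ica$g_ca * scale
  } else if (condition == "PKI") {
    g$phospho_factor <- 1
  } else if (condition != "baseline") {
    stop("unknown condition '", condition,
         "' (use baseline, ISO or PKI)")
  }
  list(gating = g, transient = tp, ica = ica)
}

#' Deterministic per-sweep seed from a master seed
#'
#' Splitting rule: starting from `master %% (2^31 - 1)`, fold in each
#' character of `paste(cell, condition, voltage, role)` as
#' `s <- (31 * s + utf8(char)) %% (2^31 - 1)`. Stated here so simulated
#' experiments are exactly reproducible sweep-by-sweep.
#'
#' @param master master integer seed.
#' @param cell_id,condition,step_potential,role sweep coordinates (role is
#'   `"pre"` or `"post"`).
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
sweep_seed <- function(master, cell_id, condition, step_potential, role) {
  m <- 2147483647
  s <- as.numeric(master) %% m
  key <- paste(cell_id, condition, format(step_potential), role, sep = "|")
  for (code in utf8ToInt(key)) s <- (31 * s + code) %% m
  as.integer(s)
}

#' Simulate a full pre/post-blocker voltage-clamp experiment
#'
#' For every (cell, condition, voltage) combination generates a pre-blocker
#' sweep (SK conductance on) and a matching post-blocker sweep (SK off),
#' tagged `"<condition>+<blocker>"` (just `"<blocker>"` for baseline), each
#' with a fresh deterministic seed from [sweep_seed()]. Conditions modify
#' the preset: `"baseline"` uses it as-is (for the TAB preset this includes
#' basal phosphorylation), `"ISO"` applies `iso_phospho`, `iso_g_total` and
#' scales I_Ca and transient amplitudes by `iso_scale`, `"PKI"` clamps
#' `phospho_factor` to 1.
#'
#' @param voltages step potentials, mV, within `[-80, +60]`.
#' @param conditions subset of `c("baseline", "ISO", "PKI")`.
#' @param params preset bundle from [preset_params()] (or a hand-built list
#'   with the same fields).
#' @param noise [noise_params()]; per-sweep seeds are derived from `seed`,
#'   overriding `noise$seed`.
#' @param seed master seed.
#' @param cells character vector of cell ids.
#' @param blocker blocker tag for the post sweeps.
#' @param dt sampling interval, ms.
#' @param step_duration step length, ms; lengthen it when the analysis
#'   needs the transient to decay through a wider calcium range (e.g. the
#'   sensitivity ramp of a high-affinity mutant).
#' @return an [experiment_set()] with `2 * length(voltages) *
#'   length(conditions) * length(cells)` sweeps.
#' @export
simulate_experiment <- function(voltages, conditions = c("baseline", "ISO"),
                                params = preset_params("tab-baseline"),
                                noise = noise_params(), seed = 1,
                                cells = "cell01", blocker = "APA",
                                dt = 0.2, step_duration = 400) {
  if (any(voltages < -80 | voltages > 60))
    stop("voltages must lie within [-80, +60] mV")
  if (!is.null(params$force_condition)) conditions <- params$force_condition
  sweeps <- list()
  for (cell in cells) {
    for (cond in conditions) {
      cp <- condition_params(params, cond)
      post_tag <- if (cond == "baseline") blocker else
        paste(cond, blocker, sep = "+")
      for (v in voltages) {
        proto <- step_protocol(step_potential = v,
                               holding_potential = params$holding,
                               step_duration = step_duration)
        for (role in c("pre", "post")) {
          ns <- noise
          ns$seed <- sweep_seed(seed, cell, cond, v, role)
          sweeps[[length(sweeps) + 1L]] <- simulate_sweep(
            proto, tp = cp$transient, g = cp$gating, ica = cp$ica,
            noise = ns, with_sk = (role == "pre"),
            capacitance = params$capacitance, cell_id = cell,
            condition = if (role == "pre") cond else post_tag, dt = dt)
        }
      }
    }
  }
  experiment_set(sweeps)
}
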