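---
title: "Biphasic SK gating: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biphasic SK gating: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sksense)
```

## The problem

Small-conductance Ca²⁺-activated K⁺ (SK) channels in ventricular myocytes
have no voltage sensor: their gate is controlled by intracellular Ca²⁺, and
in a biphasic way. Submicromolar Ca²⁺ activates the channel through
constitutively bound calmodulin (EC₅₀ in the 0.3–1 µM range), while tens of
micromolar Ca²⁺ — concentrations that submembrane microdomains reach during
the Ca²⁺ transient — inhibit it, the more strongly the more depolarized the
membrane. The interplay produces the hallmark *rectification* of the
SK current (I_SK): its current–voltage relation peaks around −20 to −10 mV
and collapses at positive potentials even though Ca²⁺ transients keep
growing. PKA phosphorylation of the channel relieves the inhibitory arm
without touching the activating one, which converts dormant channels into a
functional repolarizing current.

`sksense` implements the complete desk-side analysis around this biology:

* single-wavelength fluorescence → [Ca²⁺]ᵢ calibration and submembrane
  [Ca²⁺] reconstruction (`calibrate_fluorescence()`,
  `reconstruct_submembrane()`),
* blocker-subtraction isolation of I_SK and I–V assembly
  (`isolate_isk()`, `build_iv()`),
* the in-situ Ca²⁺-sensitivity assay on transient decay ramps
  (`extract_ramp()`, `fit_hill()`, `isk_ramp_assay()`),
* optical-map repolarization metrics (`apd_map()`,
  `conduction_velocity()`),
* a mass-action free-ion solver for pipette recipes (`free_ion()`),
* and a mechanistic simulator (`simulate_sweep()`,
  `simulate_experiment()`) that generates complete synthetic experiments
  with recorded ground truth, so that every estimator above can be
  validated without any recorded data.

## Calibration and submembrane reconstruction

Fluorescence of a single-wavelength indicator (Rhod-2) converts to calcium
by the hyperbola

$$[\mathrm{Ca}^{2+}]_i = K_d\,\frac{F - F_{min}}{F_{max} - F},$$

with `kd = 1.58` µM (the in-cell value for Rhod-2) and `fmin = fmax/15` as
defaults; `fmax` is a per-cell anchor measured by saturating the dye.
Samples at or above `Fmax` are a hard error (the hyperbola diverges);
samples below `Fmin` — noise excursions — clip to 0 µM with a warning,
because negative concentrations are unphysical. When the baseline drifts,
traces pre-normalized to F/F₀ use the same algebra (`mode = "F_over_F0"`).

Submembrane calcium is reconstructed from the bulk transient as

$$[\mathrm{Ca}^{2+}]_{sm} = [\mathrm{Ca}^{2+}]_i +
\gamma\,\frac{d[\mathrm{Ca}^{2+}]_i}{dt},$$

with the diffusion constant `gamma = 110` ms. Numerical choices, all
exposed as parameters of `submembrane_params()`:

* the derivative is taken on a Savitzky–Golay-smoothed copy of the trace
  (window 5 samples, polynomial order 2 — the standard order for a 5-point
  window) by central differences, one-sided at the edges;
* the derivative term is trusted only up to the reconstructed peak. Beyond
  it the gradient has collapsed and differentiating the decay would
  *understate* submembrane calcium, so the trace is continued as a single
  exponential that follows the decay of the bulk transient
  (`fit_single_exponential()` on [Ca²⁺]ᵢ from its own peak supplies τ and
  baseline; the amplitude is anchored at the reconstructed peak for
  continuity);
* a constant input trace is returned unchanged (the γ-term vanishes
  identically), with no decay fit;
* negative reconstructed samples clip to 0 µM with a warning.

Closed forms used as test oracles: an exponential input
$A e^{-t/\tau}$ gives a pre-splice reconstruction
$A(1-\gamma/\tau)e^{-t/\tau}$, and a linear segment of slope $m$ is offset
by exactly $\gamma m$.

## Isolating I_SK

I_SK is defined operationally: the current removed by a selective SK
blocker (apamin, UCL-1684). `isolate_isk()` subtracts the post-blocker
trace sample-by-sample from the pre-blocker trace of the same cell and
protocol, and refuses to subtract anything misaligned — no temporal
realignment, no filtering. A misaligned protocol should fail loudly rather
than generate silent subtraction artefacts. The residual post-blocker
trace is carried along as the I_Ca-plus-leak component; leak is not
modelled separately.

`build_iv()` measures, per voltage: the peak outward I_SK density and peak
inward residual density (pA/pF) within the step window, and the peak
calibrated calcium, pooling over cells as mean ± SD. Peak search uses the
step window `[onset, onset + duration]`, where the SK conductance is
driven; ties resolve to the earliest sample.

## The in-situ Ca²⁺-sensitivity assay

The decay of the Ca²⁺ transient is a slow intracellular calcium ramp.
During that phase bulk and submembrane calcium agree (the gradient term has
died out) and the L-type current has inactivated, so pairing the decaying
I_SK with the decaying calibrated [Ca²⁺]ᵢ traces out the channel's
activation curve in situ. The pairs are fitted with the Hill equation

$$I/I_{max} = \frac{1}{1 + (EC_{50}/[\mathrm{Ca}^{2+}])^h},$$

by unweighted least squares in linear concentration space, multistart
initialization over EC₅₀ ∈ {0.2, 0.5, 1.0} µM × h ∈ {1, 2, 4} (best RMSE
wins), with at least 8 points spanning a ≥3-fold calcium range required.

Estimator design decisions, each of which we validated on simulated ground
truth:

* **Ramp window.** Pairs start at the *later* of the I_SK peak and the
  bulk-calcium peak. Starting at the current peak alone would pair early
  currents — driven by submembrane calcium — with bulk calcium the channel
  does not yet see, planting a large off-curve point in the fit.
* **Monotone cleanup.** Points where calcium rises relative to the running
  minimum are dropped, never smoothed: smoothing would re-pair samples.
* **Normalization and the plateau.** The convention for I_max is the peak
  I_SK of the same cell under β-adrenergic stimulation. Because the ramp
  begins after the current peak, the measured curve tops out *below*
  I_max; `isk_ramp_assay()` therefore frees the plateau
  ($A/(1+(EC_{50}/c)^h)$, `fit_hill(..., fit_amplitude = TRUE)`), which
  decouples the recovered (EC₅₀, h) from errors in the I_max estimate. On
  noisy traces this matters a great deal: the raw maximum of a noisy trace
  overestimates I_max by roughly $\sigma\sqrt{2\ln n}$, and with a fixed
  unit plateau that bias propagates about two-fold into h. The fixed-
  plateau model of the literature remains the `fit_hill()` default.
* **Smoothing.** The calibrated calcium is smoothed with the same 5-point
  Savitzky–Golay filter used throughout before pairing, and I_SK
  likewise; with 2% multiplicative fluorescence noise the asymmetric
  survival of downward calcium excursions through the monotone cleanup
  otherwise biases EC₅₀ low.
* **Assay conditions.** The activation-only model is exact only where the
  inhibitory arm is quiescent over the ramp's calcium range. In the
  simulator this holds under strong PKA relief (the overexpression preset
  under ISO); under basal inhibition the descending arm contaminates the
  ramp and the apparent (EC₅₀, h) are structurally biased. This mirrors
  the experimental design, which normalizes to the ISO peak and fits
  decay-phase data where inhibition is assumed negligible.

Timing metrics (`timing_metrics()`) quantify the biphasic signature
directly: time-to-peak of I_SK versus submembrane calcium from the step
onset, and the submembrane calcium read at the I_SK peak.

The inhibitory arm is estimated separately (`fit_inhibition()`) from the
descending limb of the open-probability curve at fixed voltage, with a free
amplitude absorbing the (nearly saturated) activation term.

## The biphasic gating model and simulator

Open probability is modelled as activation × inhibition:

$$P_o(c, V) = \frac{c^{h_a}}{c^{h_a} + EC_{50a}^{h_a}} \cdot
\frac{1}{1 + \left(c/IC_{50}(V)\right)^{h_i}}, \qquad
IC_{50}(V) = \phi\, IC_{50}^{ref}\, e^{-(V - V_{ref})/s}.$$

Defaults (all in `gating_params()`): EC₅₀ₐ = 0.46 µM, hₐ = 2.6 (wild-type
in-situ values), IC₅₀ref = 20 µM at V_ref = −40 mV, hᵢ = 2, g_total = 5 nS,
E_K = −83.7 mV (Nernst for 5.4 mM/140 mM K⁺), φ (`phospho_factor`) ≥ 1.
PKA phosphorylation enters *only* as multiplicative relief φ of the
inhibition — never as a change in EC₅₀ₐ — which is the mechanistic claim
the simulator exists to express.

Two modelling choices deserve explanation because the observable I–V and
trace shapes forced them:

* **Voltage steepness of inhibition, `slope_mV = 18`.** The literature
  constrains only the IC₅₀ scale (~20 µM) and the fact of voltage
  dependence; the e-fold slope is free. It is, however, pinned by two
  observations at once: submembrane calcium of similar amplitude drives a
  large I_SK at −10 mV but almost none at +30 mV, and the I–V peak sits
  in the −20…0 mV range. A shallow slope (e-fold per 40 mV or more)
  cannot produce either — the driving force grows faster with voltage
  than the attainable peak P₀ declines, and the simulated I–V becomes
  monotone. An e-fold per ~18 mV reproduces the rectifying shape with a
  peak near −10…0 mV and I(+40 mV) below half of the maximum.
* **Absorbing inhibition within a sweep.** A purely instantaneous
  biphasic P₀(c) predicts that as calcium decays back through the
  activation optimum late in the step, the current should re-activate to
  its earlier peak — a second hump that recorded traces do not show:
  I_SK inactivates during the transient and stays inactivated. The
  simulator therefore evaluates the inhibition term at the *running
  maximum* of submembrane calcium within the sweep (activation stays
  instantaneous). On the rising phase this is identical to the
  memoryless model — the running maximum is the current value — so peak
  currents and the I–V are unchanged; after the calcium peak it freezes
  the inhibition at its deepest level, reproducing the observed
  monophasic decay. It also makes the decay-phase ramp exactly
  proportional to the activation curve, which is what the in-situ assay
  assumes. `open_probability()` itself remains the memoryless curve.

The Ca²⁺ transient is phenomenological
(`transient_params()`): resting 0.1 µM plus
$A(V)\,(1-e^{-t/\tau_r})^2 e^{-t/\tau_d}$ with τ_r = 15 ms, τ_d = 200 ms
and a bell-shaped $A(V)$ (1.2 µM at 0 mV, SD 30 mV) mimicking the L-type
voltage dependence. The squared rise makes the upstroke sigmoidal, as CICR
recruitment does, so the derivative — and with it ground-truth submembrane
calcium, $c_i + \gamma\,(dc_i/dt)_+$ — peaks a few milliseconds into the
transient rather than instantaneously; the positive part encodes that the
standing gradient exists only while calcium flows in, and during the decay
submembrane equals bulk. With these numbers, submembrane calcium at −10 mV
under β-adrenergic amplitudes reaches several µM to ~10 µM, the range in
which the inhibition arm bites. The I_Ca surrogate (`ica_params()`) is a
Boltzmann-gated, mono-exponentially inactivating inward current
(g = 10 nS, midpoint −10 mV, slope 6 mV, τ = 30 ms, E_Ca = +60 mV) that
exists to make the residual trace realistic; it carries no Ca²⁺-dependent
kinetics.

Noise is additive Gaussian on current (default 5 pA) and multiplicative
Gaussian on fluorescence (default 2%); fluorescence is synthesized by the
exact algebraic inverse of the calibration, so the calibration stage of the
pipeline is exercised nontrivially. Every sweep gets its own deterministic
seed derived from (master seed, cell, condition, voltage, role) by a stated
folding rule (`sweep_seed()`).

Presets (`preset_params()`) encode the experimental groups: the
hypertrophic baseline carries modest basal phosphorylation (φ = 1.3) on the
full conductance — diseased cells show I_SK without agonist; the healthy
baseline is dormant through a small functional conductance (0.5 nS); the
ISO condition applies φ = 5 with 1.5× Ca²⁺ transients and I_Ca, and on the
healthy preset also restores the conductance, a lumped stand-in for
functional recruitment. The cultured-overexpression preset (holding
−45 mV, 25 nS) models β-adrenergic stimulation as complete relief
(φ = 100), matching the complete loss of rectification seen in that
system; it is the preset under which the sensitivity assay is validated.

What the generator deliberately does **not** emulate: SR release and RyR2
flux, NCX, dyadic microdomains, stochastic channel gating, series-
resistance and junction-potential artefacts, rundown, motion artefacts,
and line-scan spatial structure (fluorescence is the already-averaged
profile, sampled on the electrical time base). Tests passing on this
generator therefore validate the *estimators* — their algebra, windowing,
normalization and noise behaviour — not the biology of real recordings.

## Optical-map metrics

Activation is the time of maximal dF/dt (central differences, earliest tie,
refined to sub-frame precision by quadratic interpolation of the derivative
peak); APD at level L runs from activation to the first post-peak crossing
of peak − L%·amplitude, with the crossing linearly interpolated between
frames — at 2000 frames/s the 0.5 ms frames would otherwise quantize APD.
Amplitude is measured against the median pre-upstroke baseline. Pixels are
masked when their amplitude fails a 5× baseline-SD signal-to-noise rule
(noise-free synthetic movies only require positive amplitude), and an
optional 3×3 spatial mean filter is off by default. Conduction velocity
comes from a single global plane fit to activation times, CV = 1/‖∇t‖
converted through the pixel pitch (0.15 mm, i.e. a 1.5 cm field over 100
pixels); the plane-fit RMSE flags curved (e.g. radial) wavefronts, and a
wavefront with no net gradient is refused. A fractional-change dye signal
that deflects downward on depolarization is handled by the `polarity`
flag. Oracles: a plane wave at 0.15 mm/ms is 15 cm/s exactly; exponential
repolarization with τ = 50 ms has APD75 = 50·ln 4 ≈ 69.3 ms and
APD90 = 50·ln 10 ≈ 115.1 ms.

## Free-ion solver

`free_ion()` solves the coupled 1:1 mass-action equilibria of cations (Mg,
Ca) against ligands (ATP, GTP, EGTA, indicator) with apparent association
constants, by Gauss–Seidel over cations with each cation's scalar
conservation equation solved exactly by `uniroot` (the equation is
monotone, so bracketing on [0, total] is safe), to a mass-balance residual
of 10⁻¹² mM. The shipped constant set is proton-corrected to pH 7.2 from
critical-stability-constant compilations, with a provenance note per
constant. Published compilations and ionic-strength corrections disagree at
the tens-of-percent level, and the constant set behind any particular
published free-ion figure is rarely stated; the package's tests therefore
hold the solver to the exact bisection oracle and to conservation/
monotonicity invariants, and to the conventional pipette-recipe figure
(free Mg²⁺ ≈ 1.37 mM from 6 mM total Mg against 5 mM ATP + 0.1 mM GTP +
0.1 mM Rhod-2) within the 10% the constant-set uncertainty warrants. Users
matching a specific calculator should supply its constants via
`binding_table()`.

## Validation scale and limitations

The test suite validates estimators at desk scale: sensitivity recovery
uses single-cell synthetic experiments at 5 kHz (noiseless) and 2 kHz with
100 noise seeds (medians within 5%); I–V and timing properties use
9-voltage experiments at 1–2 kHz; map metrics use 25–40 pixel square
movies. These sizes were chosen so the full suite runs in well under a
minute while leaving every estimator's bias measurably below its test
tolerance.

Known limitations: the inhibition arm's voltage dependence (functional
form and slope) is an assumption constrained only by the qualitative I–V
shape; `phospho_factor` is a free lumped parameter with no calibration in
µM-IC₅₀ terms; the sensitivity assay is only as good as its
inhibition-quiescence assumption, and applying it to basal (unrelieved)
conditions yields apparent, not intrinsic, activation parameters; the
submembrane reconstruction ties the decay to the bulk transient by
construction, so decay-phase submembrane kinetics are not independently
estimated; and pooled I–V statistics are mean ± SD only — hypothesis
testing is left to standard tools.
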