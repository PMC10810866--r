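---
title: "Models and methods behind ripplekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ripplekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ripplekit studies how sharp wave-ripples (SPW-Rs) emerge in the developing
hippocampal CA1 area, from two directions at once: a spiking network model
that asks *what level of inhibition a CA1-like circuit needs before it can
generate ripple-frequency oscillations*, and an analysis pipeline that
detects and quantifies SPWs, ripples and event-locked spiking in
extracellular recordings. A ground-truthed synthetic-recording generator
ties the two together so that every stage of the pipeline is testable
without access to raw data.

This vignette documents the models, the tunable parameters and the numerical
choices. Nothing here states an empirical result that the package's tests or
acceptance script do not themselves compute.

## 1. The CA1 network model

### Populations and connectivity

The model is a two-population leaky integrate-and-fire (LIF) network
representing a 0.4 mm slice of CA1 (4% of the hippocampal volume): 12,000
pyramidal cells (E) and 200 parvalbumin-positive basket cells (I), the 60:1
anatomical ratio. Neurons are connected randomly and independently with
class-specific probabilities `p_EE = 0.0164`, `p_IE = 0.1`, `p_EI = 0.1`,
`p_II = 0.2` (first subscript = target). Self-connections and duplicate
edges are excluded; per source, the out-degree is Binomial and targets are
sampled without replacement, which is exactly the per-pair Bernoulli scheme.

### Dynamics

Each neuron follows

$$C \frac{dV}{dt} = g_L (E_L - V) + g_A(t)(E_{AMPA} - V) +
  g_G(t)(E_{GABA} - V) + I_{ext}(t) + \sigma_w \sqrt{C/g_L}\,\xi(t)$$

with threshold-reset spiking and an absolute refractory period. Synaptic
conductances are biexponential, $g(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}$,
normalized so the maximum equals the stated peak conductance — this
normalization is what makes the inhibitory multipliers well defined:
`c_gei` scales the I-to-E peak conductance and `c_gii` the I-to-I one, with
1 denoting the adult configuration.

The membrane noise is additive white noise on the voltage whose amplitude is
derived from the Ornstein-Uhlenbeck stationary variance so that, with
synapses silent, the stationary voltage SD equals `sigma_noise_mV` (default
5 mV; at this level the network spikes spontaneously without external
input). Integration is Euler-Maruyama at dt = 0.1 ms; voltages start from a
Gaussian around rest with SD 0.1 mV. The integrator is compiled (Rcpp) and
uses R's RNG, so a simulation is a pure function of `(params, seed)`.

### External drive and LFP proxy

To mimic the incoming CA3 excitation that rides under an SPW, a random 20%
of E cells receive a Gaussian current pulse (SD 10 ms, amplitude 900 pA)
whose per-cell center is jittered by 2 ms around the common center. The LFP
proxy is the sum over all E cells of the absolute AMPA and GABA currents,
recorded at every integration step; it is nonnegative by construction.

### Parameter provenance and calibration

The connection probabilities, population sizes, multiplier ranges
(0.095-2 for I-to-E, 0.05-2 for I-to-I), noise SD, dt and initialization are
fixed design inputs. The single-neuron and synaptic constants are *not*
printed in the text this package works from; they are behaviour-calibrated
defaults in the lineage of published adult CA1 ripple LIF models, chosen
once so that the adult network (both multipliers at 1) produces an in-band
(80-250 Hz) fast oscillation near 150 Hz, and exposed in full in
`network_params()`. The calibration logic, in order of mechanism:

* The I-I loop (delay 0.6 ms, GABA decay 0.7 ms) sets the fast,
  interneuron-led rhythm that dominates when I-I coupling is strong.
* The E-I loop (AMPA onto I with 0.8 ms decay, GABA onto E with 1.5 ms
  decay) sets a slower, ~100 Hz rhythm that dominates when I-I coupling is
  weak. Sweeping `c_gii` therefore moves the network from the slow to the
  fast rhythm, raising the oscillation frequency.
* The strength of GABA onto E (`g = 8 nS`, times `c_gei`) controls whether
  the E population is paced at all: at the lowest multiplier the
  reconstructed LFP shows no ripple-band structure of any consequence.

No claim is made that these constants equal the original ones; the model is
validated behaviourally (see the acceptance suite).

### Spectral readout of a simulation

`psd_ripple()` computes the squared FFT magnitude of the demeaned LFP and
median-filters it across bins (kernel 5). Two numerical choices matter for
100 ms transient simulations: the trace is Hann-tapered (the drive induces a
large slow transient in the current-sum LFP whose spectral leakage would
otherwise bury the ripple band), and the FFT is zero-padded fourfold so the
in-band peak is resolved on a ~2.4 Hz grid instead of 10 Hz.

`extract_peak()` whitens the spectrum against a running median of its
local surround (±60 Hz with the central ±15 Hz excluded, so a genuine
peak's own shoulder cannot inflate its background) and reports the most
prominent in-band bin. A peak counts as an oscillation only if (i) it
exceeds its local background by the factor `prominence` (default 2.2)
*and* (ii) it carries at least `min_rel_power` (default 1%) of the
spectrum's maximum. The second condition is essential:
in the low-inhibition regime a microscopic in-band modulation over an
otherwise quiet band can be locally "prominent" while being three orders of
magnitude below the signal scale; it is not ripple-like activity in any
physiological sense.

### Problem sizes

The acceptance suite runs the sweeps at 8 multiplier levels x 5 independent
realizations per axis with 100 ms per simulation; the unit tests use
reduced networks (hundreds of neurons) wherever the property under test
(refractoriness, determinism, analytic LIF limits) does not depend on scale.

## 2. The synthetic recording generator

`make_recording()` emulates the statistics of a neonatal CA1 recording:

* **Aperiodic background**: white-noise spectrum shaped by a
  $1/f^{\chi/2}$ amplitude filter and inverse-transformed — the one-sided
  PSD is $10^{offset}/f^{\chi}$ by construction, so a log-log fit of a
  Welch spectrum recovers $-\chi$ exactly up to finite-sample error.
* **Discontinuity**: neonatal LFP alternates between activity and
  near-isoelectric stretches. A binary mask with exponentially distributed
  on/off epochs (mean on-epoch 2 s, off-epoch scaled to hit
  `active_fraction`) multiplies the background, with 10 ms cosine ramps.
* **SPWs** are Gaussian deflections (amplitude ~ Normal with 15% CV,
  truncated; FWHM `spw_halfwidth_ms`) injected with *opposite polarity* on
  the two synthetic channels — negative on the radial channel, positive at
  half amplitude on the pyramidal one — emulating the laminar reversal the
  SPW detector exploits. Event times are Poisson with at least 1 s
  separation.
* **Ripples**: a fraction `ripple_prob` of SPWs carries a Hann-windowed
  sinusoid (default 6 cycles at 140 Hz) centered on the SPW peak on the
  pyramidal channel.
* **Spikes**: per-unit inhomogeneous Poisson trains — a homogeneous
  baseline plus per-event Gaussian-locked extra spikes whose rate gain is
  calibrated analytically so that the population peri-event z-score at the
  SPW peak (as computed by `peth_z()` with its default 10 ms bins and
  event-count-matched baseline anchors) is approximately
  `spw_modulation_z`. Per-unit gains are Gamma-jittered (CV 20%).

Defaults (600 s, 1000 Hz, chi = 2, offset 2.5 — in-band background SD of a
few uV — SPWs of 300 uV at 4/min, ripples of 60 uV, 40 units at 1 Hz,
modulation z = 3) describe a clean, strongly modulated recording. What the
generator does *not* emulate: multi-channel laminar profiles beyond the two
channels the detectors need, spike waveforms and sorting artifacts,
movement and line-noise artifacts, non-Poisson spike history (bursting,
refractoriness), and age-graded parameter drift within one recording.
Passing recovery tests on this corpus therefore demonstrates the pipeline's
correctness under its stated assumptions, not detector performance on real
neonatal data, where threshold settings are adjusted per animal.

## 3. The detection pipeline

All detectors follow fixed, published threshold recipes; every constant is
a function argument.

* **Active periods**: 4-12 Hz band-pass (3rd-order Butterworth, zero
  phase), downsample to 250 Hz, square, 500 ms boxcar, z-score. Label above
  1 SD *or* a 50 uV RMS envelope; merge gaps < 1 s; discard periods whose
  peak reaches neither 2 SD nor 100 uV; drop periods < 300 ms. (The
  source recipe mixes SD and uV thresholds without stating how they
  combine; we read both pairs as OR-rules, symmetrically.)
* **SPWs**: detected on the radial difference (1-100 Hz, 250 Hz, channel
  above minus channel below the pyramidal layer) as local maxima above
  mean + multiplier x SD with prominence at least threshold/2 and
  half-height width at most 100 ms. The multiplier comes from
  `adaptive_spw_multiplier()`: 5 SD for quiet signals down to 3 SD for
  high-variance ones, linear in the signal SD between calibration bounds
  (defaults 10 and 100 uV, set from the synthetic corpus) — the package's
  concretization of a threshold "inversely proportional to the signal
  variance".
* **Ripples, power method**: band-limit to 80-200 Hz (config; 100-200,
  80-250, 100-250, 100-300 are accepted for robustness checks), square,
  12 ms boxcar; label above 3 SD, merge gaps < 30 ms, discard events whose
  peak stays below 6 SD, keep lengths in (20, 100) ms — 120 ms for induced
  (optogenetic-like) events. The 12 ms smoothing window (~1.5 ripple
  cycles) was chosen over shorter windows because it is the first length
  that brings the false-positive rate on pure noise below one event per
  minute.
* **Ripples, cycle-by-cycle method**: cycles are delimited by rising
  zero-crossings of the ripple-band-filtered signal; features (amplitude,
  period, rise-decay symmetry, peak-trough symmetry, flank monotonicity)
  are measured on the broadband signal. A cycle is part of a burst when its
  rise/decay flank amplitudes are consistent (ratio >= 0.6), its period is
  consistent with its better-matching neighbour (ratio >= 0.8, so the
  malformed edge cycle of a burst cannot veto the first interior cycle),
  and its flanks are monotonic (>= 0.85 of steps in the expected direction,
  measured on the
  *raw* signal so that band-pass smoothing cannot manufacture
  monotonicity). Events are runs of >= 3 burst cycles. Two definitions were
  deliberately resolved in favour of the reference method's spirit:
  amplitude consistency compares a cycle's own rise and decay flanks
  (tapered bursts keep these close even while the envelope changes between
  cycles), and the three thresholds differ by feature rather than sharing
  one value — a single 0.6 triple either passes filtered noise or rejects
  tapered bursts, and cannot do both.
* **Consensus and coupling**: only events found by both methods count as
  ripples (boundaries from the power method); a ripple co-occurs with an
  SPW when it overlaps the window [SPW peak ± halfwidth/2). All intervals
  are half-open `[start, stop)`, so an event that merely touches a window
  boundary does not couple.
* **Length classes**: an event is a "long" ripple when duration x peak
  frequency >= 3 cycles (the adult range starts at 3 cycles; the boundary
  case, 30 ms at 100 Hz, is inclusive by that reading).
* **Movement**: a frame moves when any tracked point displaces strictly
  more than 25 pixels from the previous frame; runs of moving frames merge.

## 4. Event-locked spiking metrics

The event window for spike metrics is [peak - halfwidth, peak + halfwidth]
of the SPW, matching the support used for SPW-ripple coupling. PETHs use
10 ms bins in a ±200 ms window; z-scoring uses baseline PETHs computed at
as many random anchors as there are events, drawn outside all event
windows with a fixed seed. A per-event "modulated" call requires the
population z to reach 2 within ±50 ms of the peak (the criterion is a
documented configuration choice, not a claim about the original one). The
chemogenetic modulation index is the standard symmetric contrast
MI = (post - pre)/(post + pre), chosen because no formula is printed in the
source; it is bounded in [-1, 1] and undefined (NaN, with a warning) when
both rates are zero.

One statistical caveat is documented rather than hidden: a z-scored PETH
bin is a self-normalized statistic, so its sampling noise is of order 1
regardless of how many events enter the histogram. Tests of the generator's
`spw_modulation_z` target therefore average the measured peak z over
several independent recordings.

## 5. Piecewise-linear (segmented) trend fits

Developmental quantities in this literature change slope at estimated
breakpoints. `piecewise_linear_fit()` fits a continuous piecewise-linear
mean with 0-2 breakpoints by exhaustive grid search (resolution 0.05 in x,
restricted to the interior 5-95% of the x-range) minimizing the residual
sum of squares; for two breakpoints a coarse pass is refined locally. When
the breakpoint count is not forced, BIC (with 2 + 2k effective parameters)
selects among 0-2. Confidence intervals come from a case-resampling
bootstrap re-running the full grid search per replicate. Degenerate x
(all equal) errors; noiseless segmented input is recovered to grid
resolution.

## 6. Known limitations

* The network's neuron/synapse constants are calibrated, not transcribed;
  conclusions should be read at the level of mechanism (inhibition
  strength vs oscillation emergence and frequency), which is how the
  acceptance suite checks them.
* 100 ms simulations give at most ~10 oscillation cycles; single-run peak
  frequencies scatter by tens of Hz, which is why sweep-level statistics
  are medians over levels and realizations.
* The cycle-by-cycle detector at a 1000 Hz synthetic sampling rate
  quantizes ripple periods to 1 ms, capping usable period-consistency
  thresholds at about 0.85.
* `run_pipeline()` covers the synthetic path (generate, detect, fit,
  metrics); applying the pipeline to real multi-channel recordings
  requires channel selection and per-animal threshold curation that are
  intentionally out of scope.
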