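---
title: "An LGN spiking network and its SSVEP-style spectral analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An LGN spiking network and its SSVEP-style spectral analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgnss)
```

## The model

`lgnss` simulates a small, de-corticated model of the lateral geniculate
nucleus (LGN), the thalamic relay of the visual pathway.  Three cell
populations are modeled in the proportion 8:2:4 over 140 neurons:

* **TCR** (80 cells): thalamocortical relay neurons, the output of the
  circuit.  Their averaged membrane potential is the "model output", a
  local-field-potential-like signal comparable to occipital EEG during
  steady-state visually evoked potential (SSVEP) experiments.
* **IN** (20 cells): local interneurons providing *feed-forward* inhibition
  from the retina onto the TCR.
* **TRN** (40 cells): reticular nucleus neurons providing *feedback*
  inhibition onto the TCR and onto themselves.

Retinal drive enters through 144 spike-source channels (a 12 × 12 pixel
field) projecting to TCR and IN.  Each neuron is an Izhikevich point neuron

$$\dot v = 0.04v^2 + 5v + 140 - u + I_{psc} + I_{dc}, \qquad
  \dot u = a(bv - u),$$

with the reset rule $v > 30 \Rightarrow v \leftarrow c,\; u \leftarrow u +
d$.  TCR and TRN use the regular-spiking (RS) parameterization, IN the
fast-spiking (FS) one; all cells are assumed to operate in tonic
(relay) mode, the regime associated with attentive sensory processing.
Burst firing and synaptic plasticity are not modeled.  Synapses are
current-based with instantaneous rise and exponential decay: an arriving
spike of weight $w$ adds $w$ nA to the target's excitatory or inhibitory
accumulator, which decays as $e^{-t/\tau}$; the two accumulators are summed
with opposite signs into $I_{psc}$.

Connectivity is sparse and probabilistic: each ordered cell pair of a
pathway is connected independently with the pathway's probability
(fixed-probability connector semantics; autapses excluded within a
population).  The probabilities are normalized anatomical fan-in fractions;
weights (nA) and delays (ms) are per pathway:

| pathway | p | w (nA) | delay (ms) | sign |
|---|---|---|---|---|
| RET → TCR | 0.071 | 5 | 10 | exc |
| RET → IN | 0.474 | 4 | 10 | exc |
| IN → TCR | 0.232 | 8 | 6 | inh |
| IN → IN | 0.236 | 2 | 4 | inh |
| TRN → TCR | 0.077 | 2 | 8 | inh |
| TRN → TRN | 0.20 | 2 | 4 | inh |
| TCR → TRN | 0.35 | 3 | 8 | exc |

There is deliberately no TCR → IN pathway (only intra-layer interneurons
are modeled) and no cortical feedback (the model is the *in vitro* slice
analogue).  Inhibition onto the TCR totals 30.9%; in the base configuration
most of it is feed-forward (IN).  The `in_suppressed` variant inverts the
balance — IN → TCR drops to p = 0.07, w = 1 nA while TRN → TCR rises to
p = 0.309 — to probe the causal role of feed-forward inhibition.

The multi-node architecture (`build_multi_node()`) instantiates the
140-neuron block three times (420 neurons) at the vertices of an
equilateral triangle: every ordered node pair is wired TCR→TRN, TRN→TCR
and TRN→TRN with the intra-node attributes (nodes are equidistant, so
inter-node delays equal intra-node ones).  Interneurons stay local.  The
multi-node output is the elementwise mean of the per-node TCR series.

## Simulation and analysis chain

Simulation is clock-driven at `dt = 0.1` ms for 6 s.  Per step: stimulus
and spike arrivals due this step are read off a ring buffer, synaptic
accumulators decay and absorb them, every neuron advances one explicit
midpoint (second-order Runge–Kutta) step with its total current held
constant over the step, threshold crossings are tested after the full step,
and emitted spikes are scheduled onto their outgoing edges (delay rounded
to whole steps).  Membrane values recorded on spike steps are clamped at 30
mV.  The run is bit-reproducible from its seeds.

A protocol run (`run_trials()`) repeats the simulation for 10 trials; trial
*k* uses seed *base_seed + k − 1*, which governs both the wiring
realization and any stochastic stimulus (a `redraw_wiring = FALSE` switch
freezes the wiring across trials).  Each population's membrane series is
averaged across neurons per trial and across trials.

The analysis chain (`preprocess()`, `welch_psd()`) mirrors standard SSVEP
practice: extract the 0.5–5.5 s epoch, remove the mean, downsample to
1 kHz by plain stride, bandpass 1–100 Hz with a zero-phase order-10
Butterworth, and estimate the power spectral density with a Welch
periodogram (Hann window, 1000-sample segments, 50% overlap, transform
length 4 × the segment, hence 0.25 Hz resolution).

## Stimuli

* `periodic_train()`: all 144 channels spike simultaneously at
  $k \cdot 1000/f$ ms (the $t = 0$ spike included; optional seeded jitter,
  default none).  Frequencies 10–50 Hz at 1 Hz resolution form the sweep
  protocol.
* `poisson_trains()`: independent homogeneous Poisson processes per
  channel, the aperiodic control.
* `retina_stimulus()`: an emulated event camera (dynamic vision sensor)
  watches a flashing LED.  Each pixel log-converts illumination
  ($V_{log} = K\log I$), a differentiator tracks the change since the last
  reset, and threshold crossings emit ON/OFF events with self-reset — so an
  OFF→ON edge of contrast $C$ yields $\lfloor AK\ln C/(V_{t+}-V_{ref})
  \rfloor$ ON events.  OFF events are then discarded (ON-center
  assumption) and only each pixel's first ON event per LED cycle is kept,
  reflecting the finding that first spikes carry most of the stimulus
  information.

## Parameter choices made by this package

Values the source tables do not pin down were fixed once, before any
spectra were inspected, and are configurable:

* **Synaptic time constants** `tau_e = 2` ms, `tau_i = 6` ms — typical
  AMPA-like and GABA\(_A\)-like decay scales for thalamocortical circuits.
* **Welch details** — Hann window, 1000-sample segments, 50% overlap; the
  4× zero-padding reads the protocol's transform-length factor as padding.
* **DVS constants** — $K = 1$ V/ln-unit, $A = 5$, $V_{ref} = 0$,
  $V_{t\pm} = \pm 1$ V, so a contrast-2 LED edge yields 3 ON events per
  pixel, a realistic per-edge density; LED duty 0.5, contrast 2.
* **Stimulus-channel count** — the synthetic generators use the same 144
  channels as the 12 × 12 retina crop, making fan-in statistics identical
  across stimulus types.
* **Harmonic presence** — a component at $kf_0$ or $(2k-1)f_0/2$ counts as
  present when it is a local spectral peak at least 3× the local background
  (median in a ±5 Hz annulus) and at least 2% of the spectrum's maximum.
  The relative floor encodes how presence is judged on a log-power plot;
  without it, numerically tiny ripples orders of magnitude below the
  fundamental would register.

## Numerical choices and degenerate inputs

* The spike test is applied after the full RK2 step; at `dt = 0.1` ms this
  carries a small systematic spike-timing drift (≈0.2 ms per ~80 ms firing
  period against a 0.1 µs Euler reference — counts agree to ±1; the drift
  is a property of the fixed-step scheme, not of the implementation, and
  vanishes as `dt → 0`).
* The order-10 bandpass is realized as ten cascaded biquads designed from
  the analog prototype via the bilinear transform; a single
  transfer-function polynomial pair of order 20 with a 1 Hz corner at
  fs = 1 kHz is numerically unusable.  Zero-phase application uses odd
  reflection plus a constant lead-in long enough for the ~1000-sample
  settle of the 1 Hz sections.  Edge ringing within the outermost few
  hundred samples is inherent to any zero-phase realization of this filter
  (reference implementations inflate the boundary envelope by up to ~30%).
* Delays are converted to whole steps (`round(d/dt)`, minimum 1); arrivals
  scheduled beyond the simulation end are discarded.
* The published initial conditions sit slightly off the network's quiescent
  fixed point (−70 mV, u = −14), so the first few hundred milliseconds
  contain a decaying transient; the analysis epoch starts at 0.5 s partly
  for this reason.  Degenerate requests fail loudly: probabilities outside
  (0, 1], delays shorter than `dt`, non-positive illumination, unsorted
  transition lists, epochs outside the series.

## What the generators emulate — and what they do not

The synthetic stimuli reproduce the *protocol* of an SSVEP experiment
(periodic flicker at known frequencies, repeated trials, an aperiodic
control), not the retina's biology: there is no photon noise, no OFF
pathway, no receptive-field structure, and the emulated event camera sees a
spatially uniform LED, so all pixels behave identically up to optional
threshold mismatch.  Passing tests therefore demonstrate that the *network
model* entrains, produces harmonics, and switches to period-doubled
(subharmonic) dynamics when feed-forward inhibition is suppressed — they do
not validate the model against biological retinal recordings, which are not
shipped with the package.  Fixture event streams generated by the emulator
are labelled `synthetic` accordingly.

## Observed behavior

With the base configuration the output entrains to periodic drive across
10–50 Hz with a prominent second harmonic (run the `sweep_periodic`
recipe); with Poisson drive entrainment is absent and the spectrum forms a
broad gamma-band bump (centroid near 50 Hz) whose noisy maximum location
is insensitive to the input rate.  Under `in_suppressed`, upper-band
periodic drive (≳36 Hz) produces strong half-integer subharmonics — at
44 Hz the 22 Hz component dominates the output — while the base circuit
shows none: feed-forward inhibition is what keeps the relay's frequency
tagging clean.  In the 3-node model at 10 Hz the fundamental's dominance
over the second harmonic weakens when feed-forward inhibition is
suppressed.

## Problem sizes

The package's test suite runs the full 6 s, 10-trial protocol for the
single-frequency checks, and reduced sweeps (5 frequencies × 3 trials) for
the frequency-resolved comparisons; the full 41-frequency × 10-trial sweep
is available through `run_recipe("sweep_periodic", scale = "full")`.  A
140-neuron, 6 s trial simulates in about a second on one CPU; the 3-node
model in about three.

## Limitations

No cortical loop (the dominant generator of EEG rhythms *in vivo*), no
burst mode, no plasticity, no conductance-based synapses, and a single
fixed `dt`.  The spectral findings are properties of this particular small
circuit and parameterization; absolute power values have no physical EEG
scale.
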