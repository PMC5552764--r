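# lgnss

Spiking network model of the thalamic lateral geniculate nucleus (LGN) with
an SSVEP-style spectral analysis chain, for computational neuroscientists
studying how the visual thalamus entrains to periodic stimulation and what
feed-forward inhibition contributes to the fidelity of that relay.

## The model

The LGN is modeled as 140 Izhikevich point neurons in three populations —
80 thalamocortical relay cells (TCR), 20 interneurons (IN), 40 reticular
nucleus cells (TRN) — plus 144 retinal spike-source channels.  Each neuron
follows

    dv/dt = 0.04 v² + 5 v + 140 − u + I_psc + I_dc
    du/dt = a (b v − u),         if v > 30: v ← c, u ← u + d

with regular-spiking (TCR, TRN) or fast-spiking (IN) tonic-mode
parameterizations, and exponentially decaying current-based synapses
(`I_syn(t) = w e^(−t/τ)`).  Pathways are realized probabilistically from
anatomical fan-in fractions: the retina excites TCR (p = 0.071, 5 nA) and
IN (p = 0.474, 4 nA); IN inhibits TCR (p = 0.232, 8 nA) and itself; TRN
inhibits TCR (p = 0.077, 2 nA) and itself; TCR excites TRN (p = 0.35,
3 nA).  Inhibition onto the relay totals 30.9%, dominated by the
feed-forward (IN) arm in the base circuit; the `in_suppressed` variant
shifts that weight onto the feedback (TRN) arm.  A 3-node, 420-neuron
architecture couples three such blocks through their TCR/TRN populations.

The "model output" is the trial- and population-averaged TCR membrane
potential (an LFP-like signal).  The analysis chain — 0.5–5.5 s epoch,
downsample to 1 kHz, zero-phase order-10 Butterworth bandpass 1–100 Hz,
Welch periodogram at 0.25 Hz resolution — mirrors SSVEP practice, and
`harmonic_profile()` flags harmonics (k·f₀) and half-integer subharmonics
((2k−1)·f₀/2).  Stimuli are synthetic periodic or Poisson spike trains, or
the output of a built-in dynamic-vision-sensor (event camera) emulator
watching a flashing LED, with the first-ON-spike-per-cycle filter applied.

## Worked example

```r
library(lgnss)
net <- build_lgn(lgn_config())
net
#> LGN network: 140 neurons in 3 population(s), 1 node(s), variant 'base'
#>   144 retinal source channels, 7 projection pathways

avg <- run_trials(net, list(type = "periodic", freq = 20),
                  n_trials = 10, base_seed = 1)
psd <- welch_psd(preprocess(model_output(avg)))
peak_frequency(psd)
#> [1] 20
as.data.frame(harmonic_profile(psd, 20))[, c("component", "freq", "power", "present")]
#>   component freq    power present
#> 1        1f   20 1.18e+02    TRUE
#> 2        2f   40 5.98e+01    TRUE
#> 3        3f   60 4.12e+01    TRUE
#> 4        4f   80 2.19e+01    TRUE
#> 5        5f  100 1.78e+00   FALSE
#> 6      1/2f   10 3.75e-02   FALSE
#> 7      3/2f   30 1.37e-02   FALSE
#> 8      5/2f   50 7.91e-03   FALSE
#> 9      7/2f   70 1.16e-02   FALSE
```

The output entrains: a 20 Hz periodic retinal drive produces a spectrum
peaking exactly at 20 Hz with harmonics through 4f and no subharmonic
content.  Rebuilding with `lgn_config("in_suppressed")` — feed-forward
inhibition weakened, feedback inhibition dominant — and driving at 44 Hz
moves the dominant peak to 22 Hz (a half-frequency, period-doubled
response), the model's signature of degraded frequency tagging.

Experiment recipes (`run_recipe()`: `tonic_demo`, `sweep_periodic`,
`sweep_poisson`, `in_suppression`, `retina_compare`, `multi_node`) run the
full protocols and write series, PSD matrices, sweep images and a JSON
summary; `inst/scripts/lgnss-cli.R` exposes them from the shell.

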