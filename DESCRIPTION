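Package: lgnss
Title: Spiking Network Model of the Lateral Geniculate Nucleus with
    SSVEP-Style Spectral Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Clock-driven simulation of a 140-neuron spiking network model of
    the thalamic lateral geniculate nucleus (LGN) built from Izhikevich point
    neurons with exponentially decaying current-based synapses.  The package
    provides biologically derived probabilistic connectivity between
    thalamocortical relay (TCR), interneuron (IN) and reticular nucleus (TRN)
    populations, periodic and Poisson retinal spike-train generators, an
    event-camera (dynamic vision sensor) pixel emulator driven by a flashing
    LED, a steady-state visually evoked potential (SSVEP) style analysis chain
    (epoching, downsampling, zero-phase Butterworth bandpass, Welch power
    spectral density), harmonic and subharmonic detection, input-frequency
    sweeps, a feed-forward-inhibition suppression variant, and a multi-node
    (3 x 140 neuron) scaled architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
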