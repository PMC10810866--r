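Package: ripplekit
Title: Simulation and Detection of Developing Hippocampal Sharp Wave-Ripples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the emergence of sharp wave-ripple (SPW-R)
    complexes in the developing hippocampal CA1 area. Provides a two-population
    leaky integrate-and-fire network model of CA1 (12,000 pyramidal cells, 200
    parvalbumin-positive basket cells) with conductance-based biexponential
    synapses, inhibitory-conductance sweeps, and an LFP proxy reconstructed
    from synaptic currents; a complete extracellular analysis pipeline with
    active-period detection, adaptive-threshold sharp-wave detection,
    dual-method (power-threshold and cycle-by-cycle) ripple detection with
    consensus and SPW coupling; Welch spectra with parameterization into
    aperiodic (1/f exponent) and periodic (Gaussian peak) components;
    event-locked spiking metrics (peri-event histograms, first-spike offsets,
    participation); piecewise-linear breakpoint trend fits; and a
    ground-truthed synthetic recording generator so every stage is testable
    without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
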