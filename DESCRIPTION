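Package: cbcstim
Title: Multi-Compartment Simulation of Retinal Bipolar Cells Under
    Subretinal Electric Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of rat ON and OFF cone bipolar cells driven by
    a voltage-controlled subretinal disk electrode. A finite-difference
    volume-conductor solver computes the extracellular potential in a layered
    chip/retina/tamponade volume; a multi-compartment cable model with
    Hodgkin-Huxley-style T-type and L-type calcium channels and dynamic
    intracellular calcium integrates the cellular response. Includes seeded
    generators for the two cell morphologies, SWC import/export, stimulus
    waveform constructors (monophasic, charge-balanced biphasic, bursts,
    sinusoids), voltage-clamp protocols, and scripted experiments
    (axon-length sweeps, electrode position maps, calcium decay times,
    single-compartment frequency responses).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
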