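Package: synaptoprobe
Title: Patch-Clamp Analysis of Synaptic Activity and Intrinsic Excitability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and group statistics for whole-cell
    patch-clamp recordings of cultured neurons, built around the analyses
    used to characterize reduced spontaneous synaptic activity in
    patient-derived dopaminergic neurons. Detects spontaneous excitatory
    postsynaptic currents (EPSCs) and fits their decay time constants,
    counts evoked action potentials over current-step families, measures
    spike shape (second-derivative threshold, amplitude, full width at
    half maximum, fast afterhyperpolarization), estimates passive membrane
    properties (input conductance, capacitance by charge integration),
    extracts capacitance-normalized sodium and potassium current-voltage
    curves, and compares neuron groups with Welch t-tests, Fisher exact
    tests, ANOVA and Kolmogorov-Smirnov statistics. A synthetic-trace
    generator with complete ground truth (Poisson EPSC trains, parametric
    spike templates, Boltzmann-gated currents, RC membrane tests and
    multi-group cohorts) makes every analysis stage verifiable without
    access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
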