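Package: purkinet
Title: Purkinje Network Topology and Reentrant Arrhythmia Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale monodomain simulation of ventricular myocardium
    coupled to a rule-based His-Purkinje system, built to study how distal
    Purkinje fiber reconnections (mesh versus tree network topology) shape
    anterograde activation, retrograde activation, and the initiation and
    maintenance of reentrant arrhythmias. Provides generators for synthetic
    Purkinje networks with reunification (cross-bridge) cables and the
    pruning algorithm that converts a meshed network into a tree while
    preserving every Purkinje-muscular junction; a two-variable
    phenomenological membrane model with action-potential-duration
    calibration; a coupled tissue/cable reaction-diffusion solver with
    resistive junctional coupling; programmed-stimulation protocol drivers
    (diastolic threshold search, His pacing, S1 pacing, S1S2 scans, rapid
    line pacing); activation-map comparison statistics; and reentry
    detection with vulnerable-window bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
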