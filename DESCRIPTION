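Package: phasortacs
Title: Multi-Site Multi-Phase tACS Montage Design with Finite-Element
    Field Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Design of transcranial alternating current stimulation (tACS)
    montages that deliver a desired electric-field amplitude and arbitrary
    inter-regional phase delays over multiple cortical regions at once.
    Provides a parametric layered-sphere finite-element head phantom with
    10-10 scalp electrodes and a Gmsh MSH reader for external labeled
    meshes, an electrostatic forward solver (P1 tetrahedral elements) with
    lead-field superposition, complex least-squares optimization of
    per-electrode injection-current phasors with uniform safety-limit
    scaling, evaluation metrics for the achieved field (amplitude and phase
    maps, half-maximum areas, circular median phases, lead angles, percent
    errors), ramped stimulation waveform rendering, and signal-detection
    working-memory indices (K value, load-weighted d-prime, lateralization
    index) with a generative simulator of lateralized change-detection
    sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
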