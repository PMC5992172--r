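Package: slideforce
Title: Stopping-Force Analysis for Kinesin-14 Driven Microtubule Transport
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of single-molecule optical-tweezers and
    motility assays of kinesin-14 (Ncd) driven microtubule transport.
    Estimates motor-team stopping forces from force traces (baseline offset,
    binding detection, plateau averaging, vector-magnitude force) and from
    weighted linear force-velocity fits; computes the passive forces used as
    independent corroborations (entropic force of confined diffusible
    crosslinkers, filament buckling force); summarises filament-track
    velocities with time weighting and boxplot statistics; counts motors from
    integrated fluorescence intensity. A synthetic-assay generator (exact
    Ornstein-Uhlenbeck bead-in-trap simulation, force-feedback scans,
    filament tracks, intensity draws, overlap-shortening series) makes every
    estimator testable by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
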