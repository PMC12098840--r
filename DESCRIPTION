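Package: magnetokit
Title: Simulation and Control Analysis for Low-Frequency Magnetic
    Neuromodulation Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Hardware-free toolkit for designing and validating low-frequency
    magnetic neuromodulation rigs. Provides an analytic magnetostatic field
    engine for circular thick coils, coaxial coil arrays and rectangular
    coils (complete elliptic integrals and finite-segment Biot-Savart), with
    field-homogeneity reports over user-defined regions; a stimulation
    protocol compiler that emits H-bridge pin-pair waveforms with dead-time
    insertion and shoot-through safety guarantees; a three-gate closed-loop
    controller over sensor and position streams with threshold interrupts;
    ROI-threshold video tracking algorithms for rodent behavioural assays
    (light-dark box, three-chamber place preference, open field) with
    centroid locomotion metrics; sensor transfer functions and agreement
    statistics (Pearson, Bland-Altman, SUS); and synthetic-data generators
    (virtual arenas, rendered frames, sensor traces with injectable
    anomalies) wired into a virtual rig for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    pracma,
    stats,
    utils,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
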