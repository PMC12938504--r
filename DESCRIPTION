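Package: grafttwin
Title: Digital Twin of a Pinch-Valve Regulated Vascular Graft Culture Platform
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale digital twin of an automated perfusion platform for
    tissue-engineered vascular grafts. Simulates the lumped-parameter hydraulic
    circuit of the platform in its two operating configurations (ISO 7198
    dynamic radial compliance testing and coronary-like counter-phase
    stimulation), including the two-stage pinch-valve control algorithm
    (open-loop pre-setting followed by per-cycle PID envelope regulation) and
    the safety interlock. Implements the image-based compliance measurement on
    synthetic stereo-microscope frame stacks (registration, binarization,
    ten-station pixel-count diameter extraction, wall subtraction) and the
    pulsatile waveform analytics used to characterize coronary-like
    hemodynamics (cycle detection, per-cycle pressure and flow metrics,
    counter-phase indices, Welch heteroscedastic ANOVA for long-term
    stability). Includes models of the silicone phantom pressure-diameter law,
    glycerol-water viscosity, and Poiseuille wall shear stress.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr,
    optparse
Config/testthat/edition: 3
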