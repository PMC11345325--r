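Package: vfimix
Title: Simulation and Quantification of the VA-ECMO Mixing Zone with
    High-Frame-Rate Ultrasound Vector Flow Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Synthetic reproduction of a bench-top vector flow imaging (VFI)
    study of the thoracic aorta under veno-arterial extracorporeal membrane
    oxygenation (VA-ECMO). Generates ground-truth pulsatile/counterflow
    velocity fields with vortices and a bi-modal pressure waveform, simulates
    dual-angle plane-wave Doppler acquisition with aliasing and noise,
    recovers per-pixel velocity vectors by least squares, segments the
    cardiac cycle, categorizes vectors into the five anterograde/retrograde
    speed-direction groups with per-frame area ratios and Welch comparisons,
    localizes the cardiac/ECMO mixing zone along the aortic path, and renders
    vector-projectile style cineloops.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
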