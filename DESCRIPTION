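Package: cmrhythm
Title: Arrhythmia, Beat-Rate-Variability and Calcium-Handling Analysis for
    Cardiomyocyte Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and classification of arrhythmogenic events (delayed
    afterdepolarizations, oscillatory pre-potentials, failed beats) in
    intracellular action-potential recordings from cardiomyocytes, together
    with the surrounding quantitative pipeline: beat/spike/R-wave detection
    for patch-clamp, microelectrode-array and ECG signals; action-potential
    feature extraction (MDP, APA, peak, dV/dt max, APD90); Poincare-plot
    beat-rate-variability measures (CV, SD1, SD2) with Gaussian-mixture
    bimodality detection; calcium-transient and caffeine-response analysis;
    nucleus/cytoplasm fluorescence density ratio quantification; ventricular
    arrhythmia episode scoring in whole-heart recordings; and a
    normality-gated parametric/non-parametric group-comparison decision
    tree. Seeded synthetic-data generators with ground-truth labels emulate
    every input modality so the whole pipeline is testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mclust,
    signal,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    nortest,
    tiff,
    png
Config/testthat/edition: 3
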