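Package: icbands
Title: Bilateral Spontaneous and Tone-Evoked Activity Analysis for
    Wide-Field Calcium Imaging of the Developing Auditory Midbrain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for wide-field calcium-imaging movies of the
    developing inferior colliculus (IC). Implements the seven-step movie
    preprocessing chain (photobleach correction, subpixel rigid registration,
    Gaussian smoothing, ROI masking, 2x2 average pooling, SVD denoising,
    dF/F0 normalization), line-scan reduction and spatiotemporal band-event
    detection, global and seed-based bilateral partial-correlation analysis
    with regional morphology, diffusion-map embedding of pixel activity, and
    tone-evoked auditory-threshold estimation from trial-averaged responses.
    A seeded synthetic-movie generator with known ground truth (band-shaped
    events with tonotopic reversal, tunable bilateral coupling, bleaching,
    motion and noise artifacts) makes every stage verifiable without raw
    recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
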