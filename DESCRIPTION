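Package: funduscreen
Title: Automated Hard-Exudate Screening of Retinal Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Classical image-processing pipeline for screening colour fundus
    photographs for hard exudates, the hallmark bright lesions of diabetic
    retinopathy. Stages: green-channel preprocessing (histogram stretching,
    median denoising, mean-adaptive gamma attenuation), retinal vascular
    pattern extraction with a twelve-orientation Gaussian matched filter and
    maximum-entropy (Kapur) binarization, vessel and optic-disk removal, fixed
    threshold lesion segmentation and a healthy/pathological decision.
    Includes a synthetic fundus phantom generator with pixel-level ground
    truth for offline validation, screening-performance metrics (sensitivity,
    specificity, accuracy, FAR, FRR) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jpeg,
    jsonlite,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
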