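Package: ulcerseg
Title: Automated Corneal Ulcer Segmentation from Fluorescein Slit-Lamp Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated, training-free segmentation of corneal ulcers in
    fluorescein-stained ocular surface photographs. Implements a classical
    pipeline: specular-reflection masking from the blue channel, green-channel
    smoothing, squaring and binarization, an elliptical pre-mask and
    morphological thinning, eye-border recognition by a generalized Hough
    transform over Gielis Superformula templates, cornea-disk extraction, and
    rejection of eyelid fluorescein accumulations by a border-contact and
    axis-ratio rule. Includes pixel-level evaluation metrics (accuracy,
    sensitivity, specificity, Jaccard/IoU, Dice), batch evaluation reports,
    and a seeded synthetic fluorescein-eye generator with exhaustive ground
    truth for testing every stage without external data.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    grDevices,
    graphics,
    jpeg,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
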