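Package: rawaaa
Title: Regional Aortic Weakness Scoring for Abdominal Aortic Aneurysms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the Regional Aortic Weakness (RAW) index for abdominal
    aortic aneurysms from image-derived surface meshes: lumen centerline
    extraction, parcellation of the outer wall into 24 tracked patches,
    region-averaged intraluminal thrombus thickness, time-averaged wall shear
    stress and maximum principal Green-Lagrange strain, quartile-based
    categorization and the 0-10 RAW score.  Includes analysis of ex vivo
    stress-strain curves (ultimate tensile strength, hysteresis energy loss),
    normality-gated two-group tests, correlation selection and bootstrap
    ROC/AUC validation, and a seeded synthetic aneurysm generator with known
    ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
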