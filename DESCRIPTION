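Package: batquant
Title: Quantification of Human Brown Adipose Tissue from PET-MRI and PET-CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-automated quantification of human brown adipose tissue
    (BAT) from co-registered PET-MRI (Dixon fat-fraction masking, BARCIST
    lean-mass SUV thresholding, in-plane erosion, depot metrics) and from
    PET-CT (Hounsfield-unit windowing, body-mass SUV thresholding,
    BAT-positive classification), together with cold-induced thermogenesis,
    thermal-imaging and extracellular-flux (OCR) metric computations.
    Includes a synthetic phantom generator emitting co-registered Dixon,
    PET and CT volumes with ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
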