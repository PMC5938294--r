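Package: lithometry
Title: Automated 3D Ureteral Stone Segmentation, Morphometry and Passage Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated three-dimensional segmentation and morphometry of
    ureteral stones on non-contrast CT. Implements adaptive half-maximum
    Hounsfield thresholding with a 200-HU floor, connected-component
    selection, spherical morphological dilation, and six size estimates
    (maximum Feret length, perpendicular-reformat width, maximal
    cross-sectional area and circumference, enclosing-surface volume and
    surface area). Couples the size estimates to location-specific logistic
    spontaneous-passage curves calibrated from published anchor
    probabilities, and provides the statistical toolkit (ROC AUC with
    DeLong intervals, Bland-Altman limits of agreement, percentage-point
    binning, Friedman's rank test) together with digital stone phantoms and
    cohort simulators for studying the impact of inter-reader measurement
    variability on the predicted prognosis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    pROC,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
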