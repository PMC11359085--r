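Package: irmimic
Title: Infrared Camera Degradation Modelling and Thermal Recovery Curve Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing whether low-cost long-wave infrared cameras are
    adequate for active-thermography applications such as skin cancer screening.
    The package characterizes a camera's spatial fixed-pattern noise and
    per-detector temporal noise from blackbody calibration stacks, corrects
    non-uniformity-correction (NUC) step artifacts, and degrades high-quality
    thermal video (temporal downsampling, point-spread-function blur, spatial
    and temporal noise injection) to mimic acquisition with a lower-cost
    imager. It also implements a thermoregulation-curve screening pipeline:
    marker-based affine registration, per-pixel double-exponential recovery
    modelling, reference-temperature curve selection, distance/energy and
    statistical-similitude feature extraction, and bootstrap classifier
    evaluation. A synthetic-scene generator provides ground-truth thermal
    acquisitions, paired two-camera captures, and blackbody stacks for
    validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    png,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    e1071,
    class,
    xgboost,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
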