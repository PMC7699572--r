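Package: aircine
Title: Dynamic Upper-Airway Cine MRI Morphometry
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies dynamic upper-airway caliber from axial cine MRI of
    spontaneously breathing subjects. Segments the airway lumen per frame with
    a seeded region-growing algorithm bounded by intensity-profile peaks along
    the transverse and anterior-posterior axes, extracts cross-sectional area
    and axis diameters in physical units, summarizes respiratory-cycle
    dynamics as true-minimum, mean and maximum via peak/valley averaging, and
    provides the paired, mixed-effects and Dunnett-adjusted comparison
    machinery used to contrast anesthetic conditions. Includes a synthetic
    breathing-phantom generator with analytic ground truth for validating the
    segmentation and the statistical calibration, plus a paired t-test power
    calculator based on the noncentral t distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    RNifti,
    tiff,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    emmeans,
    mvtnorm
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, ImageSegmentation, Visualization
RoxygenNote: 7.3.3
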