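Package: dosepaintr
Title: Biologically Guided Dose Painting for Carbon-Ion Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Voxel-wise Poisson tumor control probability (TCP) modelling
    driven by clonogenic cell-count maps, survival-minimizing dose
    escalation and redistribution under clinical box and mean-dose
    constraints, setup/range robustness scenarios, RMSE-based cell-count
    uncertainty analysis, and DVH/LVH plan evaluation. Ships a synthetic
    phantom and cohort generator emulating diffusion-MRI-derived
    microstructure maps so the full pipeline runs without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
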