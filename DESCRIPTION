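Package: castrr
Title: Calibrated Short-TR Recovery Mapping of the Brain-Blood Partition Coefficient
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the brain-blood partition coefficient (BBPC) from
    multi-TR spoiled gradient-echo image stacks by voxel-wise
    saturation-recovery fitting, calibrates relative proton density against
    phantoms of known water content, and uses the resulting BBPC maps to
    correct pseudo-continuous arterial spin labeling (pCASL) cerebral blood
    flow maps. Includes a digital mouse-head phantom simulator with known
    ground truth, rigid registration and resampling between acquisition
    grids, and region-of-interest summaries of gray-white perfusion
    contrast.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    minpack.lm,
    EBImage,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
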