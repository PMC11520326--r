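Package: fdgpet
Title: Small-Animal FDG-PET Quantification, Digital Phantoms, and
    Mixed-Effects Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end quantification and inference pipeline for dynamic
    rodent brain FDG-PET. Provides label-atlas handling (majority-vote
    downsampling, region volumes, smoothed brain-mask targets), a digital
    rat-brain phantom that renders dynamic scans with known pose and uptake
    ground truth, automated coarse/fine affine registration (6 and 9 degrees
    of freedom) to atlas space including within-subject pairing and
    study-template refinement, regional time-activity curve extraction with
    standardized uptake value (SUV) and whole-brain-normalized SUVr
    computation, and repeated-measures statistics: genotype-by-time linear
    mixed-effects models with Tukey post-hoc contrasts, brain-behavior
    models, an exploratory multiplicity screen, and voxel-wise two-sample
    t maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    lme4,
    lmerTest,
    emmeans,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
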